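# Independent brute-force oracles used to pin expected values.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# O(n^2) pairwise AUC: P(score_pos > score_neg) + 0.5 P(equal)
oracleAUC <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  wins <- outer(sp, sn, ">")
  ties <- outer(sp, sn, "==")
  (sum(wins) + 0.5 * sum(ties)) / (length(sp) * length(sn))
}

# direct metric arithmetic from a confusion list
oracleMetrics <- function(cc) {
  TP <- cc$TP; FP <- cc$FP; TN <- cc$TN; FN <- cc$FN
  den <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  list(sens = TP / (TP + FN), spec = TN / (TN + FP),
       acc = 100 * (TP + TN) / (TP + FP + TN + FN),
       mcc = if (den == 0) 0 else (as.numeric(TP) * TN - as.numeric(FP) * FN) / den)
}

# hand-computed Benjamini-Hochberg step-up
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# --- motif-mining oracle -------------------------------------------------
# Group tables read directly from the packaged CSVs (shared data, not
# shared code); matching and counting are naive loops.

oracleSchemeGroups <- function(name) {
  if (name == "NONE") return(stats::setNames(as.list(AA20), AA20))
  file <- if (name == "KOOLMAN") "scheme_koolman.csv" else "scheme_betts_russell.csv"
  tab <- read.csv(system.file("extdata", file, package = "il2kit"))
  stats::setNames(lapply(tab$residues, function(s) strsplit(s, "")[[1]]),
                  tab$group)
}

oracleSymbolSet <- function(name) {
  g <- oracleSchemeGroups(name)
  syms <- unique(c(AA20, names(g)))
  res <- lapply(syms, function(s) if (s %in% AA20) s else g[[s]])
  stats::setNames(res, syms)
}

# does a symbol pattern (list of residue sets) match sequence anywhere?
oracleMatches <- function(seq, patsets) {
  r <- strsplit(seq, "")[[1]]
  m <- length(patsets)
  if (m > length(r)) return(FALSE)
  for (off in 0:(length(r) - m)) {
    ok <- TRUE
    for (j in seq_len(m))
      if (!(r[off + j] %in% patsets[[j]])) { ok <- FALSE; break }
    if (ok) return(TRUE)
  }
  FALSE
}

oracleCountSupport <- function(seqs, patsets) {
  sum(vapply(seqs, oracleMatches, logical(1), patsets = patsets))
}

# Enumerate every pattern up to maxLen that is compatible with at least one
# window of a positive sequence (a pattern matching no positive window has
# zero positive support, hence cannot satisfy minPos >= 1), count supports
# by direct matching, and keep patterns with pos >= minPos and neg <= fp.
oracleMineMotifs <- function(posSeqs, negSeqs, scheme, fp, minPos, maxLen) {
  symset <- oracleSymbolSet(scheme)
  symOf <- lapply(AA20, function(a)
    names(symset)[vapply(symset, function(ss) a %in% ss, logical(1))])
  names(symOf) <- AA20
  pats <- new.env(parent = emptyenv())
  for (s in posSeqs) {
    r <- strsplit(s, "")[[1]]
    for (len in seq_len(min(maxLen, length(r)))) {
      for (off in 0:(length(r) - len)) {
        win <- r[(off + 1):(off + len)]
        combos <- expand.grid(lapply(win, function(a) symOf[[a]]),
                              stringsAsFactors = FALSE)
        for (k in seq_len(nrow(combos)))
          pats[[paste(unlist(combos[k, ]), collapse = " ")]] <- TRUE
      }
    }
  }
  keys <- ls(pats)
  rows <- lapply(keys, function(key) {
    syms <- strsplit(key, " ")[[1]]
    patsets <- symset[syms]
    pc <- oracleCountSupport(posSeqs, patsets)
    if (pc < minPos) return(NULL)
    nc <- oracleCountSupport(negSeqs, patsets)
    if (nc > fp) return(NULL)
    data.frame(motif = key, pos_count = pc, neg_count = nc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(motif = character(0), pos_count = integer(0),
                      neg_count = integer(0))
  out[order(out$motif), , drop = FALSE]
}

# fully exhaustive variant (every pattern over the alphabet), only viable
# for maxLen <= 2; used to validate the window-derived enumeration
oracleMineExhaustive <- function(posSeqs, negSeqs, scheme, fp, minPos, maxLen) {
  symset <- oracleSymbolSet(scheme)
  syms <- names(symset)
  all_pats <- unlist(lapply(seq_len(maxLen), function(len) {
    combos <- expand.grid(rep(list(syms), len), stringsAsFactors = FALSE)
    apply(combos, 1, paste, collapse = " ")
  }))
  rows <- lapply(all_pats, function(key) {
    ss <- symset[strsplit(key, " ")[[1]]]
    pc <- oracleCountSupport(posSeqs, ss)
    if (pc < minPos) return(NULL)
    nc <- oracleCountSupport(negSeqs, ss)
    if (nc > fp) return(NULL)
    data.frame(motif = key, pos_count = pc, neg_count = nc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(motif = character(0), pos_count = integer(0),
                      neg_count = integer(0))
  out[order(out$motif), , drop = FALSE]
}
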