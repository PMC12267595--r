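# Discriminative motif mining over plain and degenerate residue-class
# alphabets. Motifs are contiguous; a motif symbol is either a specific
# residue or a physicochemical group symbol of the active classification
# scheme (mixed symbols are permitted). Counting is sequence-level: a motif
# "occurs in" a sequence when it matches at >= 1 offset.

#' Residue classification schemes
#'
#' Returns the named residue grouping used for degenerate motif symbols.
#' `NONE` applies no grouping (20 singleton groups, so motifs are plain
#' substrings). `BETTS-RUSSELL` groups residues into polar, hydrophobic and
#' small; `KOOLMAN` into aliphatic, aromatic, sulfur, hydroxyl, basic,
#' acidic/amide and imino. The two non-trivial group tables ship as editable
#' CSV resources under `inst/extdata`.
#'
#' @param name `"NONE"`, `"BETTS-RUSSELL"` or `"KOOLMAN"`.
#' @return list with elements `name` and `groups` (named list of residue
#'   character vectors; for the non-trivial schemes the residue symbols
#'   themselves are also valid motif symbols).
#' @export
classificationScheme <- function(name = c("NONE", "BETTS-RUSSELL", "KOOLMAN")) {
  name <- match.arg(toupper(name), c("NONE", "BETTS-RUSSELL", "KOOLMAN"))
  groups <- if (name == "NONE") {
    stats::setNames(as.list(AA_ALPHABET20), AA_ALPHABET20)
  } else {
    file <- if (name == "KOOLMAN") "scheme_koolman.csv" else "scheme_betts_russell.csv"
    tab <- readPackagedTable(file)
    stats::setNames(lapply(tab$residues, function(s) strsplit(s, "")[[1]]),
                    tab$group)
  }
  list(name = name, groups = groups)
}

# alphabet of motif symbols for a scheme: the 20 residues plus (for
# non-trivial schemes) the group symbols
schemeAlphabet <- function(scheme) {
  if (scheme$name == "NONE") AA_ALPHABET20
  else c(AA_ALPHABET20, names(scheme$groups))
}

# logical membership matrix: symbol x residue-index (1..20)
schemeMembership <- function(scheme) {
  syms <- schemeAlphabet(scheme)
  memb <- matrix(FALSE, length(syms), 20,
                 dimnames = list(syms, AA_ALPHABET20))
  for (a in AA_ALPHABET20) memb[a, a] <- TRUE
  if (scheme$name != "NONE")
    for (g in names(scheme$groups)) memb[g, scheme$groups[[g]]] <- TRUE
  memb
}

motifSymbolsOf <- function(motif) {
  if (length(motif) == 1 && grepl(" ", motif)) strsplit(motif, " +")[[1]]
  else as.character(motif)
}

# start offsets (1-based) of pattern (symbol indices) in integer sequence
patternStarts <- function(iseq, pat, memb) {
  L <- length(iseq)
  m <- length(pat)
  if (m > L) return(integer(0))
  ok <- memb[pat[1], iseq[seq_len(L - m + 1)]]
  if (m > 1) for (j in 2:m)
    ok <- ok & memb[pat[j], iseq[j:(L - m + j)]]
  which(ok)
}

#' Match a motif against a sequence
#'
#' Reports every contiguous occurrence where each position's residue equals
#' the motif symbol (residue symbols) or belongs to the symbol's group
#' (class symbols), in leftmost-first order. Offsets are 0-based, half-open.
#'
#' @param sequence a peptide/protein string.
#' @param motif motif symbols: a character vector, or a single
#'   space-separated string as in motif tables (`"A L E G"`).
#' @param scheme scheme name or a [classificationScheme()] list.
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `motif`; zero rows when there is no match.
#' @examples
#' matchMotif("KKALEGKK", "A L E G")
#' matchMotif("LEVE", c("hydrophobic", "E"), scheme = "BETTS-RUSSELL")
#' @export
matchMotif <- function(sequence, motif, scheme = "NONE") {
  if (is.character(scheme)) scheme <- classificationScheme(scheme)
  memb <- schemeMembership(scheme)
  syms <- motifSymbolsOf(motif)
  unknown <- setdiff(syms, rownames(memb))
  if (length(unknown))
    stop("unknown motif symbol(s) for scheme ", scheme$name, ": ",
         paste(unknown, collapse = ", "))
  iseq <- match(seqToResidues(sequence), AA_ALPHABET20)
  pat <- match(syms, rownames(memb))
  st <- unname(patternStarts(iseq, pat, memb))
  data.frame(start = st - 1L, end = st - 1L + length(pat),
             motif = rep(paste(syms, collapse = " "), length(st)),
             stringsAsFactors = FALSE)
}

#' Mine discriminative motifs
#'
#' Breadth-first enumeration of contiguous motifs over the scheme alphabet,
#' starting from single symbols and extending to the right one symbol per
#' level. A candidate is pruned when the number of positive sequences
#' containing it drops below `minPos` (sequence-level support is
#' anti-monotone under extension). Emitted motifs satisfy
#' `pos_count >= minPos` and `neg_count <= fp`, counting sequences (not
#' occurrences). Results are sorted by `pos_count` descending, ties broken
#' by shorter length then lexicographic symbol order.
#'
#' @param pos,neg [PeptideSet-class] objects with the positive and negative
#'   sequences (labels are not consulted; set membership defines the class).
#' @param scheme scheme name or [classificationScheme()] list.
#' @param fp maximum number of negative sequences an emitted motif may occur
#'   in (default 10, the setting selected for the main dataset).
#' @param minPos minimum positive sequence support; default 2\% of the
#'   positive set (at least 1).
#' @param maxLen maximum motif length (default 7).
#' @return data.frame with columns `motif` (space-separated symbols),
#'   `scheme`, `pos_count`, `neg_count`.
#' @examples
#' pos <- PeptideSet(rep("KKALEGKK", 3), ids = paste0("p", 1:3))
#' neg <- PeptideSet(rep("DDDTTTCC", 3), ids = paste0("n", 1:3))
#' head(mineMotifs(pos, neg, fp = 0, minPos = 3, maxLen = 4))
#' @export
mineMotifs <- function(pos, neg, scheme = "NONE", fp = 10L, minPos = NULL,
                       maxLen = 7L) {
  stopifnot(fp >= 0, maxLen >= 1)
  if (length(pos) == 0) stop("empty positive set")
  if (is.character(scheme)) scheme <- classificationScheme(scheme)
  if (is.null(minPos)) minPos <- max(1L, ceiling(0.02 * length(pos)))
  stopifnot(minPos >= 1)
  memb <- schemeMembership(scheme)
  syms <- rownames(memb)
  nsym <- length(syms)
  posI <- lapply(peptideSequences(pos),
                 function(s) match(seqToResidues(s), AA_ALPHABET20))
  negI <- lapply(peptideSequences(neg),
                 function(s) match(seqToResidues(s), AA_ALPHABET20))

  containing <- function(seqlist, idx, pat) {
    idx[vapply(seqlist[idx],
               function(is) length(patternStarts(is, pat, memb)) > 0,
               logical(1))]
  }

  out_pat <- list(); out_pos <- integer(0); out_neg <- integer(0)
  # frontier entries: pattern (symbol indices), posMatch, negMatch indices
  frontier <- lapply(seq_len(nsym), function(s) {
    pm <- containing(posI, seq_along(posI), s)
    nm <- containing(negI, seq_along(negI), s)
    list(pat = s, pm = pm, nm = nm)
  })
  frontier <- Filter(function(e) length(e$pm) >= minPos, frontier)
  for (level in seq_len(maxLen)) {
    for (e in frontier) {
      if (length(e$nm) <= fp) {
        out_pat[[length(out_pat) + 1L]] <- e$pat
        out_pos <- c(out_pos, length(e$pm))
        out_neg <- c(out_neg, length(e$nm))
      }
    }
    if (level == maxLen || length(frontier) == 0) break
    nxt <- list()
    for (e in frontier) {
      for (s in seq_len(nsym)) {
        pat <- c(e$pat, s)
        pm <- containing(posI, e$pm, pat)
        if (length(pm) < minPos) next
        nm <- containing(negI, e$nm, pat)
        nxt[[length(nxt) + 1L]] <- list(pat = pat, pm = pm, nm = nm)
      }
    }
    frontier <- nxt
  }
  motif_str <- vapply(out_pat, function(p) paste(syms[p], collapse = " "),
                      character(1))
  res <- data.frame(motif = motif_str,
                    scheme = rep(scheme$name, length(motif_str)),
                    pos_count = out_pos, neg_count = out_neg,
                    stringsAsFactors = FALSE)
  len <- lengths(out_pat)
  res <- res[order(-res$pos_count, len, res$motif), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Motif coverage over a labeled dataset
#'
#' For each motif, counts the positive- and negative-labeled sequences of
#' `dataset` containing at least one hit.
#'
#' @param motifs data.frame as returned by [mineMotifs()] (columns `motif`,
#'   `scheme`), or a character vector of motifs (then `scheme` applies).
#' @param dataset a labeled [PeptideSet-class].
#' @param scheme scheme used when `motifs` is a character vector.
#' @return data.frame `motif, scheme, pos_count, neg_count`.
#' @export
motifCoverage <- function(motifs, dataset, scheme = "NONE") {
  if (is.character(motifs))
    motifs <- data.frame(motif = motifs, scheme = scheme,
                         stringsAsFactors = FALSE)
  labs <- peptideLabels(dataset)
  seqs <- peptideSequences(dataset)
  pos_count <- integer(nrow(motifs)); neg_count <- integer(nrow(motifs))
  for (k in seq_len(nrow(motifs))) {
    hit <- vapply(seqs, function(s)
      nrow(matchMotif(s, motifs$motif[k], motifs$scheme[k])) > 0, logical(1))
    pos_count[k] <- sum(hit & labs == "positive", na.rm = TRUE)
    neg_count[k] <- sum(hit & labs == "negative", na.rm = TRUE)
  }
  data.frame(motif = motifs$motif, scheme = motifs$scheme,
             pos_count = pos_count, neg_count = neg_count,
             stringsAsFactors = FALSE)
}

#' Read / write motif tables
#'
#' CSV serialization `motif,scheme,pos_count,neg_count` with symbols
#' space-separated (`"A L E G"`).
#'
#' @param motifs motif data.frame
#' @param path file path
#' @export
writeMotifCSV <- function(motifs, path) {
  utils::write.csv(motifs, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeMotifCSV
#' @export
readMotifCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
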