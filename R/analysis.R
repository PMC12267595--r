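# Dataset characterization: per-class length histograms, class-wise
# residue-composition comparison with Benjamini-Hochberg correction, and
# positional (terminal-window) enrichment in the two-sample-logo style.

#' Per-class peptide length distribution
#'
#' @param x labeled [PeptideSet-class].
#' @param minLen,maxLen histogram range (defaults 8-25).
#' @return data.frame `length`, `positive`, `negative` with one row per
#'   length in the range; class columns sum to the class sizes when all
#'   lengths fall inside the range.
#' @export
lengthDistribution <- function(x, minLen = 8L, maxLen = 25L) {
  labs <- peptideLabels(x)
  w <- Biostrings::width(x@sequences)
  lens <- seq.int(minLen, maxLen)
  cnt <- function(cls) {
    tab <- table(factor(w[which(labs == cls)], levels = lens))
    as.integer(tab)
  }
  data.frame(length = lens, positive = cnt("positive"),
             negative = cnt("negative"))
}

# two-sample test with degenerate-input handling: identical constant
# groups give p = 1; constant but different groups give p = 0
safeTwoSampleP <- function(a, b, test = c("mann-whitney", "t")) {
  test <- match.arg(test)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  if (test == "t") {
    if (stats::sd(c(a, b)) == 0) return(1)
    stats::t.test(a, b)$p.value
  } else {
    stats::wilcox.test(a, b, exact = FALSE)$p.value
  }
}

#' Class-wise amino-acid composition comparison
#'
#' Compares the per-sequence composition (percent, as [computeAAC()]) of
#' each residue between positive and negative sets, one test per residue
#' (Mann-Whitney U by default, Welch t selectable), with Benjamini-Hochberg
#' step-up correction across the 20 tests. Sequences are the sampling
#' units.
#'
#' @param pos,neg [PeptideSet-class] objects (>= 2 sequences each).
#' @param test `"mann-whitney"` (default) or `"t"`.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return data.frame with one row per residue: `residue`, `mean_pos`,
#'   `mean_neg`, `diff`, `p`, `p_adj`, `significant`.
#' @export
compositionComparison <- function(pos, neg, test = c("mann-whitney", "t"),
                                  alpha = 0.05) {
  test <- match.arg(test)
  stopifnot(length(pos) >= 2, length(neg) >= 2)
  mp <- computeFeatures(pos, "AAC")
  mn <- computeFeatures(neg, "AAC")
  p <- vapply(seq_len(20), function(j)
    safeTwoSampleP(mp[, j], mn[, j], test), numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(
    residue = AA_ALPHABET20,
    mean_pos = colMeans(mp), mean_neg = colMeans(mn),
    diff = colMeans(mp) - colMeans(mn),
    p = p, p_adj = p_adj, significant = p_adj < alpha,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Positional residue enrichment over terminal windows
#'
#' Two-sample-logo-style analysis: for each of the first `nTerm` positions
#' (N1..N8) and last `cTerm` positions (C1..C8) and each residue, the 0/1
#' residue indicator per sequence is compared between classes with a
#' two-sample t-test. Positions beyond a short peptide's span are skipped
#' for that sequence. Cells with p below `alpha` are flagged enriched
#' (higher indicator mean in positives) or depleted.
#'
#' @param pos,neg [PeptideSet-class] objects.
#' @param nTerm,cTerm terminal window sizes (default 8 each).
#' @param alpha significance level (default 0.05).
#' @return data.frame with up to `(nTerm + cTerm) * 20` rows: `position`
#'   (`N1..C8`), `residue`, `freq_pos`, `freq_neg`, `diff`, `p`, `flag`
#'   (`enriched`/`depleted`/`ns`).
#' @export
positionalEnrichment <- function(pos, neg, nTerm = 8L, cTerm = 8L,
                                 alpha = 0.05) {
  stopifnot(length(pos) >= 1, length(neg) >= 1)
  resAt <- function(seqs, posname) {
    # residue at a terminal position, NA when out of span
    idx <- as.integer(substring(posname, 2))
    vapply(seqs, function(s) {
      L <- nchar(s)
      i <- if (startsWith(posname, "N")) idx else L - (cTerm - idx)
      if (i >= 1 && i <= L) substring(s, i, i) else NA_character_
    }, character(1))
  }
  sp <- peptideSequences(pos)
  sn <- peptideSequences(neg)
  positions <- c(paste0("N", seq_len(nTerm)), paste0("C", seq_len(cTerm)))
  out <- list()
  for (pn in positions) {
    rp <- resAt(sp, pn); rn <- resAt(sn, pn)
    rp <- rp[!is.na(rp)]; rn <- rn[!is.na(rn)]
    if (length(rp) == 0 || length(rn) == 0) next
    for (a in AA_ALPHABET20) {
      ip <- as.numeric(rp == a); inn <- as.numeric(rn == a)
      pval <- safeTwoSampleP(ip, inn, "t")
      d <- mean(ip) - mean(inn)
      flag <- if (pval < alpha) (if (d > 0) "enriched" else "depleted") else "ns"
      out[[length(out) + 1L]] <- data.frame(
        position = pn, residue = a, freq_pos = mean(ip),
        freq_neg = mean(inn), diff = d, p = pval, flag = flag,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
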