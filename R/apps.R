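# The four user-facing workflows: batch prediction, single-residue mutant
# design, overlapping protein-window scanning and motif scanning. All are
# pure functions of their inputs (plus the fitted model), so repeated runs
# are byte-identical. Machine-readable coordinates are 0-based half-open;
# the human-readable columns (pos1 etc.) are 1-based inclusive.

#' Predict IL-2 induction for a peptide set
#'
#' Scores every record with the model, applies the hybrid motif adjustment
#' and emits one prediction row per input in input order. Records outside
#' the model's supported length range (8-25 by default) are still scored
#' but flagged in the `warning` column.
#'
#' @param x [PeptideSet-class] of query peptides.
#' @param model a [PeptideClassifier-class].
#' @param posMotifs,negMotifs motif tables (see [hybridScore()]).
#' @param threshold decision threshold on the final score.
#' @param minLen,maxLen supported length range for the warning flag.
#' @return data.frame: `id`, `sequence`, `base_prob`, `pos_motif_hit`,
#'   `neg_motif_hit`, `final_score`, `call`, `warning`.
#' @export
predictPeptides <- function(x, model, posMotifs = NULL, negMotifs = NULL,
                            threshold = 0.5, minLen = 8L, maxLen = 25L) {
  if (length(x) == 0) stop("empty input")
  base_prob <- predictProbability(model, x)
  seqs <- peptideSequences(x)
  rows <- lapply(seq_along(seqs), function(i)
    hybridScore(seqs[[i]], base_prob[i], posMotifs, negMotifs, threshold,
                id = peptideIds(x)[i]))
  out <- do.call(rbind, rows)
  L <- nchar(out$sequence)
  out$warning <- ifelse(L < minLen | L > maxLen,
                        sprintf("length %d outside supported range %d-%d",
                                L, minLen, maxLen), "")
  rownames(out) <- NULL
  out
}

#' Design single-residue mutants of a peptide
#'
#' Enumerates the parent and all `19 * L` single-residue substitutions
#' (indels excluded), hybrid-scores each, and ranks them by final score
#' descending; ties are broken by (position, mutant residue) for
#' reproducibility. Rank 1 is the highest score.
#'
#' @param sequence parent peptide.
#' @inheritParams predictPeptides
#' @return data.frame with `19 * L + 1` rows: `position` (0-based; `NA`
#'   for the parent), `pos1` (1-based), `wild`, `mutant`, `sequence`,
#'   `base_prob`, `final_score`, `call`, `rank`.
#' @export
designMutants <- function(sequence, model, posMotifs = NULL,
                          negMotifs = NULL, threshold = 0.5) {
  r <- seqToResidues(sequence)
  L <- length(r)
  muts <- list(data.frame(position = NA_integer_, wild = NA_character_,
                          mutant = NA_character_, sequence = sequence,
                          stringsAsFactors = FALSE))
  for (i in seq_len(L)) {
    for (a in setdiff(AA_ALPHABET20, r[i])) {
      s <- r; s[i] <- a
      muts[[length(muts) + 1L]] <- data.frame(
        position = i - 1L, wild = r[i], mutant = a,
        sequence = paste(s, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, muts)
  ps <- PeptideSet(tab$sequence, ids = sprintf("m%04d", seq_len(nrow(tab))))
  pred <- predictPeptides(ps, model, posMotifs, negMotifs, threshold,
                          minLen = 1L, maxLen = .Machine$integer.max)
  tab$base_prob <- pred$base_prob
  tab$final_score <- pred$final_score
  tab$call <- pred$call
  # ties by (position, mutant) lexicographic; parent (NA position) first
  ord <- order(-tab$final_score,
               ifelse(is.na(tab$position), -1L, tab$position),
               tab$mutant, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- cumsum(!duplicated(round(-tab$final_score, 12)))
  tab$pos1 <- tab$position + 1L
  rownames(tab) <- NULL
  tab[, c("position", "pos1", "wild", "mutant", "sequence", "base_prob",
          "final_score", "call", "rank")]
}

#' Scan a protein for IL-2 inducing regions
#'
#' Slides a window of length `window` along the protein at offsets
#' `0, step, 2*step, ...` while the window fits, hybrid-scores every
#' fragment, and (optionally) aggregates a per-residue score as the mean of
#' the windows covering each residue.
#'
#' @param sequence protein sequence (length >= `window`).
#' @param window fragment length (default 15, the modal inducer length).
#' @param step offset increment (default 1 = fully overlapping).
#' @inheritParams predictPeptides
#' @param perResidue also return the per-residue mean score profile.
#' @return data.frame of `floor((L - window)/step) + 1` fragments:
#'   `start` (0-based), `end` (exclusive), `start1`, `end1` (1-based
#'   inclusive), `sequence`, `base_prob`, `final_score`, `call`; with
#'   `perResidue = TRUE`, a list `(fragments, residue_profile)`.
#' @export
scanProtein <- function(sequence, model, window = 15L, step = 1L,
                        posMotifs = NULL, negMotifs = NULL,
                        threshold = 0.5, perResidue = FALSE) {
  r <- seqToResidues(sequence)
  L <- length(r)
  if (window > L) stop("window exceeds protein length")
  stopifnot(step >= 1)
  starts <- seq.int(0L, L - window, by = step)
  frags <- vapply(starts, function(s)
    paste(r[(s + 1):(s + window)], collapse = ""), character(1))
  ps <- PeptideSet(frags, ids = sprintf("f%04d", seq_along(frags)))
  pred <- predictPeptides(ps, model, posMotifs, negMotifs, threshold)
  out <- data.frame(start = starts, end = starts + window,
                    start1 = starts + 1L, end1 = starts + window,
                    sequence = frags, base_prob = pred$base_prob,
                    final_score = pred$final_score, call = pred$call,
                    stringsAsFactors = FALSE)
  if (!perResidue) return(out)
  prof <- vapply(seq_len(L), function(i) {
    cover <- out$start < i & out$end >= i
    if (any(cover)) mean(out$final_score[cover]) else NA_real_
  }, numeric(1))
  list(fragments = out,
       residue_profile = data.frame(position = seq_len(L) - 1L,
                                    residue = r, mean_score = prof))
}

#' Scan a sequence against inducer and non-inducer motif lists
#'
#' Reports every hit from both lists (overlaps included) with its class
#' attribution.
#'
#' @param sequence query peptide or protein.
#' @param posMotifs,negMotifs motif tables or character vectors.
#' @return data.frame: `start`, `end` (0-based half-open), `start1`,
#'   `end1`, `motif`, `class` (`inducer-motif`/`non-inducer-motif`); zero
#'   rows (with header) when nothing matches.
#' @export
motifScan <- function(sequence, posMotifs = NULL, negMotifs = NULL) {
  scanOne <- function(motifs, cls) {
    if (is.null(motifs)) return(NULL)
    if (is.character(motifs))
      motifs <- data.frame(motif = motifs, scheme = "NONE",
                           stringsAsFactors = FALSE)
    if (nrow(motifs) == 0) return(NULL)
    hits <- lapply(seq_len(nrow(motifs)), function(k)
      matchMotif(sequence, motifs$motif[k], motifs$scheme[k]))
    hits <- do.call(rbind, hits)
    if (nrow(hits) == 0) return(NULL)
    hits$class <- cls
    hits
  }
  out <- rbind(scanOne(posMotifs, "inducer-motif"),
               scanOne(negMotifs, "non-inducer-motif"))
  if (is.null(out))
    out <- data.frame(start = integer(0), end = integer(0),
                      motif = character(0), class = character(0),
                      stringsAsFactors = FALSE)
  out$start1 <- out$start + 1L
  out$end1 <- out$end
  rownames(out) <- NULL
  out[order(out$start, out$end, out$motif),
      c("start", "end", "start1", "end1", "motif", "class"), drop = FALSE]
}
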