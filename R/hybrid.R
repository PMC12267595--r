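# Hybrid scoring: the model probability is adjusted by motif evidence —
# +0.5 when any inducer motif matches, -0.5 when any non-inducer motif
# matches — and clamped to [0, 1] so it can still be read as a probability.
# Any-hit semantics: multiple matches from one list do not stack.

motifHitFlag <- function(sequence, motifs) {
  if (is.null(motifs) || (is.data.frame(motifs) && nrow(motifs) == 0) ||
      length(motifs) == 0) return(FALSE)
  if (is.character(motifs))
    motifs <- data.frame(motif = motifs, scheme = "NONE",
                         stringsAsFactors = FALSE)
  for (k in seq_len(nrow(motifs)))
    if (nrow(matchMotif(sequence, motifs$motif[k], motifs$scheme[k])) > 0)
      return(TRUE)
  FALSE
}

#' Motif-adjusted hybrid score
#'
#' `final = clamp(base + 0.5 * posHit - 0.5 * negHit, 0, 1)`; the class
#' call is `inducer` when the final score reaches `threshold`.
#'
#' @param sequence peptide sequence.
#' @param baseProb model probability in \[0, 1\].
#' @param posMotifs,negMotifs inducer / non-inducer motif tables (as from
#'   [mineMotifs()]) or character vectors; `NULL` or empty disables that
#'   adjustment.
#' @param threshold decision threshold on the final score (default 0.5).
#' @param clamp clamp the adjusted score to \[0, 1\] (default); with
#'   `FALSE` the raw adjusted value is kept.
#' @param id record id for the output row.
#' @return one-row data.frame: `id`, `sequence`, `base_prob`,
#'   `pos_motif_hit`, `neg_motif_hit`, `final_score`, `call`.
#' @examples
#' hybridScore("KKALEGKK", 0.4, posMotifs = "A L E G")$final_score  # 0.9
#' @export
hybridScore <- function(sequence, baseProb, posMotifs = NULL,
                        negMotifs = NULL, threshold = 0.5, clamp = TRUE,
                        id = NA_character_) {
  stopifnot(baseProb >= 0, baseProb <= 1)
  pos_hit <- motifHitFlag(sequence, posMotifs)
  neg_hit <- motifHitFlag(sequence, negMotifs)
  final <- baseProb + 0.5 * pos_hit - 0.5 * neg_hit
  if (clamp) final <- min(1, max(0, final))
  data.frame(id = id, sequence = sequence, base_prob = baseProb,
             pos_motif_hit = pos_hit, neg_motif_hit = neg_hit,
             final_score = final,
             call = ifelse(final >= threshold, "inducer", "non-inducer"),
             stringsAsFactors = FALSE)
}

#' Evaluate the hybrid scorer on a labeled test set
#'
#' Scores every test peptide with the base model, applies the motif
#' adjustment, and reports metrics for both the hybrid and the base scores
#' (so the delta is visible). When the hit flags never fire (empty motif
#' lists, or motifs matching everything in both lists) the hybrid scores
#' equal the base scores exactly. If any motif was mined on a test sequence
#' the function warns about leakage.
#'
#' @param test labeled [PeptideSet-class].
#' @param model a [PeptideClassifier-class].
#' @param posMotifs,negMotifs motif tables as in [hybridScore()].
#' @param threshold decision threshold.
#' @return list with `hybrid` and `base` ([classMetrics()] lists) and
#'   `predictions` (per-peptide data.frame).
#' @export
evaluateHybrid <- function(test, model, posMotifs = NULL, negMotifs = NULL,
                           threshold = 0.5) {
  base_prob <- predictProbability(model, test)
  seqs <- peptideSequences(test)
  rows <- lapply(seq_along(seqs), function(i)
    hybridScore(seqs[[i]], base_prob[i], posMotifs, negMotifs, threshold,
                id = peptideIds(test)[i]))
  pred <- do.call(rbind, rows)
  labs <- peptideLabels(test)
  list(
    hybrid = classMetrics(scores = pred$final_score, labels = labs,
                          threshold = threshold),
    base = classMetrics(scores = pred$base_prob, labels = labs,
                        threshold = threshold),
    predictions = pred)
}

#' Flag motif/test leakage
#'
#' Warns when any motif in `motifs` was mined from (i.e. occurs in) the
#' held-out sequences used for evaluation — a check that motif lists were
#' built on training data only cannot be automated, but full containment of
#' the test set in the mining input can be detected when the mining input
#' is supplied.
#'
#' @param motifs motif table.
#' @param miningInput [PeptideSet-class] the motifs were mined from.
#' @param test [PeptideSet-class] used for evaluation.
#' @return `TRUE` (invisibly) when leakage was detected.
#' @export
checkMotifLeakage <- function(motifs, miningInput, test) {
  leak <- intersect(peptideSequences(miningInput), peptideSequences(test))
  if (length(leak) > 0) {
    warning("motif mining input shares ", length(leak),
            " sequence(s) with the evaluation set")
    return(invisible(TRUE))
  }
  invisible(FALSE)
}
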