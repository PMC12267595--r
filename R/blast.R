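# Similarity-based annotation via the NCBI blast+ short-peptide protein
# search (makeblastdb / blastp -task blastp-short). An optional,
# external-tool-backed alternative to the model-based predictor: each query
# inherits the label of its best database hit.

blastAvailable <- function() {
  nzchar(Sys.which("blastp")) && nzchar(Sys.which("makeblastdb"))
}

#' Annotate peptides by similarity search
#'
#' Builds a protein BLAST database from the labeled `db` peptides, searches
#' every `query` peptide with `blastp -task blastp-short` at the given
#' e-value cutoff, drops self-hits (query id equal to subject id), and
#' assigns each query the label of its first remaining hit (BLAST hit
#' order: best first) or `"no hit"`. When queries are labeled, hits are
#' tabulated as correct/incorrect positive/negative calls and summarized
#' with [classMetrics()] (TP = correct positive hits, FP = incorrect
#' positive hits, TN = correct negative, FN = incorrect negative).
#'
#' @param query [PeptideSet-class] of query peptides.
#' @param db labeled [PeptideSet-class] used as the search database.
#' @param evalue e-value cutoff (e.g. `1e-3`).
#' @return list with `annotations` (data.frame `id`, `hit_id`, `call`),
#'   `counts` (correct/incorrect positive/negative hit counts plus
#'   `total_hits` and `no_hit`), and `metrics` (`NULL` when queries are
#'   unlabeled).
#' @export
similarityAnnotate <- function(query, db, evalue = 1e-3) {
  if (!blastAvailable())
    stop("NCBI blast+ not found on PATH; install blast+ (makeblastdb, ",
         "blastp) to use similarity annotation")
  if (anyNA(peptideLabels(db))) stop("db must be fully labeled")
  wd <- tempfile("il2blast")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  dbf <- file.path(wd, "db.fasta")
  qf <- file.path(wd, "query.fasta")
  writePeptideFasta(db, dbf)
  writePeptideFasta(query, qf)
  st <- system2(Sys.which("makeblastdb"),
                c("-in", dbf, "-dbtype", "prot"),
                stdout = FALSE, stderr = FALSE)
  if (st != 0) stop("makeblastdb failed")
  outf <- file.path(wd, "hits.tsv")
  st <- system2(Sys.which("blastp"),
                c("-task", "blastp-short", "-query", qf, "-db", dbf,
                  "-evalue", format(evalue, scientific = TRUE),
                  "-outfmt", "6", "-out", outf),
                stdout = FALSE, stderr = FALSE)
  if (st != 0) stop("blastp failed")
  hits <- if (file.info(outf)$size > 0)
    utils::read.table(outf, sep = "\t", stringsAsFactors = FALSE)[, 1:2]
  else data.frame(V1 = character(0), V2 = character(0))
  names(hits) <- c("qid", "sid")
  hits <- hits[hits$qid != hits$sid, , drop = FALSE]
  first <- hits[!duplicated(hits$qid), , drop = FALSE]

  db_lab <- stats::setNames(as.character(peptideLabels(db)), peptideIds(db))
  ann <- data.frame(id = peptideIds(query), hit_id = NA_character_,
                    call = "no hit", stringsAsFactors = FALSE)
  m <- match(ann$id, first$qid)
  found <- !is.na(m)
  ann$hit_id[found] <- first$sid[m[found]]
  ann$call[found] <- unname(db_lab[ann$hit_id[found]])

  qlab <- as.character(peptideLabels(query))
  counts <- list(
    correct_positive = sum(found & ann$call == "positive" & qlab == "positive",
                           na.rm = TRUE),
    incorrect_positive = sum(found & ann$call == "positive" & qlab == "negative",
                             na.rm = TRUE),
    correct_negative = sum(found & ann$call == "negative" & qlab == "negative",
                           na.rm = TRUE),
    incorrect_negative = sum(found & ann$call == "negative" & qlab == "positive",
                             na.rm = TRUE),
    total_hits = sum(found),
    no_hit = sum(!found))
  metrics <- NULL
  if (!anyNA(qlab) && counts$total_hits > 0)
    metrics <- classMetrics(list(TP = counts$correct_positive,
                                 FP = counts$incorrect_positive,
                                 TN = counts$correct_negative,
                                 FN = counts$incorrect_negative))
  list(annotations = ann, counts = counts, metrics = metrics)
}
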