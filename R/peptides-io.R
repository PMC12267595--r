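#' Read peptides from a FASTA file
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file into a
#' [PeptideSet-class]. Record ids are the header token up to the first
#' whitespace; sequences are uppercased. In strict mode (default) any record
#' containing a residue outside the 20 canonical letters is an error; in
#' lenient mode such records are dropped with a warning.
#'
#' @param path path to a FASTA file.
#' @param labels optional label vector (recycled encodings as in
#'   [PeptideSet()]), e.g. when reading a single-class file.
#' @param strict reject (`TRUE`) or drop (`FALSE`) records with
#'   non-canonical residues (B, J, O, U, X, Z, ...).
#' @return a [PeptideSet-class]; provenance records the file path.
#' @export
readPeptideFasta <- function(path, labels = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0) stop("no records in FASTA file: ", path)
  seqs <- toupper(as.character(aas))
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1L)
  names(seqs) <- ids
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET20, collapse = "")), seqs)
  if (any(bad)) {
    if (strict)
      stop(sum(bad), " record(s) contain non-canonical residues ",
           "(use strict = FALSE to drop them): ",
           paste(utils::head(ids[bad], 5), collapse = ", "))
    warning("dropping ", sum(bad), " record(s) with non-canonical residues")
    seqs <- seqs[!bad]
    if (!is.null(labels) && length(labels) == length(bad))
      labels <- labels[!bad]
    if (length(seqs) == 0) stop("no records left after dropping")
  }
  if (!is.null(labels) && length(labels) == 1)
    labels <- rep(labels, length(seqs))
  PeptideSet(seqs, labels = labels, provenance = path)
}

#' Read a labeled peptide dataset from CSV
#'
#' Expects the dialect `id,sequence,label` with label coded 1 (inducer) or
#' 0 (non-inducer); a missing/empty label yields an unlabeled record.
#'
#' @inheritParams readPeptideFasta
#' @return a [PeptideSet-class].
#' @export
readPeptideCSV <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sequence", "label")
  if (!all(need[1:2] %in% names(df)))
    stop("CSV must have columns id,sequence[,label]")
  if (nrow(df) == 0) stop("no records in CSV file: ", path)
  seqs <- toupper(df$sequence)
  labels <- if ("label" %in% names(df)) df$label else NULL
  if (!is.null(labels)) labels[labels %in% c("", NA)] <- NA
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET20, collapse = "")), seqs)
  if (any(bad)) {
    if (strict) stop(sum(bad), " record(s) contain non-canonical residues")
    warning("dropping ", sum(bad), " record(s) with non-canonical residues")
    df <- df[!bad, , drop = FALSE]
    seqs <- seqs[!bad]
    if (!is.null(labels)) labels <- labels[!bad]
  }
  PeptideSet(seqs, labels = if (is.null(labels)) NULL else as.numeric(labels),
             ids = as.character(df$id), provenance = path)
}

#' Write a peptide set
#'
#' `writePeptideFasta` writes one FASTA file (optionally a single class);
#' `writePeptideCSV` writes the `id,sequence,label` dialect with labels
#' coded 1/0 (empty when unlabeled).
#'
#' @param x a [PeptideSet-class]
#' @param path output file path
#' @param class optional class filter (`"positive"`/`"negative"`) for FASTA.
#' @return `path`, invisibly.
#' @export
writePeptideFasta <- function(x, path, class = NULL) {
  if (!is.null(class)) x <- x[which(peptideLabels(x) == class)]
  Biostrings::writeXStringSet(x@sequences, filepath = path)
  invisible(path)
}

#' @rdname writePeptideFasta
#' @export
writePeptideCSV <- function(x, path) {
  lab <- as.integer(peptideLabels(x) == "positive")
  lab <- ifelse(is.na(lab), "", as.character(lab))
  utils::write.csv(
    data.frame(id = peptideIds(x), sequence = unname(peptideSequences(x)),
               label = lab, stringsAsFactors = FALSE),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Curate a peptide set
#'
#' Applies the dataset curation rules: remove peptides with length outside
#' `[minLen, maxLen]`, then remove redundant peptides (exact sequence
#' identity; first occurrence kept). A sequence appearing with both class
#' labels is a label conflict and is dropped entirely. The curation report
#' (input/removed/retained counts per rule) is attached to the result and
#' retrievable with [curationReport()].
#'
#' @param x a [PeptideSet-class]
#' @param minLen,maxLen inclusive length bounds (defaults 8 and 25, the
#'   range suitable for MHC antigen processing).
#' @return the curated [PeptideSet-class] (possibly empty, with a warning).
#' @examples
#' ps <- PeptideSet(c(a = "ACDEFGH", b = "ACDEFGHK", c = "ACDEFGHK"),
#'                  labels = c(1, 1, 0))
#' curationReport(curatePeptides(ps))
#' @export
curatePeptides <- function(x, minLen = 8L, maxLen = 25L) {
  stopifnot(minLen >= 1, maxLen >= minLen)
  n_input <- length(x)
  w <- Biostrings::width(x@sequences)
  keep_len <- w >= minLen & w <= maxLen
  n_len <- sum(!keep_len)
  y <- x[which(keep_len)]

  seqs <- peptideSequences(y)
  labs <- peptideLabels(y)
  # label conflicts: same sequence seen with both classes
  tab <- split(as.character(labs), seqs)
  conflict_seqs <- names(tab)[vapply(tab, function(l) {
    u <- unique(l[!is.na(l)])
    length(u) > 1
  }, logical(1))]
  is_conflict <- seqs %in% conflict_seqs
  n_conflict <- length(conflict_seqs)
  n_conflict_records <- sum(is_conflict)
  y <- y[which(!is_conflict)]

  seqs <- peptideSequences(y)
  dup <- duplicated(seqs)
  n_dup <- sum(dup)
  y <- y[which(!dup)]

  report <- list(
    n_input = n_input,
    n_removed_length = n_len,
    n_conflict_sequences = n_conflict,
    n_removed_conflict = n_conflict_records,
    n_removed_duplicate = n_dup,
    n_retained = length(y),
    min_len = as.integer(minLen),
    max_len = as.integer(maxLen),
    empty = length(y) == 0
  )
  if (report$empty && n_input > 0)
    warning("curation removed every record")
  y@metadata$curation <- report
  y
}

#' Write a curation report as CSV
#'
#' @param report list returned by [curationReport()]
#' @param path output file
#' @export
writeCurationReport <- function(report, path) {
  df <- data.frame(rule = names(report), value = unlist(lapply(report, as.character)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a peptide set into training and held-out sets
#'
#' Holds out `round(ratio * N)` records (nearest integer, ties to even as in
#' base [round()]); the rest form the training set. With `stratified = TRUE`
#' (default) class proportions are preserved within rounding, allocating
#' per-class test counts by largest remainder so the total is exact. The
#' partition is reproducible for a given seed.
#'
#' @param x a labeled (if `stratified`) [PeptideSet-class]
#' @param ratio held-out fraction, in (0, 1); default 0.2 (an 80:20 split).
#' @param seed integer RNG seed (default 42).
#' @param stratified preserve class proportions.
#' @return a [PeptideSplit-class].
#' @examples
#' ps <- generatePeptides(syntheticConfig(nPos = 30, nNeg = 20, seed = 1))
#' splitPeptides(ps, ratio = 0.2, seed = 42)
#' @export
splitPeptides <- function(x, ratio = 0.2, seed = 42L, stratified = TRUE) {
  stopifnot(ratio > 0, ratio < 1)
  n <- length(x)
  if (n < 2) stop("need at least 2 records to split")
  labs <- peptideLabels(x)
  if (stratified && anyNA(labs))
    stop("stratified split requires a fully labeled dataset")
  n_test <- round(ratio * n)

  idx_test <- withSeed(seed, {
    if (stratified) {
      classes <- split(seq_len(n), labs)
      sizes <- vapply(classes, length, integer(1))
      exact <- ratio * sizes
      base <- floor(exact)
      rem <- n_test - sum(base)
      if (rem > 0) {
        extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      } else if (rem < 0) {
        cut <- order(exact - base)[seq_len(-rem)]
        base[cut] <- base[cut] - 1
      }
      unlist(mapply(function(ix, k) sample(ix, k), classes, base,
                    SIMPLIFY = FALSE), use.names = FALSE)
    } else {
      sample(seq_len(n), n_test)
    }
  })
  idx_test <- sort(idx_test)
  idx_train <- setdiff(seq_len(n), idx_test)
  new("PeptideSplit",
      train = x[idx_train], test = x[idx_test],
      ratio = ratio, seed = as.integer(seed))
}

# evaluate expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
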