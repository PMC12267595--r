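#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
NULL

# canonical 20-letter amino-acid alphabet, alphabetical order
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Labeled peptide set
#'
#' An S4 container for a collection of peptide sequences with optional binary
#' class labels (IL-2 inducer = `"positive"`, non-inducer = `"negative"`).
#' Sequences are stored as a [Biostrings::AAStringSet] restricted to the 20
#' canonical amino-acid letters; labels are a factor aligned with the
#' sequences (`NA` for unlabeled records).
#'
#' @slot sequences [Biostrings::AAStringSet] of peptide sequences; names are
#'   the record identifiers.
#' @slot labels factor with levels `negative`, `positive`, one entry per
#'   sequence; may contain `NA`.
#' @slot provenance free-text description of where the records came from.
#' @slot metadata list for bookkeeping (e.g. the curation report).
#'
#' @seealso [PeptideSet()], [curatePeptides()], [splitPeptides()]
#' @export
setClass("PeptideSet",
  representation(
    sequences = "AAStringSet",
    labels = "factor",
    provenance = "character",
    metadata = "list"
  ),
  prototype(
    provenance = "",
    metadata = list()
  )
)

setValidity("PeptideSet", function(object) {
  msgs <- character(0)
  n <- length(object@sequences)
  if (length(object@labels) != n)
    msgs <- c(msgs, "labels must have one entry per sequence")
  if (!identical(levels(object@labels), c("negative", "positive")))
    msgs <- c(msgs, "labels must be a factor with levels negative, positive")
  if (n > 0) {
    if (any(Biostrings::width(object@sequences) < 1))
      msgs <- c(msgs, "sequences must be non-empty")
    seqs <- as.character(object@sequences)
    bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET20, collapse = "")), seqs)
    if (any(bad))
      msgs <- c(msgs, sprintf(
        "%d sequence(s) contain non-canonical residues (allowed: %s)",
        sum(bad), paste(AA_ALPHABET20, collapse = "")))
    if (is.null(names(object@sequences)) || anyNA(names(object@sequences)))
      msgs <- c(msgs, "all records must have an id")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PeptideSet
#'
#' @param sequences character vector of peptide sequences (uppercased
#'   internally) or an [Biostrings::AAStringSet].
#' @param labels optional vector of class labels; accepted encodings are
#'   `"positive"`/`"negative"`, `1`/`0`, or `TRUE`/`FALSE`; `NA` marks an
#'   unlabeled record.
#' @param ids character vector of record identifiers; defaults to the names
#'   of `sequences` or `pep1..pepN`.
#' @param provenance free-text provenance note.
#'
#' @return A [PeptideSet-class] object.
#' @examples
#' ps <- PeptideSet(c(p1 = "ACDEFGHIKL", p2 = "LLLLAAAAKK"),
#'                  labels = c(1, 0))
#' nPositive(ps)
#' @export
PeptideSet <- function(sequences, labels = NULL, ids = NULL, provenance = "") {
  if (is(sequences, "AAStringSet")) {
    seqchr <- as.character(sequences)
  } else {
    nm <- names(sequences)
    seqchr <- toupper(as.character(sequences))  # toupper drops names
    names(seqchr) <- nm
  }
  n <- length(seqchr)
  if (is.null(ids)) {
    ids <- names(seqchr)
    if (is.null(ids))
      ids <- if (n == 0) character(0) else paste0("pep", seq_len(n))
  }
  if (length(ids) != n) stop("ids must have one entry per sequence")
  names(seqchr) <- ids
  lab <- normalizeLabels(labels, n)
  new("PeptideSet",
      sequences = Biostrings::AAStringSet(seqchr),
      labels = lab, provenance = provenance, metadata = list())
}

normalizeLabels <- function(labels, n) {
  lev <- c("negative", "positive")
  if (is.null(labels)) return(factor(rep(NA_character_, n), levels = lev))
  if (length(labels) != n)
    stop("labels must have length ", n)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- ifelse(labels, "positive", "negative")
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1, NA)))
      stop("numeric labels must be 0/1")
    labels <- c("negative", "positive")[labels + 1L]
  }
  labels <- tolower(as.character(labels))
  labels[labels %in% c("1", "pos", "inducer")] <- "positive"
  labels[labels %in% c("0", "neg", "non-inducer")] <- "negative"
  if (!all(labels %in% c(lev, NA)))
    stop("labels must encode positive/negative (or 1/0)")
  factor(labels, levels = lev)
}

#' Train/test split of a peptide set
#'
#' @slot train,test [PeptideSet-class] partitions.
#' @slot ratio fraction of records held out in `test`.
#' @slot seed integer seed that produced the partition.
#' @export
setClass("PeptideSplit",
  representation(train = "PeptideSet", test = "PeptideSet",
                 ratio = "numeric", seed = "integer"))

setValidity("PeptideSplit", function(object) {
  if (object@ratio <= 0 || object@ratio >= 1)
    return("ratio must be in (0, 1)")
  if (length(intersect(peptideSequences(object@train),
                       peptideSequences(object@test))) > 0)
    return("train and test share sequences")
  TRUE
})

#' @describeIn PeptideSet-class number of records
#' @param x a `PeptideSet`
#' @export
setMethod("length", "PeptideSet", function(x) length(x@sequences))

#' Accessors for PeptideSet
#'
#' `peptideIds`, `peptideSequences` and `peptideLabels` return the record
#' identifiers, plain-character sequences and label factor; `nPositive` and
#' `nNegative` count labeled records per class; `curationReport` returns the
#' report attached by [curatePeptides()] (or `NULL`).
#'
#' @param x a [PeptideSet-class]
#' @return vectors aligned with the record order.
#' @name peptide-accessors
NULL

#' @rdname peptide-accessors
#' @export
peptideIds <- function(x) names(x@sequences)

#' @rdname peptide-accessors
#' @export
peptideSequences <- function(x) {
  s <- as.character(x@sequences)
  names(s) <- names(x@sequences)
  s
}

#' @rdname peptide-accessors
#' @export
peptideLabels <- function(x) x@labels

#' @rdname peptide-accessors
#' @export
nPositive <- function(x) sum(x@labels == "positive", na.rm = TRUE)

#' @rdname peptide-accessors
#' @export
nNegative <- function(x) sum(x@labels == "negative", na.rm = TRUE)

#' @rdname peptide-accessors
#' @export
curationReport <- function(x) x@metadata$curation

#' @describeIn PeptideSet-class subset records
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "PeptideSet", function(x, i, j, ..., drop = FALSE) {
  new("PeptideSet", sequences = x@sequences[i], labels = x@labels[i],
      provenance = x@provenance, metadata = x@metadata)
})

setMethod("show", "PeptideSet", function(object) {
  cat(sprintf("PeptideSet with %d record(s): %d positive, %d negative, %d unlabeled\n",
              length(object), nPositive(object), nNegative(object),
              sum(is.na(object@labels))))
  if (length(object) > 0) {
    w <- Biostrings::width(object@sequences)
    cat(sprintf("  lengths: %d-%d (median %g)\n", min(w), max(w),
                stats::median(w)))
  }
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "PeptideSplit", function(object) {
  cat(sprintf("PeptideSplit: %d train / %d test (ratio %.2f, seed %d)\n",
              length(object@train), length(object@test),
              object@ratio, object@seed))
})

#' @rdname peptide-accessors
#' @export
trainSet <- function(x) {
  stopifnot(is(x, "PeptideSplit"))
  x@train
}

#' @rdname peptide-accessors
#' @export
testSet <- function(x) {
  stopifnot(is(x, "PeptideSplit"))
  x@test
}
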