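# Programmatic fixtures shared across test files.

randomPeptides <- function(n, lmin = 8, lmax = 12, seed = 1, prefix = "r") {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(AA20, sample(lmin:lmax, 1), replace = TRUE), collapse = ""),
    character(1))
  PeptideSet(seqs, ids = sprintf("%s%03d", prefix, seq_len(n)))
}

writeTempFasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# small labeled set with a clean composition signal, for cheap model tests
signalPeptideSet <- function(nPerClass = 40, seed = 11) {
  generatePeptides(syntheticConfig(nPos = nPerClass, nNeg = nPerClass,
                                   seed = seed))
}

# one cached quick model (LASSO on AAC) reused by the app-workflow tests
.fixture_env <- new.env()
quickModel <- function() {
  if (is.null(.fixture_env$model)) {
    ps <- signalPeptideSet(60, seed = 21)
    m <- computeFeatures(ps, "AAC")
    .fixture_env$model <- trainModel(m, peptideLabels(ps), "LASSO", seed = 1)
  }
  .fixture_env$model
}
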