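test_that("classification schemes cover every residue", {
  none <- classificationScheme("NONE")
  expect_length(none$groups, 20)
  expect_true(all(lengths(none$groups) == 1))
  for (nm in c("BETTS-RUSSELL", "KOOLMAN")) {
    sch <- classificationScheme(nm)
    expect_true(all(AA20 %in% unlist(sch$groups)))
  }
})

test_that("motif matching reports all contiguous hits leftmost-first", {
  h <- matchMotif("KKALEGK", "A L E G")
  expect_equal(h$start, 2L)
  expect_equal(h$end, 6L)
  h <- matchMotif("ALEGALEG", c("A", "L", "E", "G"))
  expect_equal(h$start, c(0L, 4L))
  expect_equal(h$end, c(4L, 8L))
  # class symbol: L and V are hydrophobic under BETTS-RUSSELL
  h <- matchMotif("LEVE", c("hydrophobic", "E"), "BETTS-RUSSELL")
  expect_equal(h$start, c(0L, 2L))
  expect_equal(nrow(matchMotif("AAAA", "C")), 0L)
  expect_error(matchMotif("AAAA", "nope", "NONE"), "unknown")
})

test_that("mining recovers a shared exclusive motif and respects fp", {
  set.seed(31)
  mk <- function(core) vapply(1:10, function(i)
    paste0(paste(sample(c("K", "R", "H"), 4, TRUE), collapse = ""), core,
           paste(sample(c("K", "R", "H"), 3, TRUE), collapse = "")),
    character(1))
  pos <- PeptideSet(mk("ALEG"), ids = paste0("p", 1:10))
  neg <- PeptideSet(vapply(1:10, function(i)
    paste(sample(c("D", "T", "C", "S"), 10, TRUE), collapse = ""),
    character(1)), ids = paste0("n", 1:10))
  m0 <- mineMotifs(pos, neg, "NONE", fp = 0, minPos = 10, maxLen = 6)
  expect_true("A L E G" %in% m0$motif)
  row <- m0[m0$motif == "A L E G", ]
  expect_equal(row$pos_count, 10L)
  expect_equal(row$neg_count, 0L)
  # relaxing fp can only widen the result set
  m10 <- mineMotifs(pos, neg, "NONE", fp = 10, minPos = 10, maxLen = 6)
  expect_true(all(m0$motif %in% m10$motif))
})

test_that("positive support is anti-monotone under extension", {
  ps <- generatePeptides(syntheticConfig(nPos = 50, nNeg = 50, seed = 13))
  pos <- ps[which(peptideLabels(ps) == "positive")]
  neg <- ps[which(peptideLabels(ps) == "negative")]
  mined <- mineMotifs(pos, neg, "NONE", fp = 50, minPos = 5, maxLen = 5)
  counts <- stats::setNames(mined$pos_count, mined$motif)
  for (m in names(counts)) {
    syms <- strsplit(m, " ")[[1]]
    if (length(syms) < 2) next
    prefix <- paste(utils::head(syms, -1), collapse = " ")
    if (prefix %in% names(counts))
      expect_lte(counts[[m]], counts[[prefix]])
  }
})

test_that("swapping the class sets mines the negative-class motifs", {
  pos <- PeptideSet(rep("KKALEGKK", 5), ids = paste0("p", 1:5))
  neg <- PeptideSet(rep("DDTTCCDD", 5), ids = paste0("n", 1:5))
  fwd <- mineMotifs(pos, neg, "NONE", fp = 0, minPos = 5, maxLen = 4)
  rev <- mineMotifs(neg, pos, "NONE", fp = 0, minPos = 5, maxLen = 4)
  expect_true("A L E G" %in% fwd$motif)
  expect_true("D D T T" %in% rev$motif)
  expect_false(any(rev$motif %in% fwd$motif))
})

test_that("miner equals brute-force enumeration on tiny instances", {
  schemes <- c("NONE", "BETTS-RUSSELL", "KOOLMAN")
  for (i in 1:9) {
    scheme <- schemes[(i - 1) %% 3 + 1]
    set.seed(100 + i)
    pos <- vapply(1:6, function(k)
      paste(sample(AA20[1:8], sample(5:9, 1), TRUE), collapse = ""),
      character(1))
    neg <- vapply(1:6, function(k)
      paste(sample(AA20[5:14], sample(5:9, 1), TRUE), collapse = ""),
      character(1))
    fp <- sample(0:2, 1)
    minPos <- sample(2:3, 1)
    got <- mineMotifs(PeptideSet(pos, ids = paste0("p", 1:6)),
                      PeptideSet(neg, ids = paste0("n", 1:6)),
                      scheme, fp = fp, minPos = minPos, maxLen = 3)
    want <- oracleMineMotifs(pos, neg, scheme, fp, minPos, 3)
    got <- got[order(got$motif), c("motif", "pos_count", "neg_count")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("instance", i, scheme))
  }
})

test_that("window-derived oracle agrees with full exhaustive enumeration", {
  for (scheme in c("NONE", "KOOLMAN")) {
    set.seed(77)
    pos <- vapply(1:5, function(k)
      paste(sample(AA20[1:6], 6, TRUE), collapse = ""), character(1))
    neg <- vapply(1:5, function(k)
      paste(sample(AA20[4:10], 6, TRUE), collapse = ""), character(1))
    a <- oracleMineMotifs(pos, neg, scheme, fp = 1, minPos = 2, maxLen = 2)
    b <- oracleMineExhaustive(pos, neg, scheme, fp = 1, minPos = 2, maxLen = 2)
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
  }
})

test_that("motif coverage counts containing sequences per class", {
  empty <- PeptideSet(character(0))
  cov <- motifCoverage("A", empty)
  expect_equal(cov$pos_count, 0L)
  expect_equal(cov$neg_count, 0L)
  ds <- PeptideSet(c("AA", "CC"), labels = c(1, 0), ids = c("x", "y"))
  cov <- motifCoverage("A", ds)
  expect_equal(cov$pos_count, 1L)
  expect_equal(cov$neg_count, 0L)
  # coverage of mined motifs on the mining data equals the mined counts
  ps <- generatePeptides(syntheticConfig(nPos = 30, nNeg = 30, seed = 17))
  pos <- ps[which(peptideLabels(ps) == "positive")]
  neg <- ps[which(peptideLabels(ps) == "negative")]
  mined <- mineMotifs(pos, neg, "NONE", fp = 0, minPos = 10, maxLen = 5)
  top <- utils::head(mined, 10)
  cov <- motifCoverage(top, ps)
  expect_equal(cov$pos_count, top$pos_count)
  expect_equal(cov$neg_count, top$neg_count)
})

test_that("motif tables round-trip through CSV", {
  tab <- data.frame(motif = c("A L E G", "L E G S"), scheme = "NONE",
                    pos_count = c(103L, 104L), neg_count = c(0L, 0L),
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".csv")
  writeMotifCSV(tab, f)
  expect_equal(readMotifCSV(f), tab)
})
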