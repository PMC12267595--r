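test_that("amino-acid composition is a percentage vector summing to 100", {
  expect_equal(unname(computeAAC("AAAA")["AAC_A"]), 100)
  expect_true(all(computeAAC("AAAA")[-1] == 0))
  expect_equal(unname(computeAAC(paste(AA20, collapse = ""))),
               rep(5, 20))
  aac <- computeAAC("AC")
  expect_equal(unname(aac[c("AAC_A", "AAC_C")]), c(50, 50))
  for (s in peptideSequences(randomPeptides(10, seed = 6)))
    expect_equal(sum(computeAAC(s)), 100, tolerance = 1e-9)
  expect_error(computeAAC(""), "empty")
})

test_that("dipeptide composition counts overlapping adjacent pairs", {
  d <- computeDPC("AAAA")
  expect_equal(unname(d["DPC_AA"]), 100)
  d <- computeDPC("ACAC")
  expect_equal(unname(d["DPC_AC"]), 100 * 2 / 3)
  expect_equal(unname(d["DPC_CA"]), 100 * 1 / 3)
  dl <- computeDPC("ACAC", appendLength = TRUE)
  expect_length(dl, 401)
  expect_equal(unname(dl["LEN"]), 4)
  expect_error(computeDPC("A"), "length")
  for (s in peptideSequences(randomPeptides(10, seed = 7)))
    expect_equal(sum(computeDPC(s)), 100, tolerance = 1e-9)
})

test_that("dipeptide frequencies of a two-letter repeat match the closed form", {
  k <- 50
  s <- paste(rep(c("A", "C"), k), collapse = "")  # ACAC... length 100
  d <- computeDPC(s)
  # 2k-1 pairs: k of AC, k-1 of CA
  expect_equal(unname(d["DPC_AC"]), 100 * k / (2 * k - 1))
  expect_equal(unname(d["DPC_CA"]), 100 * (k - 1) / (2 * k - 1))
  expect_true(abs(d["DPC_AC"] - 50) < 1 && abs(d["DPC_CA"] - 50) < 1)
})

test_that("CTD has 147 entries with valid composition/transition structure", {
  v <- computeCTD("AAAA")
  expect_length(v, 147)
  comp <- v[grep("_C[123]$", names(v))]
  # per property the composition of A's group is 100, others 0
  expect_true(all(tapply(comp, rep(1:7, each = 3), max) == 100))
  expect_true(all(v[grep("_T(12|13|23)$", names(v))] == 0))
  # charge property of KKDD: single positive->negative transition among 3 pairs
  tr <- computeCTD("KKDD")[paste0("CTD_charge_T", c("12", "13", "23"))]
  expect_equal(unname(tr), c(0, 100 / 3, 0))
})

test_that("CTD compositions sum to 100 and distributions are monotone", {
  for (s in peptideSequences(randomPeptides(8, 8, 15, seed = 8))) {
    v <- computeCTD(s)
    comp <- v[grep("_C[123]$", names(v))]
    sums <- as.numeric(tapply(comp, rep(1:7, each = 3), sum))
    expect_equal(sums, rep(100, 7), tolerance = 1e-9)
    dist <- v[grep("_D[123]_", names(v))]
    expect_true(all(dist >= 0 & dist <= 100))
    # non-decreasing across first/25/50/75/100 within each property x group
    idx <- matrix(seq_along(dist), nrow = 5)
    for (col in seq_len(ncol(idx)))
      expect_true(all(diff(dist[idx[, col]]) >= -1e-12))
  }
})

test_that("terminal binary profile sets one bit per defined position", {
  v16 <- computeAAB(paste(rep("L", 16), collapse = ""))
  expect_length(v16, 320)
  expect_equal(sum(v16), 16)
  v <- computeAAB(paste(c(rep("A", 8), rep("C", 8)), collapse = ""))
  expect_true(all(v[paste0("AAB_N", 1:8, "_A")] == 1))
  expect_true(all(v[paste0("AAB_C", 1:8, "_C")] == 1))
  expect_equal(sum(v), 16)
  # 10-mer: N and C windows overlap, still 16 set bits
  expect_equal(sum(computeAAB("ACDEFGHIKL")), 16)
})

test_that("run and gap descriptors follow their stated formulas", {
  expect_equal(unname(computeRRI("AAAC")["RRI_A"]), 9 / 4)
  expect_equal(unname(computeRRI("AAAC")["RRI_C"]), 1 / 4)
  # ACACA: A at 1,3,5 -> gap sum 4; C at 2,4 -> gap sum 2; L = 5
  ddr <- computeDDR("ACACA")
  expect_equal(unname(ddr["DDR_A"]), 100 * 4 / 5)
  expect_equal(unname(ddr["DDR_C"]), 100 * 2 / 5)
  expect_equal(unname(ddr["DDR_D"]), 0)  # absent residue
  expect_equal(unname(computeDDR("AC")["DDR_A"]), 0)  # single occurrence
})

test_that("physicochemical class composition covers the packaged 25 classes", {
  v <- computePCP("KKRR")
  expect_length(v, 25)
  expect_equal(unname(v["PCP_positively_charged"]), 100)
  expect_equal(unname(v["PCP_negatively_charged"]), 0)
  expect_true(all(v >= 0 & v <= 100))
})

test_that("feature matrices align with record order and carry the set tag", {
  ps <- randomPeptides(5, 8, 12, seed = 9)
  for (fs in c("AAC", "DPC", "DPC_LEN", "CTD", "PCP", "DDR", "RRI", "AAB")) {
    m <- computeFeatures(ps, fs)
    expect_equal(nrow(m), 5L)
    expect_equal(rownames(m), peptideIds(ps))
    expect_equal(attr(m, "featureSet"), fs)
  }
  expect_equal(ncol(computeFeatures(ps, "AAC")), 20L)
  expect_equal(ncol(computeFeatures(ps, "DPC")), 400L)
  expect_equal(ncol(computeFeatures(ps, "DPC_LEN")), 401L)
  expect_equal(ncol(computeFeatures(ps, "CTD")), 147L)
  expect_equal(ncol(computeFeatures(ps, "AAB")), 320L)
  expect_error(computeFeatures(ps, "NOPE"))
  # permuting rows permutes the matrix identically (no hidden sorting)
  perm <- c(3, 1, 5, 2, 4)
  m1 <- computeFeatures(ps, "AAC")
  m2 <- computeFeatures(ps[perm], "AAC")
  expect_equal(m2, m1[perm, ], ignore_attr = TRUE)
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  writeFeatureCSV(m1, f)
  expect_equal(readFeatureCSV(f), m1, ignore_attr = TRUE)
})
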