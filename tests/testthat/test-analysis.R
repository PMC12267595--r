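test_that("length histogram conserves class counts", {
  ps <- PeptideSet(c(paste(rep("A", 15), collapse = ""),
                     paste(rep("C", 15), collapse = ""),
                     paste(rep("D", 15), collapse = "")),
                   labels = c(1, 1, 1), ids = paste0("p", 1:3))
  h <- lengthDistribution(ps)
  expect_equal(h$positive[h$length == 15], 3L)
  expect_equal(sum(h$positive), 3L)
  ps2 <- generatePeptides(syntheticConfig(nPos = 80, nNeg = 60, seed = 71))
  h2 <- lengthDistribution(ps2)
  expect_equal(sum(h2$positive), 80L)
  expect_equal(sum(h2$negative), 60L)
})

test_that("the generator's modal length is 15 in both classes", {
  ps <- generatePeptides(syntheticConfig(nPos = 500, nNeg = 500, seed = 72))
  h <- lengthDistribution(ps)
  expect_equal(h$length[which.max(h$positive)], 15L)
  expect_equal(h$length[which.max(h$negative)], 15L)
})

test_that("identical classes yield no significant composition differences", {
  ps <- randomPeptides(20, 8, 15, seed = 73)
  tab <- compositionComparison(ps, ps)
  expect_false(any(tab$significant))
  expect_true(all(tab$diff == 0))
})

test_that("a planted two-fold enrichment is detected after BH correction", {
  ps <- generatePeptides(syntheticConfig(nPos = 500, nNeg = 500, seed = 74))
  pos <- ps[which(peptideLabels(ps) == "positive")]
  neg <- ps[which(peptideLabels(ps) == "negative")]
  tab <- compositionComparison(pos, neg)
  expect_true(tab$significant[tab$residue == "A"])
  expect_gt(tab$diff[tab$residue == "A"], 0)
  # negative-class enrichment shows as negative diff
  expect_true(tab$significant[tab$residue == "C"])
  expect_lt(tab$diff[tab$residue == "C"], 0)
  # t-test variant runs and agrees on the strong signals
  tt <- compositionComparison(pos, neg, test = "t")
  expect_true(tt$significant[tt$residue == "A"])
})

test_that("adjusted p-values equal the hand-computed BH step-up", {
  ps1 <- randomPeptides(15, 8, 12, seed = 75, prefix = "a")
  ps2 <- randomPeptides(15, 8, 12, seed = 76, prefix = "b")
  tab <- compositionComparison(ps1, ps2)
  expect_equal(tab$p_adj, oracleBH(tab$p), tolerance = 1e-12)
  # BH is monotone non-decreasing in raw p-value rank
  o <- order(tab$p)
  expect_true(all(diff(tab$p_adj[o]) >= -1e-12))
})

test_that("swapping classes negates diffs and preserves p-values", {
  pos <- randomPeptides(15, 8, 12, seed = 77, prefix = "a")
  neg <- randomPeptides(15, 8, 12, seed = 78, prefix = "b")
  t1 <- compositionComparison(pos, neg)
  t2 <- compositionComparison(neg, pos)
  expect_equal(t1$diff, -t2$diff)
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
})

test_that("composition means agree with the AAC descriptor columns", {
  pos <- randomPeptides(10, 8, 12, seed = 79)
  neg <- randomPeptides(10, 8, 12, seed = 80, prefix = "n")
  tab <- compositionComparison(pos, neg)
  expect_equal(tab$mean_pos, unname(colMeans(computeFeatures(pos, "AAC"))))
  expect_equal(tab$mean_neg, unname(colMeans(computeFeatures(neg, "AAC"))))
})

test_that("positional enrichment flags a constructed N-terminal preference", {
  set.seed(81)
  pos <- PeptideSet(vapply(1:15, function(i)
    paste0("L", paste(sample(AA20, 9, TRUE), collapse = "")), character(1)),
    ids = paste0("p", 1:15))
  neg <- PeptideSet(vapply(1:15, function(i)
    paste0("D", paste(sample(AA20, 9, TRUE), collapse = "")), character(1)),
    ids = paste0("n", 1:15))
  tab <- positionalEnrichment(pos, neg)
  cell <- tab[tab$position == "N1" & tab$residue == "L", ]
  expect_equal(cell$flag, "enriched")
  expect_lt(cell$p, 0.05)
  cellD <- tab[tab$position == "N1" & tab$residue == "D", ]
  expect_equal(cellD$flag, "depleted")
  expect_lte(nrow(tab), 16 * 20)
})

test_that("identical classes produce no positional flags", {
  ps <- randomPeptides(12, 10, 14, seed = 82)
  tab <- positionalEnrichment(ps, ps)
  expect_true(all(tab$flag == "ns"))
})
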