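test_that("confusion counting treats threshold ties as positive calls", {
  cc <- confusionCounts(c(0.9, 0.1), c(1, 0))
  expect_equal(cc, list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  cc <- confusionCounts(0.5, 0)
  expect_equal(cc$FP, 1L)
  cc <- confusionCounts(rep(1, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(cc$FP, 3L)
  expect_error(confusionCounts(numeric(0), integer(0)), "empty")
})

test_that("metrics match brute-force arithmetic and pairwise AUC", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    cc <- confusionCounts(s, y)
    m <- classMetrics(cc, scores = s, labels = y)
    o <- oracleMetrics(cc)
    expect_equal(m$sensitivity, o$sens, tolerance = 1e-12)
    expect_equal(m$specificity, o$spec, tolerance = 1e-12)
    expect_equal(m$accuracy, o$acc, tolerance = 1e-12)
    expect_equal(m$mcc, o$mcc, tolerance = 1e-12)
    expect_equal(m$auc, oracleAUC(s, y), tolerance = 1e-12)
  }
})

test_that("metric edge cases: perfection, symmetry, degeneracy", {
  y <- c(1, 1, 0, 0)
  m <- classMetrics(scores = c(0.9, 0.8, 0.2, 0.1), labels = y)
  expect_equal(m$mcc, 1)
  expect_equal(m$auc, 1)
  # TP=FN and TN=FP with symmetric scores -> MCC 0
  expect_equal(mccScore(list(TP = 5, FN = 5, TN = 3, FP = 3)), 0)
  # degenerate confusions return 0, not NaN
  expect_equal(mccScore(list(TP = 4, FP = 0, TN = 0, FN = 0)), 0)
  expect_equal(mccScore(list(TP = 0, FP = 0, TN = 7, FN = 0)), 0)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(42)
  y <- sample(c(0, 1), 60, replace = TRUE)
  s <- runif(60)
  a <- aucScore(s, y)
  expect_equal(aucScore(2 * s + 3, y), a)
  expect_equal(aucScore(exp(s), y), a)
  expect_equal(aucScore(rank(s), y), a)
})

test_that("grid-search training is deterministic and row-order invariant", {
  ps <- signalPeptideSet(40, seed = 23)
  m <- computeFeatures(ps, "AAC")
  y <- peptideLabels(ps)
  f1 <- trainModel(m, y, "ET", grid = data.frame(num.trees = 100, mtry = 4),
                   seed = 5)
  f2 <- trainModel(m, y, "ET", grid = data.frame(num.trees = 100, mtry = 4),
                   seed = 5)
  test <- computeFeatures(signalPeptideSet(10, seed = 24), "AAC")
  expect_identical(predictProbability(f1, test), predictProbability(f2, test))
  expect_identical(f1@best, f2@best)
  # permuting training rows changes nothing under a fixed seed
  perm <- sample(seq_len(nrow(m)))
  f3 <- trainModel(m[perm, ], y[perm], "ET",
                   grid = data.frame(num.trees = 100, mtry = 4), seed = 5)
  expect_identical(predictProbability(f1, test), predictProbability(f3, test))
  expect_equal(f1@cvScore, f3@cvScore)
})

test_that("training rejects degenerate inputs", {
  m <- matrix(runif(40), 10, 4, dimnames = list(paste0("r", 1:10), letters[1:4]))
  expect_error(trainModel(m, rep(1, 10), "ET"), "single class")
  m2 <- m; m2[1, 1] <- NA
  expect_error(trainModel(m2, rep(c(0, 1), 5), "ET"), "non-finite")
})

test_that("every algorithm trains and returns calibrated-range scores", {
  ps <- signalPeptideSet(25, seed = 29)
  m <- computeFeatures(ps, "AAC")
  y <- peptideLabels(ps)
  test_ps <- signalPeptideSet(10, seed = 30)
  grids <- list(DT = data.frame(cp = 0.01, minsplit = 10),
                RF = data.frame(num.trees = 50, mtry = 4),
                ET = data.frame(num.trees = 50, mtry = 4),
                KNN = data.frame(k = 3),
                MLP = data.frame(size = 2, decay = 0.1),
                SVR = data.frame(cost = 1, gamma = 0.05),
                XGB = data.frame(nrounds = 20, max_depth = 3, eta = 0.3),
                LASSO = data.frame(lambda = 0.01))
  for (alg in names(grids)) {
    fit <- trainModel(m, y, alg, grid = grids[[alg]], seed = 2)
    p <- predictProbability(fit, test_ps)
    expect_length(p, length(test_ps))
    expect_true(all(p >= 0 & p <= 1), info = alg)
  }
})

test_that("feature-set mismatch at prediction time is caught", {
  fit <- quickModel()  # AAC model
  dpc <- computeFeatures(signalPeptideSet(5, seed = 31), "DPC")
  expect_error(predictProbability(fit, dpc), "mismatch")
})

test_that("feature selection returns k distinct columns and finds a label leak", {
  set.seed(51)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(runif(n * 12), n, 12,
              dimnames = list(paste0("r", seq_len(n)), paste0("f", 1:12)))
  x[, "f7"] <- y  # a column identical to the label
  for (meth in c("mRMR", "L1", "RFE", "importance")) {
    sel <- selectFeatures(x, y, meth, k = 5, seed = 3)
    expect_length(sel, 5)
    expect_false(anyDuplicated(sel) > 0)
    expect_true(all(sel %in% colnames(x)))
    expect_equal(sel[1], "f7", info = meth)
  }
  expect_error(selectFeatures(x, y, "mRMR", k = 50), "exceeds")
  expect_error(selectFeatures(x, rep(1, n), "mRMR", k = 2), "single class")
})

test_that("the first mRMR pick maximizes mutual information with the label", {
  set.seed(52)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("g", 1:6)))
  x[, 3] <- y + rnorm(n, sd = 0.2)  # strongest association
  sel <- selectFeatures(x, y, "mRMR", k = 3, seed = 1)
  # exhaustive MI over 3-bin equal-frequency discretization
  mi <- apply(x, 2, function(v) {
    qs <- unique(quantile(v, seq(0, 1, length.out = 4)))
    d <- as.integer(cut(v, qs, include.lowest = TRUE))
    tab <- table(d, y); p <- tab / sum(tab)
    ex <- outer(rowSums(p), colSums(p))
    sum(p[p > 0] * log(p[p > 0] / ex[p > 0]))
  })
  expect_equal(sel[1], names(which.max(mi)))
})

test_that("model bundles survive a save/load round trip", {
  fit <- quickModel()
  f <- tempfile(fileext = ".rds")
  saveModel(fit, f)
  fit2 <- loadModel(f)
  test <- computeFeatures(signalPeptideSet(6, seed = 33), "AAC")
  expect_identical(predictProbability(fit, test),
                   predictProbability(fit2, test))
})
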