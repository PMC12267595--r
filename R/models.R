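# Classifier training with the evaluation protocol used throughout the
# package: exhaustive grid search, each grid point scored by mean rank-AUC
# over stratified 5-fold cross-validation on the training rows only, best
# point refit on all training rows. Model fitting is delegated to the
# standard implementations (rpart, ranger, class::knn, nnet, e1071::svm,
# xgboost, glmnet); the protocol and bookkeeping live here.

ALGORITHMS <- c("DT", "RF", "KNN", "MLP", "ET", "SVR", "XGB", "LASSO")

#' Fitted peptide classifier
#'
#' Returned by [trainModel()]. Holds the algorithm tag, the feature-set tag
#' and feature names the model expects, the hyperparameter grid searched,
#' the winning grid point with its cross-validated AUC, and the fitted
#' model object.
#'
#' @slot algorithm one of `DT, RF, KNN, MLP, ET, SVR, XGB, LASSO`.
#' @slot featureSet feature-set tag (e.g. `"DPC_LEN"`).
#' @slot featureNames column names the model consumes, in order.
#' @slot grid hyperparameter grid searched (data.frame).
#' @slot best winning grid point (one-row data.frame).
#' @slot cvScore mean cross-validated AUC of the winning point.
#' @slot fit opaque fitted state.
#' @slot seed integer seed used for folds and fitting.
#' @export
setClass("PeptideClassifier",
  representation(algorithm = "character", featureSet = "character",
                 featureNames = "character", grid = "data.frame",
                 best = "data.frame", cvScore = "numeric", fit = "ANY",
                 seed = "integer"))

setMethod("show", "PeptideClassifier", function(object) {
  cat(sprintf("PeptideClassifier: %s on %s (%d features)\n",
              object@algorithm, object@featureSet,
              length(object@featureNames)))
  cat(sprintf("  CV AUC %.3f at {%s}\n", object@cvScore,
              paste(names(object@best), unlist(object@best),
                    sep = "=", collapse = ", ")))
})

#' Default hyperparameter grids
#'
#' Small documented grids per algorithm (the source protocol states none).
#' Tree counts span 200-500, depth-type controls a coarse range; `mtry` for
#' the forest variants is derived from the feature count (`sqrt(p)` and
#' `p/4`).
#'
#' @param algorithm algorithm tag.
#' @param p number of feature columns.
#' @return data.frame, one row per grid point.
#' @export
defaultGrid <- function(algorithm, p) {
  switch(algorithm,
    DT = expand.grid(cp = c(0.01, 0.001), minsplit = c(20, 10)),
    RF = expand.grid(num.trees = c(250, 500),
                     mtry = unique(pmax(1, floor(c(sqrt(p), p / 4))))),
    ET = expand.grid(num.trees = c(200, 500),
                     mtry = unique(pmax(1, floor(c(sqrt(p), p / 4))))),
    KNN = expand.grid(k = c(3, 5, 9)),
    MLP = expand.grid(size = c(3, 8), decay = c(0.1, 0.01)),
    SVR = expand.grid(cost = c(1, 10), gamma = 1 / p),
    XGB = expand.grid(nrounds = c(100, 200), max_depth = c(3, 6), eta = 0.3),
    LASSO = expand.grid(lambda = c(0.1, 0.01, 0.001)),
    stop("unknown algorithm: ", algorithm))
}

fitAlgorithm <- function(algorithm, x, y, params, seed) {
  # y: integer 0/1
  set.seed(seed)
  switch(algorithm,
    DT = {
      df <- data.frame(.y = factor(y, levels = c(0, 1)), x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = params$cp,
                                                  minsplit = params$minsplit))
    },
    RF = ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                        probability = TRUE, num.trees = params$num.trees,
                        mtry = min(params$mtry, ncol(x)), seed = seed,
                        num.threads = 1),
    ET = ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                        probability = TRUE, splitrule = "extratrees",
                        num.random.splits = 1, replace = FALSE,
                        sample.fraction = 1, num.trees = params$num.trees,
                        mtry = min(params$mtry, ncol(x)), seed = seed,
                        num.threads = 1),
    KNN = list(train = x, y = y, k = params$k),
    MLP = nnet::nnet(x = x, y = y, size = params$size, decay = params$decay,
                     entropy = TRUE, maxit = 150, trace = FALSE,
                     MaxNWts = 100000),
    SVR = e1071::svm(x = x, y = as.numeric(y), type = "eps-regression",
                     kernel = "radial", cost = params$cost,
                     gamma = params$gamma),
    XGB = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = params$nrounds, verbose = 0),
    LASSO = glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                           lambda = params$lambda),
    stop("unknown algorithm: ", algorithm))
}

predictAlgorithm <- function(algorithm, fit, x) {
  p <- switch(algorithm,
    DT = stats::predict(fit, data.frame(x, check.names = FALSE),
                        type = "prob")[, "1"],
    RF = , ET = stats::predict(fit, data = x,
                               num.threads = 1)$predictions[, "1"],
    KNN = {
      pr <- class::knn(fit$train, x, factor(fit$y, levels = c(0, 1)),
                       k = fit$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    MLP = as.numeric(stats::predict(fit, x)),
    SVR = pmin(1, pmax(0, as.numeric(stats::predict(fit, x)))),
    XGB = as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))),
    LASSO = as.numeric(stats::predict(fit, x, type = "response")),
    stop("unknown algorithm: ", algorithm))
  unname(p)
}

# stratified fold ids, deterministic under seed and invariant to row order
# (rows are canonicalized by the caller)
stratifiedFolds <- function(y, k, seed) {
  fold <- integer(length(y))
  withSeed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Train a classifier by grid-search cross-validation
#'
#' Runs an exhaustive grid search; each grid point is scored by its mean
#' rank-based ROC AUC over `cvFolds` stratified folds of the training rows
#' (held-out test rows are never touched). The best point (ties: first in
#' grid order) is refit on all training rows. Rows are internally
#' canonicalized by (label, row id) before fold assignment, so the result
#' does not depend on input row order.
#'
#' @param features numeric feature matrix with row names (ids), e.g. from
#'   [computeFeatures()].
#' @param labels class labels aligned with rows.
#' @param algorithm one of `DT, RF, KNN, MLP, ET, SVR, XGB, LASSO`. `SVR`
#'   is a radial-kernel support-vector regressor used as a classifier; its
#'   predictions are clamped to \[0, 1\].
#' @param grid hyperparameter grid (data.frame); defaults to
#'   [defaultGrid()].
#' @param cvFolds number of folds (default 5).
#' @param seed integer seed controlling folds and fitting.
#' @param featureSet feature-set tag stored with the model; defaults to the
#'   `"featureSet"` attribute of `features`.
#' @return a [PeptideClassifier-class].
#' @examples
#' ps <- generatePeptides(syntheticConfig(nPos = 40, nNeg = 40, seed = 3))
#' m <- computeFeatures(ps, "AAC")
#' fit <- trainModel(m, peptideLabels(ps), "LASSO", seed = 1)
#' fit
#' @export
trainModel <- function(features, labels, algorithm = "ET", grid = NULL,
                       cvFolds = 5L, seed = 42L, featureSet = NULL) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  stopifnot(cvFolds >= 2)
  y <- asBinaryLabels(labels)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (any(!is.finite(features))) stop("non-finite feature values")
  if (nrow(features) < cvFolds) stop("fewer rows than folds")
  if (is.null(featureSet))
    featureSet <- attr(features, "featureSet") %||% "custom"
  if (is.null(rownames(features)))
    rownames(features) <- paste0("row", seq_len(nrow(features)))
  if (is.null(grid)) grid <- defaultGrid(algorithm, ncol(features))
  stopifnot(nrow(grid) >= 1)

  ord <- order(y, rownames(features))
  x <- features[ord, , drop = FALSE]
  y <- y[ord]
  fold <- stratifiedFolds(y, cvFolds, seed)

  cv_scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- grid[g, , drop = FALSE]
    aucs <- vapply(seq_len(cvFolds), function(f) {
      tr <- fold != f
      fit <- fitAlgorithm(algorithm, x[tr, , drop = FALSE], y[tr], params,
                          seed + g)
      p <- predictAlgorithm(algorithm, fit, x[!tr, , drop = FALSE])
      aucScore(p, y[!tr])
    }, numeric(1))
    cv_scores[g] <- mean(aucs, na.rm = TRUE)
  }
  best_g <- which.max(cv_scores)
  best <- grid[best_g, , drop = FALSE]
  fit <- fitAlgorithm(algorithm, x, y, best, seed + best_g)
  new("PeptideClassifier", algorithm = algorithm, featureSet = featureSet,
      featureNames = colnames(features), grid = grid, best = best,
      cvScore = cv_scores[best_g], fit = fit, seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class probabilities
#'
#' Accepts a feature matrix (columns are aligned to the model's feature
#' names) or a [PeptideSet-class] (features are computed with the model's
#' feature-set tag first).
#'
#' @param model a [PeptideClassifier-class].
#' @param newdata matrix or [PeptideSet-class].
#' @return numeric vector of positive-class probabilities in \[0, 1\].
#' @export
predictProbability <- function(model, newdata) {
  if (is(newdata, "PeptideSet"))
    newdata <- computeFeatures(newdata, model@featureSet)
  missing_cols <- setdiff(model@featureNames, colnames(newdata))
  if (length(missing_cols))
    stop("newdata lacks ", length(missing_cols), " model feature(s); ",
         "feature-set mismatch? (model expects ", model@featureSet, ")")
  x <- newdata[, model@featureNames, drop = FALSE]
  predictAlgorithm(model@algorithm, model@fit, x)
}

#' Evaluate a classifier on a labeled peptide set
#'
#' @param model a [PeptideClassifier-class].
#' @param test labeled [PeptideSet-class] or feature matrix.
#' @param labels labels when `test` is a matrix.
#' @param threshold decision threshold.
#' @return [classMetrics()] list.
#' @export
evaluateModel <- function(model, test, labels = NULL, threshold = 0.5) {
  if (is(test, "PeptideSet")) {
    labels <- peptideLabels(test)
  }
  p <- predictProbability(model, test)
  classMetrics(scores = p, labels = labels, threshold = threshold)
}

#' Save / load a fitted classifier bundle
#'
#' Persists the full [PeptideClassifier-class] (spec, feature names and
#' fitted state) to a single file.
#'
#' @param model a [PeptideClassifier-class]
#' @param path file path
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
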