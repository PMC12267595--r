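# Feature selection on descriptor matrices: mRMR (mutual information on
# discretized features), L1-penalized linear classifier coefficients,
# recursive feature elimination with a tree ensemble, and impurity-based
# importance ranking (a documented stand-in for SHAP — only the downstream
# model quality is consumed, not attribution values).

# equal-frequency discretization into <= nbins levels; columns with few
# distinct values (e.g. binary indicators) keep their values as levels
discretizeColumn <- function(v, nbins = 3L) {
  u <- unique(v)
  if (length(u) <= nbins) return(as.integer(factor(v, levels = sort(u))))
  qs <- unique(stats::quantile(v, probs = seq(0, 1, length.out = nbins + 1)))
  if (length(qs) < 2) return(rep(1L, length(v)))
  as.integer(cut(v, breaks = qs, include.lowest = TRUE))
}

# mutual information (nats) between two discrete vectors
mutualInformation <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  ex <- outer(pa, pb)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / ex[nz]))
}

#' Select top-k features
#'
#' Four selection strategies over a feature matrix and binary labels:
#' \describe{
#'   \item{mRMR}{greedy maximum (relevance - mean redundancy), with
#'     relevance and redundancy measured as mutual information on features
#'     discretized into 3 equal-frequency bins.}
#'   \item{L1}{coefficients of an L1-penalized logistic model; the penalty
#'     is relaxed along the regularization path until at least `k` features
#'     have nonzero coefficients, then the top `k` by absolute
#'     coefficient.}
#'   \item{RFE}{recursive feature elimination with an extra-trees ensemble,
#'     dropping 10\% of the surviving features per round (never below
#'     `k`).}
#'   \item{importance}{impurity-based ranking from a single extra-trees
#'     ensemble.}
#' }
#'
#' @param features numeric matrix with column names.
#' @param labels class labels aligned with rows.
#' @param method `"mRMR"`, `"L1"`, `"RFE"` or `"importance"`.
#' @param k number of features to keep (typically 10, 100 or 200).
#' @param seed integer seed for the tree-based methods.
#' @return character vector of exactly `k` distinct column names.
#' @examples
#' ps <- generatePeptides(syntheticConfig(nPos = 30, nNeg = 30, seed = 5))
#' m <- computeFeatures(ps, "AAC")
#' selectFeatures(m, peptideLabels(ps), "importance", k = 5)
#' @export
selectFeatures <- function(features, labels,
                           method = c("mRMR", "L1", "RFE", "importance"),
                           k = 10L, seed = 42L) {
  method <- match.arg(method)
  y <- asBinaryLabels(labels)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  p <- ncol(features)
  if (k > p) stop("k exceeds the number of feature columns")
  cn <- colnames(features)
  if (is.null(cn)) stop("features must have column names")

  if (method == "mRMR") {
    xd <- apply(features, 2, discretizeColumn)
    rel <- apply(xd, 2, mutualInformation, b = y)
    selected <- integer(0)
    candidates <- seq_len(p)
    red_sum <- numeric(p)
    for (step in seq_len(k)) {
      score <- if (length(selected) == 0) rel[candidates]
               else rel[candidates] - red_sum[candidates] / length(selected)
      pick <- candidates[which.max(score)]
      selected <- c(selected, pick)
      candidates <- setdiff(candidates, pick)
      if (length(candidates) && step < k) {
        add <- vapply(candidates, function(j)
          mutualInformation(xd[, j], xd[, pick]), numeric(1))
        red_sum[candidates] <- red_sum[candidates] + add
      }
    }
    return(cn[selected])
  }

  if (method == "L1") {
    fit <- glmnet::glmnet(features, y, family = "binomial", alpha = 1,
                          nlambda = 100)
    nz <- fit$df
    ok <- which(nz >= k)
    lam_i <- if (length(ok)) ok[1] else length(fit$lambda)
    beta <- abs(as.numeric(fit$beta[, lam_i]))
    return(cn[order(-beta, seq_len(p))[seq_len(k)]])
  }

  etImportance <- function(cols, s) {
    fit <- ranger::ranger(x = features[, cols, drop = FALSE],
                          y = factor(y, levels = c(0, 1)),
                          num.trees = 200, importance = "impurity",
                          splitrule = "extratrees", num.random.splits = 1,
                          replace = FALSE, sample.fraction = 1,
                          seed = s, num.threads = 1)
    fit$variable.importance
  }

  if (method == "RFE") {
    keep <- cn
    round <- 0L
    while (length(keep) > k) {
      round <- round + 1L
      imp <- etImportance(keep, seed + round)
      drop_n <- min(max(1L, floor(0.1 * length(keep))), length(keep) - k)
      keep <- names(sort(imp, decreasing = TRUE))[seq_len(length(keep) - drop_n)]
    }
    imp <- etImportance(keep, seed)
    return(names(sort(imp, decreasing = TRUE))[seq_len(k)])
  }

  # importance
  imp <- etImportance(cn, seed)
  names(sort(imp, decreasing = TRUE))[seq_len(k)]
}
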