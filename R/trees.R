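#' Random forest probability classifier
#'
#' Bagged CART regression trees on the 0/1 outcome (variance splitting,
#' which coincides with Gini impurity for a binary target); the predicted
#' class-1 probability is the across-tree mean of leaf outcome rates.
#' Randomness (bootstrap and per-node `mtry` feature subsampling) uses R's
#' RNG, so fits are reproducible under `set.seed()`.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Binary 0/1 outcome.
#' @param n_trees Number of trees (default 500).
#' @param min_leaf Minimum samples per leaf.
#' @param mtry Features tried per split; default `floor(sqrt(ncol(x)))`.
#' @param max_depth Depth cap; `-1` (default) grows to purity.
#' @return Object of class `pcs_rf`.
#' @export
rf_fit <- function(x, y, n_trees = 500L, min_leaf = 1L, mtry = NULL,
                   max_depth = -1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  n <- nrow(x)
  trees <- vector("list", n_trees)
  oob <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    rows <- sample.int(n, n, replace = TRUE)
    oob[[b]] <- which(tabulate(rows, n) == 0L) - 1L
    trees[[b]] <- tree_fit_cpp(x, y, rows - 1L, as.integer(mtry),
                               as.integer(min_leaf), as.integer(max_depth))
  }
  structure(list(trees = trees, oob = oob, features = colnames(x)),
            class = "pcs_rf")
}

#' Out-of-bag predictions of a random forest
#'
#' Each training row is predicted only by trees whose bootstrap sample did
#' not contain it - the standard honest estimate used for Breiman-style
#' permutation importance.
#'
#' @param object A [rf_fit()] model.
#' @param newdata The training feature matrix (row order must match the
#'   fit), optionally with columns permuted.
#' @return OOB-aggregated class-1 probabilities.
#' @export
predict_oob <- function(object, newdata) {
  stopifnot(inherits(object, "pcs_rf"))
  newdata <- as.matrix(newdata)[, object$features, drop = FALSE]
  forest_predict_oob_cpp(object$trees, object$oob, newdata)
}

#' @rdname rf_fit
#' @param object A `pcs_rf` model.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @return `predict()`: class-1 probabilities in \[0, 1\].
#' @export
predict.pcs_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$features, drop = FALSE]
  forest_predict_cpp(object$trees, newdata)
}

#' Gradient-boosted decision trees for binary outcomes
#'
#' Logistic-loss gradient boosting: each round fits a depth-limited
#' regression tree to the residual `y - p`, then applies a Newton update
#' per leaf (`sum(residual) / sum(p(1-p))`) scaled by the learning rate.
#'
#' @inheritParams rf_fit
#' @param learning_rate Shrinkage per boosting round.
#' @param max_depth Tree depth (default 3).
#' @return Object of class `pcs_gbdt`.
#' @export
gbdt_fit <- function(x, y, n_trees = 500L, learning_rate = 0.1,
                     max_depth = 3L, min_leaf = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  n <- nrow(x)
  p <- ncol(x)
  pri <- mean(y)
  f0 <- stats::qlogis(min(max(pri, 1e-6), 1 - 1e-6))
  fx <- rep(f0, n)
  rows <- seq_len(n) - 1L
  trees <- vector("list", n_trees)
  gammas <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    pb <- stats::plogis(fx)
    resid <- y - pb
    w <- pmax(pb * (1 - pb), 1e-6)
    tree <- tree_fit_cpp(x, resid, rows, p, as.integer(min_leaf),
                         as.integer(max_depth))
    leaf <- tree_leaf_cpp(tree, x) + 1L
    gnum <- tapply(resid, leaf, sum)
    gden <- tapply(w, leaf, sum)
    gamma <- rep(0, length(tree$value))
    gamma[as.integer(names(gnum))] <- gnum / gden
    fx <- fx + learning_rate * gamma[leaf]
    trees[[b]] <- tree
    gammas[[b]] <- gamma
  }
  structure(list(trees = trees, gammas = gammas, f0 = f0,
                 learning_rate = learning_rate, features = colnames(x)),
            class = "pcs_gbdt")
}

#' @rdname gbdt_fit
#' @param object A `pcs_gbdt` model.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @return `predict()`: class-1 probabilities in \[0, 1\].
#' @export
predict.pcs_gbdt <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$features, drop = FALSE]
  fx <- rep(object$f0, nrow(newdata))
  for (b in seq_along(object$trees)) {
    leaf <- tree_leaf_cpp(object$trees[[b]], newdata) + 1L
    fx <- fx + object$learning_rate * object$gammas[[b]][leaf]
  }
  stats::plogis(fx)
}
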