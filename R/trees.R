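#' @title Regression trees and tree ensembles with native missing-value routing
#'
#' @description From-scratch CART regression trees, random forests and
#'   gradient-boosted trees (XGBoost-style second-order gain with `lambda`/
#'   `gamma` regularisation). Every node records its training *cover* (number
#'   of training rows routed through it) and, for internal nodes, a *default
#'   direction* for rows whose split feature is missing. Both are required by
#'   the exact path-dependent Shapley explainer ([exact_shapley()]).
#'
#' @details Split candidates are midpoints between consecutive distinct
#'   observed values of each feature; rows with the split feature missing are
#'   sent down whichever direction yields the higher gain, and that direction
#'   becomes the node default. Gain ties break deterministically to the lowest
#'   feature index and then the lowest threshold.
#'
#' @name tree_ensemble
NULL

# coerce a feature table (matrix / data.frame) to a numeric matrix with
# missing values as NaN (what the C++ engine expects)
as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  storage.mode(X) <- "double"
  X[is.na(X)] <- NaN
  X
}

new_shap_tree <- function(nodes, feature_names) {
  structure(list(nodes = nodes, feature_names = feature_names),
            class = "shap_tree")
}

#' Fit a single regression tree
#'
#' Grows one greedy binary regression tree. In `mode = "cart"` the split gain
#' is the SSE reduction and leaf values are node means of `y`; in
#' `mode = "boosted"` the gain is the second-order (XGBoost) gain
#' \eqn{\frac12[G_L^2/(H_L+\lambda) + G_R^2/(H_R+\lambda) - G^2/(H+\lambda)] - \gamma}
#' and leaf values are \eqn{-G/(H+\lambda)}, where `g`/`h` are the supplied
#' gradient/hessian statistics (squared loss: `g = prediction - y`, `h = 1`).
#'
#' @param X feature matrix or data frame; `NA`/`NaN` cells are treated as
#'   missing and routed by learned default directions.
#' @param y numeric response (`mode = "cart"`); ignored when `g` is given.
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_leaf minimum number of training rows in each child.
#' @param mtry number of candidate features per split (all by default).
#' @param lambda,gamma boosted-mode regularisation (L2 on leaf values and
#'   per-split penalty).
#' @param mode `"cart"` or `"boosted"`.
#' @param g,h optional gradient/hessian vectors for boosted mode.
#' @param rows optional 1-based training-row subset (bootstrap sample).
#' @param seed integer seed for the per-split feature subsample.
#' @return an object of class `shap_tree`.
#' @export
fit_regression_tree <- function(X, y = NULL, max_depth = 30L, min_leaf = 2L,
                                mtry = NULL, lambda = 0, gamma = 0,
                                mode = c("cart", "boosted"), g = NULL,
                                h = NULL, rows = NULL, seed = 1L) {
  mode <- match.arg(mode)
  X <- as_feature_matrix(X)
  if (nrow(X) < 1L) stop("empty input: at least one row is required")
  if (mode == "cart") {
    if (is.null(y)) stop("'y' is required in cart mode")
    if (!all(is.finite(y))) stop("'y' must be finite")
    g <- -as.numeric(y)
    h <- rep(1, length(y))
    lambda <- 0
    gamma <- 0
  } else {
    if (is.null(g)) {
      if (is.null(y)) stop("boosted mode needs 'g'/'h' or 'y'")
      g <- -as.numeric(y)
    }
    if (is.null(h)) h <- rep(1, length(g))
  }
  if (length(g) != nrow(X)) stop("length of response does not match rows of X")
  if (is.null(rows)) rows <- seq_len(nrow(X))
  if (is.null(mtry)) mtry <- ncol(X)
  nodes <- cpp_grow_tree(X, g, h, as.integer(rows) - 1L,
                         as.integer(max_depth), as.integer(min_leaf),
                         as.integer(mtry), lambda, gamma, as.integer(seed))
  new_shap_tree(nodes, colnames(X))
}

#' @export
predict.shap_tree <- function(object, newdata, ...) {
  cpp_predict_tree(object$nodes, as_feature_matrix(newdata))
}

new_tree_ensemble <- function(mode, trees, feature_names, base_score = 0,
                              learning_rate = 1, row_ids = NULL) {
  structure(list(mode = mode, trees = trees, feature_names = feature_names,
                 base_score = base_score, learning_rate = learning_rate,
                 row_ids = row_ids),
            class = "tree_ensemble")
}

#' Fit a random forest of CART regression trees
#'
#' @inheritParams fit_regression_tree
#' @param n_trees number of trees.
#' @param bootstrap draw a bootstrap resample per tree (`TRUE` by default).
#' @param mtry features considered per split; default all features, the
#'   regression default of the reference random-forest implementations (per
#'   -split subsampling remains available).
#' @param row_ids optional identifiers of the training rows (stored for
#'   train/test leakage checks in [shap_for_fold()]).
#' @return an object of class `tree_ensemble` (`mode = "forest"`); predictions
#'   are the unweighted mean over trees.
#' @export
fit_forest <- function(X, y, n_trees = 100L, bootstrap = TRUE, mtry = NULL,
                       min_leaf = 2L, max_depth = 30L, seed = 1L,
                       row_ids = NULL) {
  if (n_trees < 1L) stop("n_trees must be at least 1")
  X <- as_feature_matrix(X)
  if (is.null(mtry)) mtry <- ncol(X)
  set.seed(as.integer(seed))
  tree_seeds <- sample.int(.Machine$integer.max, n_trees)
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    rows <- if (bootstrap) sample.int(nrow(X), nrow(X), replace = TRUE)
            else seq_len(nrow(X))
    trees[[b]] <- fit_regression_tree(X, y, max_depth = max_depth,
                                      min_leaf = min_leaf, mtry = mtry,
                                      mode = "cart", rows = rows,
                                      seed = tree_seeds[b])
  }
  new_tree_ensemble("forest", trees, colnames(X), row_ids = row_ids)
}

#' Fit a gradient-boosted tree ensemble
#'
#' Sequential fitting to squared-loss residuals: the base score is `mean(y)`,
#' each round grows one tree on gradients `g = prediction - y` (hessian 1) and
#' leaf values \eqn{-G/(H+\lambda)}, scaled by the learning rate. Missing
#' feature values are routed natively by learned default directions.
#'
#' @inheritParams fit_forest
#' @param n_rounds number of boosting rounds (trees).
#' @param learning_rate shrinkage applied to every tree's output.
#' @return an object of class `tree_ensemble` (`mode = "boosted"`).
#' @export
fit_boosted <- function(X, y, n_rounds = 100L, learning_rate = 0.3,
                        max_depth = 6L, lambda = 1, gamma = 0, min_leaf = 1L,
                        seed = 1L, row_ids = NULL) {
  if (learning_rate <= 0) stop("learning rate must be positive")
  if (n_rounds < 0L) stop("n_rounds must be non-negative")
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  set.seed(as.integer(seed))
  tree_seeds <- if (n_rounds > 0L) sample.int(.Machine$integer.max, n_rounds)
                else integer(0)
  base <- mean(y)
  pred <- rep(base, length(y))
  trees <- vector("list", n_rounds)
  for (b in seq_len(n_rounds)) {
    tr <- fit_regression_tree(X, max_depth = max_depth, min_leaf = min_leaf,
                              lambda = lambda, gamma = gamma,
                              mode = "boosted", g = pred - y,
                              h = rep(1, length(y)), seed = tree_seeds[b])
    trees[[b]] <- tr
    pred <- pred + learning_rate * predict(tr, X)
  }
  new_tree_ensemble("boosted", trees, colnames(X), base_score = base,
                    learning_rate = learning_rate, row_ids = row_ids)
}

#' @export
predict.tree_ensemble <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  if (length(object$trees) == 0L)
    return(rep(object$base_score, nrow(X)))
  per_tree <- vapply(object$trees, function(tr) cpp_predict_tree(tr$nodes, X),
                     numeric(nrow(X)))
  per_tree <- matrix(per_tree, nrow = nrow(X))
  if (object$mode == "forest") rowMeans(per_tree)
  else object$base_score + object$learning_rate * rowSums(per_tree)
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat(sprintf("<tree_ensemble: %s, %d trees, %d features>\n", x$mode,
              length(x$trees), length(x$feature_names)))
  invisible(x)
}

#' Permutation importance of each feature
#'
#' Mean increase in test MSE after shuffling one feature column at a time,
#' averaged over `repeats` shuffles.
#'
#' @param model a fitted `tree_ensemble` (or `shap_tree`).
#' @param X,y evaluation data.
#' @param repeats number of shuffles per feature.
#' @param seed integer seed.
#' @return named numeric vector of importance scores (one per feature).
#' @export
permutation_importance <- function(model, X, y, repeats = 10L, seed = 1L) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  base_mse <- mean((predict(model, X) - y)^2)
  set.seed(as.integer(seed))
  scores <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    inc <- numeric(repeats)
    for (r in seq_len(repeats)) {
      Xp <- X
      Xp[, j] <- X[sample.int(nrow(X)), j]
      inc[r] <- mean((predict(model, Xp) - y)^2) - base_mse
    }
    scores[j] <- mean(inc)
  }
  names(scores) <- colnames(X)
  scores
}

#' Serialize / restore a tree ensemble as JSON
#'
#' The JSON carries, per node: split feature (name), threshold, default
#' direction for missing values, training cover, and leaf value — everything
#' the Shapley explainer needs, so fixtures can be stored as plain text.
#'
#' @param model a `tree_ensemble`.
#' @param path file to write; if `NULL` the JSON string is returned.
#' @export
ensemble_to_json <- function(model, path = NULL) {
  obj <- list(mode = model$mode, base_score = model$base_score,
              learning_rate = model$learning_rate,
              feature_names = model$feature_names,
              trees = lapply(model$trees, function(tr) tr$nodes))
  js <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname ensemble_to_json
#' @param json a path to, or string of, JSON written by [ensemble_to_json()].
#' @export
ensemble_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE)
  trees <- lapply(obj$trees, function(nd) {
    nd <- lapply(nd, unlist)
    nd$feature <- as.integer(nd$feature)
    nd$left <- as.integer(nd$left)
    nd$right <- as.integer(nd$right)
    nd$missing_left <- as.logical(nd$missing_left)
    new_shap_tree(nd, unlist(obj$feature_names))
  })
  new_tree_ensemble(obj$mode, trees, unlist(obj$feature_names),
                    base_score = obj$base_score,
                    learning_rate = obj$learning_rate)
}

# single-tree ensemble helper used by tests and the explainer
as_tree_ensemble <- function(tree, mode = "forest") {
  stopifnot(inherits(tree, "shap_tree"))
  new_tree_ensemble(mode, list(tree), tree$feature_names,
                    base_score = 0, learning_rate = 1)
}
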