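#' @title Exact Shapley decomposition of tree-ensemble predictions
#'
#' @description Decomposes every prediction `fx` into an additive model
#'   \deqn{f_x = \phi_0 + \sum_{i=1}^{M} \phi_{x_i}} where \eqn{\phi_0} is the
#'   expected (typical) prediction and \eqn{\phi_{x_i}} the exact Shapley value
#'   of covariate `i` under the tree *path-dependent* conditional expectation:
#'   features outside the conditioning set are marginalised by averaging both
#'   children of their splits, weighted by training cover.
#'
#' @name shap_engine
NULL

shap_feature_cap <- 16L

#' Path-dependent conditional expectation of a tree
#'
#' Evaluates \eqn{v(S)}: at an internal node splitting on feature `j`, if `j`
#' is in `S` the branch dictated by `x` is followed (missing values follow the
#' node's default direction); if not, the cover-weighted average of both
#' children is returned; leaves return their value.
#'
#' @param tree a `shap_tree` (or a single-tree `tree_ensemble`).
#' @param x a feature row (named numeric vector or 1-row matrix); `NA` means
#'   missing.
#' @param S conditioning subset: feature names or integer indices (may be
#'   empty).
#' @return the conditional expectation, a single number.
#' @export
path_expectation <- function(tree, x, S = integer(0)) {
  if (inherits(tree, "tree_ensemble")) {
    stopifnot(length(tree$trees) == 1L)
    tree <- tree$trees[[1L]]
  }
  stopifnot(inherits(tree, "shap_tree"))
  x <- as.numeric(as_feature_matrix(matrix(as.numeric(x), nrow = 1L)))
  if (is.character(S)) S <- match(S, tree$feature_names)
  if (anyNA(S)) stop("unknown feature name in S")
  cpp_path_expectation(tree$nodes, x, as.integer(S) - 1L)
}

# per-tree phi matrix and phi0 for a block of rows
ensemble_shap_matrix <- function(model, X) {
  X <- as_feature_matrix(X)
  p <- ncol(X)
  if (p > shap_feature_cap)
    stop(sprintf(paste0("too many features for exact Shapley enumeration ",
                        "(%d > cap %d); a sampling approximation would be ",
                        "required"), p, shap_feature_cap))
  phi <- matrix(0, nrow(X), p)
  phi0 <- 0
  for (tr in model$trees) {
    res <- cpp_tree_shap(tr$nodes, X)
    phi <- phi + res$phi
    phi0 <- phi0 + res$phi0
  }
  n_tree <- length(model$trees)
  if (model$mode == "forest") {
    if (n_tree == 0L) stop("forest with no trees")
    phi <- phi / n_tree
    phi0 <- phi0 / n_tree
  } else {
    phi <- phi * model$learning_rate
    phi0 <- model$base_score + model$learning_rate * phi0
  }
  colnames(phi) <- colnames(X)
  list(phi = phi, phi0 = phi0)
}

#' Exact Shapley values for one feature row
#'
#' Computes \eqn{\phi_i = \sum_{S \subseteq M\setminus\{i\}}
#' \frac{|S|!\,(M-|S|-1)!}{M!}\,[v(S\cup\{i\}) - v(S)]} with \eqn{v} the
#' path-dependent expectation, exploiting additivity over trees. The result is
#' exact: the per-leaf closed form used internally is algebraically identical
#' to full subset enumeration.
#'
#' @param model a fitted `tree_ensemble` (or a `shap_tree`).
#' @param x one feature row (named numeric vector, or 1-row matrix/data frame);
#'   `NA` marks missing values, which are routed by default directions.
#' @return an object of class `shap_decomposition`: list with `phi0` (base
#'   value), `phi` (named contributions), `fx` (model prediction) and `M`.
#' @export
exact_shapley <- function(model, x) {
  if (inherits(model, "shap_tree")) model <- as_tree_ensemble(model)
  if (is.data.frame(x) || is.matrix(x)) {
    X <- as_feature_matrix(x)[1L, , drop = FALSE]
  } else {
    X <- matrix(as.numeric(x), nrow = 1L,
                dimnames = list(NULL, names(x)))
  }
  if (is.null(colnames(X))) colnames(X) <- model$feature_names
  res <- ensemble_shap_matrix(model, X)
  fx <- predict(model, X)
  structure(list(phi0 = res$phi0,
                 phi = setNames(res$phi[1L, ], colnames(X)),
                 fx = fx, M = ncol(X)),
            class = "shap_decomposition")
}

#' @export
print.shap_decomposition <- function(x, ...) {
  cat(sprintf("<shap_decomposition: phi0 = %.4g, fx = %.4g, M = %d>\n",
              x$phi0, x$fx, x$M))
  print(round(x$phi, 4))
  invisible(x)
}

#' SHAP values of a fitted model on one cross-validation test fold
#'
#' One decomposition per test row, returned in long format ready for pooling
#' across folds. The model must have been fitted on the complementary training
#' fold: if identifiers stored in the model overlap the test rows a leakage
#' error is raised.
#'
#' @param model a `tree_ensemble`, optionally carrying `row_ids` of its
#'   training rows.
#' @param table a [feature_table()] for the test rows (imputed or native
#'   missing, matching how the model was fitted).
#' @param fold fold identifier recorded in the output.
#' @return a long-format data frame (class `pooled_shap` after pooling):
#'   patient, occasion, fold, covariate, covariate_value, missing_flag,
#'   shap_value, phi0, prediction.
#' @export
shap_for_fold <- function(model, table, fold = NA_integer_) {
  stopifnot(inherits(table, "feature_table"))
  test_ids <- paste(table$ids$patient, table$ids$occasion, sep = ":")
  if (!is.null(model$row_ids) && length(intersect(model$row_ids, test_ids)))
    stop("leakage: model was trained on rows present in the test fold")
  res <- ensemble_shap_matrix(model, table$X)
  fx <- predict(model, table$X)
  n <- nrow(table$X); p <- ncol(table$X)
  data.frame(
    patient = rep(table$ids$patient, times = p),
    occasion = rep(table$ids$occasion, times = p),
    fold = fold,
    covariate = rep(colnames(table$X), each = n),
    covariate_value = as.vector(table$X),
    missing_flag = as.vector(table$missing),
    shap_value = as.vector(res$phi),
    phi0 = res$phi0,
    prediction = rep(fx, times = p),
    stringsAsFactors = FALSE
  )
}

#' Pool per-fold SHAP tables
#'
#' @param ... long-format per-fold tables from [shap_for_fold()] (or a single
#'   list of them).
#' @return the concatenated table, class `pooled_shap`.
#' @export
pool_shap <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !is.data.frame(parts[[1L]])) parts <- parts[[1L]]
  out <- do.call(rbind, parts)
  key <- unique(out[, c("patient", "occasion", "fold")])
  dup <- duplicated(key[, c("patient", "occasion")])
  if (any(dup))
    stop("pooling error: a subject-occasion appears in more than one fold")
  class(out) <- c("pooled_shap", "data.frame")
  out
}

#' Rank covariates by mean absolute SHAP value
#'
#' @param pooled a `pooled_shap` long table.
#' @return data frame (covariate, mean_abs_shap) in descending order; ties
#'   break alphabetically.
#' @export
rank_covariates <- function(pooled) {
  stopifnot(nrow(pooled) > 0L)
  agg <- tapply(abs(pooled$shap_value), pooled$covariate, mean)
  out <- data.frame(covariate = names(agg), mean_abs_shap = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs_shap, out$covariate), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Waterfall breakdown of a single prediction
#'
#' Orders the contributions of one decomposition by decreasing absolute value
#' and accumulates them from the base value \eqn{\phi_0} to the prediction
#' `fx`.
#'
#' @param d a `shap_decomposition` from [exact_shapley()].
#' @return data frame (covariate, phi, cumulative); the last cumulative value
#'   equals the model prediction.
#' @export
individual_breakdown <- function(d) {
  stopifnot(inherits(d, "shap_decomposition"))
  ord <- order(-abs(d$phi), names(d$phi))
  phi <- d$phi[ord]
  data.frame(covariate = names(phi), phi = as.numeric(phi),
             cumulative = d$phi0 + cumsum(as.numeric(phi)),
             stringsAsFactors = FALSE)
}

#' Combine the SHAP values of several covariates
#'
#' Sums, per subject-occasion, the SHAP values of a covariate set (e.g. weight
#' and BMI) to expose effects shared among correlated covariates. The result
#' is indexed by one covariate's value with a second available for
#' stratification/colouring.
#'
#' @param pooled a `pooled_shap` long table.
#' @param covariates character vector of covariates whose SHAP values are
#'   summed.
#' @param index covariate whose value indexes the combined effect (default:
#'   first of `covariates`).
#' @param by optional stratification covariate whose value is carried along.
#' @return data frame (patient, occasion, fold, index_value, by_value,
#'   combined_shap).
#' @export
combine_shap <- function(pooled, covariates, index = covariates[1L],
                         by = NULL) {
  stopifnot(length(covariates) >= 1L)
  all_cov <- unique(pooled$covariate)
  unknown <- setdiff(c(covariates, index, by), all_cov)
  if (length(unknown))
    stop("unknown covariate name(s): ", paste(unknown, collapse = ", "))
  key <- paste(pooled$patient, pooled$occasion, sep = ":")
  sel <- pooled$covariate %in% covariates
  sums <- tapply(pooled$shap_value[sel], key[sel], sum)
  idx_rows <- pooled[pooled$covariate == index, , drop = FALSE]
  idx_key <- paste(idx_rows$patient, idx_rows$occasion, sep = ":")
  out <- data.frame(patient = idx_rows$patient, occasion = idx_rows$occasion,
                    fold = idx_rows$fold,
                    index_value = idx_rows$covariate_value,
                    combined_shap = as.numeric(sums[idx_key]),
                    stringsAsFactors = FALSE)
  if (!is.null(by)) {
    by_rows <- pooled[pooled$covariate == by, , drop = FALSE]
    by_key <- paste(by_rows$patient, by_rows$occasion, sep = ":")
    out$by_value <- by_rows$covariate_value[match(idx_key, by_key)]
  }
  out
}
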