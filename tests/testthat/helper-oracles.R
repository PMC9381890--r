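# Independent oracles and fixture builders shared across the suite.
#
# The oracles deliberately use different algorithms from the package:
# path_expectation is re-derived by enumerating root-to-leaf paths and
# multiplying per-node weights, and Shapley values by full subset enumeration
# over bitmasks with the factorial weights. They stay independent of the
# recursive/per-leaf closed forms used by the implementation.

make_shap_tree <- function(feature, threshold, left, right, missing_left,
                           value, cover, feature_names) {
  structure(list(nodes = list(feature = as.integer(feature),
                              threshold = as.numeric(threshold),
                              left = as.integer(left),
                              right = as.integer(right),
                              missing_left = as.logical(missing_left),
                              value = as.numeric(value),
                              cover = as.numeric(cover)),
                 feature_names = feature_names),
            class = "shap_tree")
}

# the two-feature worked example: root splits f1 (covers 60/40) with left
# leaf 10; the right child splits f2 (covers 30/10) into leaves 20 and 40
fixture_tree <- function() {
  make_shap_tree(feature = c(0L, -1L, 1L, -1L, -1L),
                 threshold = c(0.5, 0, 0.5, 0, 0),
                 left = c(1L, -1L, 3L, -1L, -1L),
                 right = c(2L, -1L, 4L, -1L, -1L),
                 missing_left = rep(TRUE, 5),
                 value = c(0, 10, 0, 20, 40),
                 cover = c(100, 60, 40, 30, 10),
                 feature_names = c("f1", "f2"))
}

# random tree with internally consistent covers (parent = left + right)
random_tree <- function(p, max_depth = 4L, root_cover = 32L) {
  nodes <- list(feature = integer(0), threshold = numeric(0),
                left = integer(0), right = integer(0),
                missing_left = logical(0), value = numeric(0),
                cover = numeric(0))
  add_node <- function(cover, depth) {
    i <- length(nodes$feature) + 1L
    nodes$feature[i] <<- -1L; nodes$threshold[i] <<- 0
    nodes$left[i] <<- -1L; nodes$right[i] <<- -1L
    nodes$missing_left[i] <<- TRUE; nodes$value[i] <<- 0
    nodes$cover[i] <<- cover
    if (depth >= max_depth || cover < 4L || runif(1) < 0.25) {
      nodes$value[i] <<- round(rnorm(1, 0, 10), 3)
      return(i)
    }
    cl <- sample(seq_len(cover - 1L), 1L)
    nodes$feature[i] <<- sample.int(p, 1L) - 1L
    nodes$threshold[i] <<- round(runif(1, -1, 1), 3)
    nodes$missing_left[i] <<- runif(1) < 0.5
    nodes$left[i] <<- add_node(cl, depth + 1L) - 1L
    nodes$right[i] <<- add_node(cover - cl, depth + 1L) - 1L
    i
  }
  add_node(root_cover, 0L)
  make_shap_tree(nodes$feature, nodes$threshold, nodes$left, nodes$right,
                 nodes$missing_left, nodes$value, nodes$cover,
                 paste0("f", seq_len(p)))
}

random_x <- function(p, na_prob = 0.15) {
  x <- runif(p, -1, 1)
  x[runif(p) < na_prob] <- NA
  setNames(x, paste0("f", seq_len(p)))
}

# oracle: enumerate every root-to-leaf path; the leaf's weight is the product
# over the path's internal nodes of either the routing indicator (feature
# conditioned) or the child cover fraction (feature marginalised)
oracle_path_expectation <- function(tree, x, S) {
  nd <- tree$nodes
  if (is.character(S)) S <- match(S, tree$feature_names)
  route_child <- function(i) {
    f <- nd$feature[i] + 1L
    v <- x[f]
    go_left <- if (is.na(v)) nd$missing_left[i] else v < nd$threshold[i]
    if (go_left) nd$left[i] else nd$right[i]
  }
  total <- 0
  walk <- function(i, w) {
    if (nd$feature[i + 1L] < 0L) {
      total <<- total + w * nd$value[i + 1L]
      return(invisible())
    }
    f <- nd$feature[i + 1L] + 1L
    for (child in c(nd$left[i + 1L], nd$right[i + 1L])) {
      wc <- if (f %in% S) {
        if (child == route_child(i + 1L)) 1 else 0
      } else nd$cover[child + 1L] / nd$cover[i + 1L]
      if (wc > 0) walk(child, w * wc)
    }
  }
  walk(0L, 1)
  total
}

oracle_ensemble_v <- function(model, x, S) {
  vs <- vapply(model$trees, function(tr) oracle_path_expectation(tr, x, S),
               numeric(1))
  if (model$mode == "forest") mean(vs)
  else model$base_score + model$learning_rate * sum(vs)
}

# oracle: full 2^M subset enumeration of the Shapley formula
oracle_shapley <- function(model, x) {
  if (inherits(model, "shap_tree")) model <- shapcov:::as_tree_ensemble(model)
  p <- length(x)
  vcache <- numeric(2^p)
  for (mask in 0:(2^p - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1L))) > 0L)
    vcache[mask + 1L] <- oracle_ensemble_v(model, x, S)
  }
  phi <- numeric(p)
  for (i in seq_len(p)) {
    bit_i <- bitwShiftL(1L, i - 1L)
    for (mask in 0:(2^p - 1L)) {
      if (bitwAnd(mask, bit_i) > 0L) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1L))) > 0L)
      w <- factorial(s) * factorial(p - s - 1L) / factorial(p)
      phi[i] <- phi[i] +
        w * (vcache[bitwOr(mask, bit_i) + 1L] - vcache[mask + 1L])
    }
  }
  list(phi0 = vcache[1L], phi = setNames(phi, names(x)))
}

# small random regression data with optional missing cells
random_regression_data <- function(n, p, na_prob = 0.1) {
  X <- matrix(runif(n * p, -1, 1), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  X[matrix(runif(n * p) < na_prob, n, p)] <- NA
  y <- 2 * ifelse(is.na(X[, 1]), 0, X[, 1]) + rnorm(n, 0, 0.3)
  list(X = X, y = y)
}

# feature table wrapper for raw matrices (tests bypass the study plumbing)
as_feature_table <- function(X, patient = seq_len(nrow(X)), occasion = 1L,
                             missing = NULL) {
  if (is.null(missing)) missing <- is.na(X)
  structure(list(X = X, missing = missing,
                 ids = data.frame(patient = patient, occasion = occasion),
                 levels = list()),
            class = "feature_table")
}

neutral_truth <- function(...) {
  truth_model(b_cl = 0, b_v1 = 0, age_exp = 0, blood_o_cl = 1, bdd_cl = 1,
              bdd_v1 = 1, bmi_v1 = 1, ...)
}
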