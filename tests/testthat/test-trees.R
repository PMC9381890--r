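test_that("constant response yields a single leaf predicting that constant", {
  X <- matrix(runif(40), 20, 2)
  tr <- fit_regression_tree(X, rep(3.5, 20))
  expect_equal(length(tr$nodes$feature), 1L)
  expect_equal(tr$nodes$feature, -1L)
  expect_equal(unname(predict(tr, X)), rep(3.5, 20))
})

test_that("depth-1 tree on a step function splits at the midpoint", {
  tr <- fit_regression_tree(matrix(c(1, 2, 3, 4), ncol = 1), c(0, 0, 1, 1),
                            max_depth = 1, min_leaf = 1)
  expect_equal(tr$nodes$threshold[1], 2.5)
  expect_equal(sort(tr$nodes$value[tr$nodes$feature < 0][
    c(1, 2)]), c(0, 1))
  expect_equal(unname(predict(tr, matrix(c(1.2, 3.9), ncol = 1))), c(0, 1))
})

test_that("boosted leaf values are shrunk mean residuals", {
  # single leaf, lambda = 0: -G/H = mean residual
  tr <- fit_regression_tree(matrix(1:4, ncol = 1), mode = "boosted",
                            g = -c(1, 2, 3, 4), h = rep(1, 4),
                            max_depth = 0)
  expect_equal(tr$nodes$value, 2.5)
  # lambda shrinks toward zero
  tr2 <- fit_regression_tree(matrix(1:4, ncol = 1), mode = "boosted",
                             g = -c(1, 2, 3, 4), h = rep(1, 4),
                             max_depth = 0, lambda = 1)
  expect_equal(tr2$nodes$value, 10 / 5)
})

test_that("cover bookkeeping is conserved at every internal node", {
  set.seed(31)
  dat <- random_regression_data(150, 5)
  for (model in list(fit_forest(dat$X, dat$y, n_trees = 5, seed = 2),
                     fit_boosted(dat$X, dat$y, n_rounds = 5, seed = 2))) {
    for (tr in model$trees) {
      nd <- tr$nodes
      internal <- which(nd$feature >= 0)
      expect_equal(nd$cover[internal],
                   nd$cover[nd$left[internal] + 1L] +
                     nd$cover[nd$right[internal] + 1L])
      expect_true(all(is.finite(nd$value[nd$feature < 0])))
      expect_true(all(is.finite(nd$threshold[internal])))
    }
  }
})

test_that("missing rows follow the recorded default direction", {
  set.seed(8)
  # x2 missing for a block whose y is clearly low: default must route left
  x1 <- runif(60)
  x2 <- c(runif(40, 0.5, 1), rep(NA, 20))
  y <- ifelse(is.na(x2), -5, 10 * x2)
  X <- cbind(x1 = x1, x2 = x2)
  tr <- fit_regression_tree(X, y, max_depth = 2, min_leaf = 5)
  pred_na <- predict(tr, cbind(x1 = 0.5, x2 = NA))
  expect_lt(unname(pred_na), 0)
})

test_that("ensembles are deterministic under a seed and degrade gracefully", {
  set.seed(3)
  dat <- random_regression_data(80, 4)
  f1 <- fit_forest(dat$X, dat$y, n_trees = 10, seed = 99)
  f2 <- fit_forest(dat$X, dat$y, n_trees = 10, seed = 99)
  expect_identical(f1$trees, f2$trees)
  expect_identical(predict(f1, dat$X), predict(f2, dat$X))
  b1 <- fit_boosted(dat$X, dat$y, n_rounds = 8, seed = 99)
  b2 <- fit_boosted(dat$X, dat$y, n_rounds = 8, seed = 99)
  expect_identical(predict(b1, dat$X), predict(b2, dat$X))
  # single unbagged full-feature tree == plain CART
  f3 <- fit_forest(dat$X, dat$y, n_trees = 1, bootstrap = FALSE,
                   mtry = ncol(dat$X), seed = 1)
  cart <- fit_regression_tree(dat$X, dat$y)
  expect_equal(predict(f3, dat$X), predict(cart, dat$X))
  expect_error(fit_forest(dat$X, dat$y, n_trees = 0), "n_trees")
  expect_error(fit_boosted(dat$X, dat$y, learning_rate = 0),
               "learning rate")
})

test_that("zero boosting rounds predict the base score", {
  set.seed(4)
  dat <- random_regression_data(30, 3)
  b0 <- fit_boosted(dat$X, dat$y, n_rounds = 0)
  expect_equal(unname(predict(b0, dat$X)), rep(mean(dat$y), 30))
})

test_that("boosted training loss is non-increasing and can interpolate", {
  set.seed(12)
  n <- 40
  X <- matrix(runif(n * 3), n, 3)
  y <- sin(4 * X[, 1]) + X[, 2]
  losses <- sapply(c(1, 5, 20, 60), function(k) {
    b <- fit_boosted(X, y, n_rounds = k, seed = 1)
    mean((predict(b, X) - y)^2)
  })
  expect_true(all(diff(losses) <= 1e-12))
  full <- fit_boosted(X, y, n_rounds = 80, learning_rate = 1,
                      max_depth = 12, seed = 1)
  expect_lt(mean((predict(full, X) - y)^2), 1e-10)
})

test_that("held-out error beats the intercept-only predictor on signal", {
  set.seed(77)
  n <- 240
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- 3 * X[, 1] + rnorm(n, 0, 0.5)
  tr_rows <- 1:160; te_rows <- 161:240
  for (fit in list(fit_forest(X[tr_rows, ], y[tr_rows], n_trees = 50,
                              seed = 5),
                   fit_boosted(X[tr_rows, ], y[tr_rows], n_rounds = 50,
                               seed = 5))) {
    mse <- mean((predict(fit, X[te_rows, ]) - y[te_rows])^2)
    expect_lt(mse, var(y[te_rows]))
    expect_lt(mean(abs(predict(fit, X[te_rows, ]) - y[te_rows])),
              mean(abs(mean(y[tr_rows]) - y[te_rows])))
  }
})

test_that("permutation importance separates signal from noise", {
  set.seed(6)
  n <- 150
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- 2 * X[, 2]
  fit <- fit_forest(X, y, n_trees = 40, seed = 3)
  sc <- permutation_importance(fit, X, y, repeats = 5, seed = 9)
  expect_equal(names(which.max(sc)), "f2")
  expect_true(all(sc["f2"] > sc[-2]))
  # a feature absent from every split scores ~0
  fit1 <- fit_regression_tree(X[, 1:2], y, max_depth = 2)
  fit1w <- shapcov:::as_tree_ensemble(fit1)
  fit1w$feature_names <- colnames(X)
  sc1 <- permutation_importance(fit1w, X, y, repeats = 5, seed = 9)
  expect_lt(abs(sc1["f4"]), 1e-12)
})

test_that("JSON serialization round-trips models exactly", {
  set.seed(10)
  dat <- random_regression_data(60, 4)
  for (model in list(fit_forest(dat$X, dat$y, n_trees = 6, seed = 1),
                     fit_boosted(dat$X, dat$y, n_rounds = 6, seed = 1))) {
    path <- tempfile(fileext = ".json")
    ensemble_to_json(model, path)
    back <- ensemble_from_json(path)
    expect_identical(predict(back, dat$X), predict(model, dat$X))
    expect_equal(back$trees[[3]]$nodes$cover, model$trees[[3]]$nodes$cover)
    unlink(path)
  }
})

test_that("forest predictions track an established implementation", {
  skip_if_not_installed("randomForest")
  set.seed(20)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- 2 * X[, 1] - X[, 3]^2 + rnorm(n, 0, 0.3)
  mine <- fit_forest(X, y, n_trees = 100, seed = 1)
  ref <- randomForest::randomForest(X, y, ntree = 100)
  r <- cor(predict(mine, X), predict(ref, X))
  message(sprintf("forest agreement with randomForest: r = %.3f", r))
  expect_gt(r, 0.9)
})
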