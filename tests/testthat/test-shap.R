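test_that("path expectation reproduces the worked fixture values", {
  tr <- fixture_tree()
  x <- c(f1 = 1, f2 = 0)  # routed right at f1, to the 20-leaf at f2
  expect_equal(path_expectation(tr, x, integer(0)), 16)
  expect_equal(path_expectation(tr, x, "f2"), 14)
  expect_equal(path_expectation(tr, x, "f1"), 25)
  expect_equal(path_expectation(tr, x, c("f1", "f2")), 20)
})

test_that("exact Shapley on the fixture tree gives 7.5 / -3.5", {
  tr <- fixture_tree()
  d <- exact_shapley(tr, c(f1 = 1, f2 = 0))
  expect_equal(d$phi0, 16)
  expect_equal(unname(d$phi["f1"]), 7.5)
  expect_equal(unname(d$phi["f2"]), -3.5)
  expect_equal(d$phi0 + sum(d$phi), d$fx)
  expect_equal(d$fx, 20)
})

test_that("conditioning on all features equals the prediction, on none the cover-weighted leaf mean", {
  set.seed(11)
  for (rep in 1:20) {
    p <- sample(2:5, 1)
    tr <- random_tree(p)
    x <- random_x(p)
    expect_equal(path_expectation(tr, x, seq_len(p)),
                 unname(predict(tr, matrix(x, nrow = 1))))
    nd <- tr$nodes
    leaves <- nd$feature < 0
    expect_equal(path_expectation(tr, x, integer(0)),
                 sum(nd$value[leaves] * nd$cover[leaves]) / nd$cover[1])
  }
})

test_that("path expectation matches the weighted-path oracle on random trees", {
  set.seed(21)
  for (rep in 1:200) {
    p <- sample(2:6, 1)
    tr <- random_tree(p)
    x <- random_x(p)
    for (k in 1:3) {
      S <- sample(seq_len(p), sample(0:p, 1))
      expect_equal(path_expectation(tr, x, S),
                   oracle_path_expectation(tr, x, S), tolerance = 1e-12)
    }
  }
})

test_that("ensemble Shapley values match full subset enumeration", {
  set.seed(33)
  for (rep in 1:8) {
    p <- sample(3:5, 1)
    dat <- random_regression_data(30, p)
    model <- if (rep %% 2 == 0)
      fit_forest(dat$X, dat$y, n_trees = 4, seed = rep)
    else fit_boosted(dat$X, dat$y, n_rounds = 4, max_depth = 3, seed = rep)
    x <- random_x(p)
    d <- exact_shapley(model, x)
    orc <- oracle_shapley(model, x)
    expect_equal(d$phi0, orc$phi0, tolerance = 1e-10)
    expect_equal(unname(d$phi), unname(orc$phi), tolerance = 1e-10)
  }
})

test_that("efficiency, dummy and symmetry axioms hold", {
  set.seed(5)
  # efficiency on random ensembles with missing values in x
  for (rep in 1:5) {
    dat <- random_regression_data(80, 6)
    fo <- fit_forest(dat$X, dat$y, n_trees = 20, seed = rep)
    X <- dat$X[1:20, ]
    res <- shapcov:::ensemble_shap_matrix(fo, X)
    expect_lt(max(abs(res$phi0 + rowSums(res$phi) - predict(fo, X))), 1e-8)
  }
  # dummy: a feature used in no tree has phi identically zero
  dat <- random_regression_data(60, 4, na_prob = 0)
  Xd <- cbind(dat$X, dummy = rnorm(60))
  fo <- fit_forest(Xd[, 1:4], dat$y, n_trees = 10, seed = 1)
  fo$feature_names <- colnames(Xd)
  fo$trees <- lapply(fo$trees, function(tr) {
    tr$feature_names <- colnames(Xd); tr
  })
  d <- exact_shapley(fo, Xd[3, ])
  expect_identical(unname(d$phi["dummy"]), 0)
  # symmetry: two trees identical up to swapping duplicated features
  t1 <- make_shap_tree(c(0L, -1L, -1L), c(0.5, 0, 0), c(1L, -1L, -1L),
                       c(2L, -1L, -1L), rep(TRUE, 3), c(0, -4, 6),
                       c(10, 5, 5), c("a", "b"))
  t2 <- make_shap_tree(c(1L, -1L, -1L), c(0.5, 0, 0), c(1L, -1L, -1L),
                       c(2L, -1L, -1L), rep(TRUE, 3), c(0, -4, 6),
                       c(10, 5, 5), c("a", "b"))
  ens <- shapcov:::new_tree_ensemble("forest", list(t1, t2), c("a", "b"))
  d <- exact_shapley(ens, c(a = 0.9, b = 0.9))
  expect_equal(unname(d$phi["a"]), unname(d$phi["b"]))
})

test_that("per-fold SHAP pools to one decomposition per occasion", {
  set.seed(9)
  dat <- random_regression_data(40, 4, na_prob = 0)
  folds <- rep(1:4, each = 10)
  parts <- lapply(1:4, function(f) {
    tr <- folds != f
    fit <- fit_forest(dat$X[tr, ], dat$y[tr], n_trees = 10, seed = f,
                      row_ids = paste0(which(tr), ":1"))
    shap_for_fold(fit, as_feature_table(dat$X[!tr, , drop = FALSE],
                                        patient = which(!tr)), fold = f)
  })
  pooled <- pool_shap(parts)
  expect_equal(nrow(pooled), 40 * 4)
  expect_equal(sort(unique(pooled$patient)), 1:40)
  # each occasion in exactly one fold
  occ <- unique(pooled[, c("patient", "fold")])
  expect_equal(nrow(occ), 40)
  # pooled mean of (phi0 + sum phi) equals pooled mean prediction
  tot <- tapply(pooled$shap_value, pooled$patient, sum) +
    tapply(pooled$phi0, pooled$patient, mean)
  expect_equal(mean(tot), mean(tapply(pooled$prediction, pooled$patient,
                                      mean)), tolerance = 1e-10)
})

test_that("train/test overlap raises a leakage error", {
  set.seed(2)
  dat <- random_regression_data(20, 3, na_prob = 0)
  fit <- fit_forest(dat$X, dat$y, n_trees = 5, seed = 1,
                    row_ids = paste0(1:20, ":1"))
  expect_error(shap_for_fold(fit, as_feature_table(dat$X[1:5, ])),
               "leakage")
})

test_that("covariate ranking is ordered, tie-broken alphabetically, row-order invariant", {
  pooled <- data.frame(
    patient = rep(1:4, 3), occasion = 1, fold = 1,
    covariate = rep(c("b", "a", "zero"), each = 4),
    covariate_value = 0, missing_flag = FALSE,
    shap_value = c(1, -1, 2, -2, 1, -1, 2, -2, 0, 0, 0, 0),
    phi0 = 5, prediction = 5)
  class(pooled) <- c("pooled_shap", "data.frame")
  rk <- rank_covariates(pooled)
  expect_equal(rk$covariate, c("a", "b", "zero"))
  expect_equal(rk$mean_abs_shap, c(1.5, 1.5, 0))
  rk2 <- rank_covariates(pooled[sample(nrow(pooled)), ])
  expect_equal(rk, rk2)
})

test_that("individual breakdown accumulates from phi0 to the prediction", {
  d <- structure(list(phi0 = 100, phi = c(w = 30, a = -10, b = 2, c = 0),
                      fx = 122, M = 4), class = "shap_decomposition")
  bd <- individual_breakdown(d)
  expect_equal(bd$covariate, c("w", "a", "b", "c"))
  expect_equal(bd$cumulative[4], d$fx)
  flat <- structure(list(phi0 = 7, phi = c(a = 0, b = 0), fx = 7, M = 2),
                    class = "shap_decomposition")
  expect_equal(individual_breakdown(flat)$cumulative, c(7, 7))
})

test_that("combined SHAP sums per row and recovers fx - phi0 for all covariates", {
  pooled <- data.frame(
    patient = rep(1:2, each = 3), occasion = 1, fold = 1,
    covariate = rep(c("weight", "age", "bmi"), 2),
    covariate_value = c(70, 40, 25, 20, 5, 16),
    missing_flag = FALSE,
    shap_value = c(2, -1, 0.5, -3, 1, 0.25),
    phi0 = 10, prediction = c(rep(11.5, 3), rep(8.25, 3)))
  class(pooled) <- c("pooled_shap", "data.frame")
  cw <- combine_shap(pooled, c("weight", "age"))
  expect_equal(cw$combined_shap, c(1, -2))
  expect_equal(cw$index_value, c(70, 20))
  all3 <- combine_shap(pooled, c("weight", "age", "bmi"), by = "age")
  expect_equal(all3$combined_shap,
               unique(pooled$prediction) - unique(pooled$phi0))
  expect_equal(all3$by_value, c(40, 5))
  expect_error(combine_shap(pooled, "nope"), "unknown covariate")
})

test_that("SHAP values agree with the reference tree-SHAP implementation", {
  skip_if_not_installed("xgboost")
  set.seed(14)
  n <- 120; p <- 5
  # feature values exactly representable in float32, so the reference
  # model's quantised thresholds route identically after export
  X <- matrix(sample(seq(0, 1, by = 1 / 16), n * p, replace = TRUE), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  y <- 3 * X[, 1] - 2 * X[, 2] * X[, 3] + rnorm(n, 0, 0.1)
  bst <- xgboost::xgb.train(
    params = list(max_depth = 3, eta = 0.3, base_score = 0.5,
                  objective = "reg:squarederror"),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = 10)
  contrib <- predict(bst, xgboost::xgb.DMatrix(X[1:15, ]),
                     predcontrib = TRUE)
  dump <- xgboost::xgb.model.dt.tree(model = bst)
  trees <- lapply(split(dump, dump$Tree), function(td) {
    td <- as.data.frame(td)
    id2idx <- setNames(seq_len(nrow(td)) - 1L, td$ID)
    leaf <- td$Feature == "Leaf"
    make_shap_tree(
      feature = ifelse(leaf, -1L, match(td$Feature, colnames(X)) - 1L),
      threshold = ifelse(leaf, 0, td$Split),
      left = ifelse(leaf, -1L, id2idx[td$Yes]),
      right = ifelse(leaf, -1L, id2idx[td$No]),
      missing_left = ifelse(leaf, TRUE, td$Missing == td$Yes),
      value = ifelse(leaf, td$Gain, 0),
      cover = td$Cover, feature_names = colnames(X))
  })
  ens <- shapcov:::new_tree_ensemble("boosted", trees, colnames(X),
                                     base_score = 0.5, learning_rate = 1)
  for (i in 1:15) {
    d <- exact_shapley(ens, X[i, ])
    expect_equal(unname(d$phi), unname(contrib[i, 1:p]), tolerance = 1e-6)
    expect_equal(d$phi0, unname(contrib[i, "(Intercept)"]),
                 tolerance = 1e-6)
  }
})
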