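#' @title Full covariate-analysis pipeline
#'
#' @description Orchestrates the method end to end: simulate (or read) a
#'   study, estimate per-occasion empirical Bayes CL and V1, build the
#'   13-covariate feature table, run a patient-grouped 10-fold
#'   cross-validation of a tree ensemble per target parameter, compute exact
#'   SHAP values on every test fold, pool them, and derive covariate curves
#'   and parametric form fits.
#'
#' @name pipeline
NULL

dataset_columns <- c("ID", "OCC", "TIME", "EVID", "AMT", "RATE", "DV", "MDV")

#' Write a study dataset as a NONMEM-style CSV
#'
#' Missing cells are written as `"."`; numerics are written with enough
#' digits to round-trip exactly.
#'
#' @param study a `study_data` object (or its `records` data frame).
#' @param path output CSV path.
#' @param truth_path optional path for the ground-truth table (true etas and
#'   parameters), when present.
#' @export
write_dataset <- function(study, path, truth_path = NULL) {
  rec <- if (inherits(study, "study_data")) study$records else study
  out <- rec
  for (j in names(out)) {
    v <- out[[j]]
    if (is.numeric(v)) v <- sprintf("%.17g", v)
    v <- as.character(v)
    v[is.na(out[[j]]) | v == "NA"] <- "."
    out[[j]] <- v
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path) && inherits(study, "study_data") &&
      !is.null(study$truth))
    write.csv(study$truth, truth_path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a NONMEM-style study CSV
#'
#' Expected header: `ID, OCC, TIME, EVID, AMT, RATE, DV, MDV` plus covariate
#' columns; `"."` or empty cells are missing. All validation violations are
#' collected and reported together: missing mandatory columns, negative
#' times, dose rows carrying an observed value, occasions without any dose,
#' covariates varying within an occasion.
#'
#' @param path CSV path.
#' @return a `study_data` object (with `truth = NULL`).
#' @export
read_dataset <- function(path) {
  rec <- read.csv(path, na.strings = c(".", "", "NA"),
                  stringsAsFactors = FALSE)
  problems <- character(0)
  missing_cols <- setdiff(dataset_columns, names(rec))
  if (length(missing_cols))
    problems <- c(problems, paste("missing mandatory column(s):",
                                  paste(missing_cols, collapse = ", ")))
  if (!length(missing_cols)) {
    bad_t <- which(rec$TIME < 0)
    if (length(bad_t))
      problems <- c(problems, paste("negative TIME at row(s):",
                                    paste(head(bad_t, 10L), collapse = ", ")))
    bad_dv <- which(rec$EVID == 1L & !is.na(rec$DV))
    if (length(bad_dv))
      problems <- c(problems, paste("dose row(s) carrying DV at row(s):",
                                    paste(head(bad_dv, 10L), collapse = ", ")))
    key <- paste(rec$ID, rec$OCC, sep = ":")
    has_dose <- tapply(rec$EVID == 1L, key, any)
    if (any(!has_dose))
      problems <- c(problems,
                    paste("occasion(s) without any dose:",
                          paste(head(names(has_dose)[!has_dose], 10L),
                                collapse = ", ")))
    cov_cols <- intersect(covariate_names(), names(rec))
    for (cc in cov_cols) {
      nvar <- tapply(rec[[cc]], key, function(v)
        length(unique(v[!is.na(v)])) > 1L || anyNA(v) && any(!is.na(v)))
      if (any(nvar))
        problems <- c(problems,
                      paste0("covariate '", cc,
                             "' varies within occasion(s): ",
                             paste(head(names(nvar)[nvar], 5L),
                                   collapse = ", ")))
    }
  }
  if (length(problems))
    stop("dataset validation failed:\n  - ",
         paste(problems, collapse = "\n  - "))
  if (is.character(rec$bleeding_complication))
    rec$bleeding_complication <- as.logical(rec$bleeding_complication)
  keys <- unique(rec[, c("ID", "OCC")])
  cov_cols <- intersect(covariate_names(), names(rec))
  covs <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- rec[rec$ID == keys$ID[i] & rec$OCC == keys$OCC[i], , drop = FALSE]
    cbind(data.frame(patient = keys$ID[i], occasion = keys$OCC[i]),
          sub[1L, cov_cols, drop = FALSE], row.names = NULL)
  }))
  structure(list(records = rec, truth = NULL, covariates = covs),
            class = "study_data")
}

categorical_levels <- function() {
  list(center = c("1", "2", "3", "4", "5"),
       blood_group = c("non-O", "O"),
       concentrate = c("non-BDD", "BDD-rFVIII"),
       surgical_risk = c("low", "high"),
       severity = c("moderate", "severe"),
       bleeding_complication = c("FALSE", "TRUE"))
}

#' Build the ML feature table from a covariate table
#'
#' One row per occasion, 13 covariates: continuous columns as numeric,
#' categorical columns as positive integer codes (level order recorded);
#' missing cells are `NA` at this stage. Identifiers and true random effects
#' are never part of the features.
#'
#' @param covs covariate data frame (from `study_data$covariates`), or a
#'   `study_data` object.
#' @return object of class `feature_table`: numeric matrix `X`, logical
#'   `missing` matrix, `ids` data frame, `levels` list.
#' @export
feature_table <- function(covs) {
  if (inherits(covs, "study_data")) covs <- covs$covariates
  lev <- categorical_levels()
  cols <- covariate_names()
  n <- nrow(covs)
  X <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (j in cols) {
    v <- covs[[j]]
    if (j %in% names(lev)) {
      code <- match(as.character(v), lev[[j]])
      X[, j] <- as.numeric(code)
    } else {
      X[, j] <- as.numeric(v)
    }
  }
  structure(list(X = X, missing = is.na(X),
                 ids = data.frame(patient = covs$patient,
                                  occasion = covs$occasion),
                 levels = lev),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d occasions x %d covariates, %d missing cells>\n",
              nrow(x$X), ncol(x$X), sum(x$missing)))
  invisible(x)
}

subset_feature_table <- function(table, rows) {
  structure(list(X = table$X[rows, , drop = FALSE],
                 missing = table$missing[rows, , drop = FALSE],
                 ids = table$ids[rows, , drop = FALSE],
                 levels = table$levels),
            class = "feature_table")
}

#' Impute a feature table (leakage-safe)
#'
#' `"mean_category"` replaces missing continuous values by the mean of the
#' *training rows only* (applied to train and test alike) and maps missing
#' categorical cells to a dedicated category (code 0). `"native"` leaves the
#' table untouched, for ensembles that route missing values natively.
#'
#' @param table a [feature_table()].
#' @param strategy `"mean_category"` or `"native"`.
#' @param training row indices (or logical mask) whose values define the
#'   imputation means; defaults to all rows (dataset-level imputation).
#' @return an imputed `feature_table`.
#' @export
impute_features <- function(table, strategy = c("mean_category", "native"),
                            training = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "native") return(table)
  if (is.null(training)) training <- seq_len(nrow(table$X))
  X <- table$X
  lev <- table$levels
  for (j in colnames(X)) {
    nas <- is.na(X[, j])
    if (!any(nas)) next
    if (j %in% names(lev)) {
      X[nas, j] <- 0
    } else {
      m <- mean(X[training, j], na.rm = TRUE)
      if (!is.finite(m))
        stop("continuous column '", j, "' entirely missing in training rows")
      X[nas, j] <- m
    }
  }
  out <- table
  out$X <- X
  out
}

#' Patient-grouped cross-validation plan
#'
#' Patients are shuffled with the seed and dealt round-robin into `k` folds;
#' occasions inherit their patient's fold, so no patient ever appears in more
#' than one fold.
#'
#' @param ids data frame with `patient` and `occasion` columns (or a
#'   `feature_table` / `study_data`).
#' @param k fold count.
#' @param seed integer seed.
#' @return data frame (patient, occasion, fold), class `cv_plan`.
#' @export
make_cv_plan <- function(ids, k = 10L, seed = 1L) {
  if (inherits(ids, "study_data")) ids <- feature_table(ids)$ids
  if (inherits(ids, "feature_table")) ids <- ids$ids
  patients <- unique(ids$patient)
  if (k < 2L) stop("k must be >= 2")
  if (k > length(patients)) stop("k exceeds the number of patients")
  set.seed(as.integer(seed))
  shuffled <- sample(patients)
  fold_of <- setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  out <- data.frame(patient = ids$patient, occasion = ids$occasion,
                    fold = unname(fold_of[as.character(ids$patient)]))
  class(out) <- c("cv_plan", "data.frame")
  out
}

#' Prediction accuracy metrics
#'
#' MAE is computed per fold and summarised as mean +/- SD across folds;
#' R-squared is `1 - SSE/SST` on the pooled test predictions.
#'
#' @param predictions,truths aligned numeric vectors.
#' @param folds fold label per element.
#' @return list: `mae_mean`, `mae_sd`, `r2`, `per_fold` data frame.
#' @export
metrics_report <- function(predictions, truths, folds) {
  if (length(predictions) != length(truths) ||
      length(predictions) != length(folds))
    stop("predictions, truths and folds must have equal length")
  mae <- tapply(abs(predictions - truths), folds, mean)
  sse <- sum((predictions - truths)^2)
  sst <- sum((truths - mean(truths))^2)
  list(mae_mean = mean(mae),
       mae_sd = if (length(mae) > 1L) sd(mae) else 0,
       r2 = 1 - sse / sst,
       per_fold = data.frame(fold = as.integer(names(mae)),
                             mae = as.numeric(mae)))
}

fit_cv_model <- function(model, X, y, ml_params, seed, row_ids) {
  if (model %in% c("boosted", "boosted_native")) {
    args <- utils::modifyList(
      list(X = X, y = y, seed = seed, row_ids = row_ids), ml_params)
    do.call(fit_boosted, args)
  } else {
    args <- utils::modifyList(
      list(X = X, y = y, seed = seed, row_ids = row_ids), ml_params)
    do.call(fit_forest, args)
  }
}

#' Run the full covariate-analysis study
#'
#' Per target parameter (CL and V1, fitted independently): empirical Bayes
#' estimates become the ML targets, a patient-grouped k-fold CV fits the
#' chosen tree ensemble per training fold, test-fold predictions and exact
#' SHAP values are pooled, covariate curves and parametric form fits are
#' derived, and concentration-level accuracy is computed by solving the
#' two-compartment model with the test-set predicted CL/V1 (Q and V2 at
#' their fixed population values, which carry no random effects).
#'
#' @param study a `study_data` object; if `NULL`, one is simulated from
#'   `truth` and `design`.
#' @param truth,design generator configuration used when `study` is `NULL`.
#' @param pop the fixed base [population_model()] for EBE estimation.
#' @param model `"forest"`, `"boosted"` (imputed features) or
#'   `"boosted_native"` (native missing routing).
#' @param k_folds CV fold count.
#' @param seed master seed; every stage seed derives from it.
#' @param ml_params named list of overrides for [fit_forest()] /
#'   [fit_boosted()].
#' @param span LOESS span for covariate curves.
#' @param fold_aware_imputation impute with training-fold means (`TRUE`,
#'   leakage-safe default) or dataset-level means (`FALSE`).
#' @param per_patient_ebe share one eta pair across a patient's occasions.
#' @return object of class `study_result`: `ebe`, `metrics` (per target +
#'   concentration RMSE), `pooled` (per-target `pooled_shap`), `ranking`,
#'   `curves`, `form_fits`, `plan`.
#' @export
run_study <- function(study = NULL, truth = truth_model(),
                      design = study_design(), pop = population_model(),
                      model = c("forest", "boosted", "boosted_native"),
                      k_folds = 10L, seed = 1L, ml_params = list(),
                      span = 0.75, fold_aware_imputation = TRUE,
                      per_patient_ebe = FALSE) {
  model <- match.arg(model)
  seeds <- local({ set.seed(as.integer(seed)); sample.int(2^30, 4L) })
  if (is.null(study)) study <- simulate_study(truth, design, seed = seeds[1L])

  ebe <- estimate_ebe_table(pop, study, per_patient = per_patient_ebe)
  ft <- feature_table(study)
  key_ft <- paste(ft$ids$patient, ft$ids$occasion, sep = ":")
  key_ebe <- paste(ebe$patient, ebe$occasion, sep = ":")
  ebe <- ebe[match(key_ft, key_ebe), , drop = FALSE]

  plan <- make_cv_plan(ft, k = k_folds, seed = seeds[2L])
  fold_of <- plan$fold[match(key_ft, paste(plan$patient, plan$occasion,
                                           sep = ":"))]
  strategy <- if (model == "boosted_native") "native" else "mean_category"

  targets <- list(cl = ebe$cl_i, v1 = ebe$v1_i)
  set.seed(seeds[3L])
  fit_seeds <- matrix(sample.int(2^30, 2L * k_folds), nrow = 2L)
  result <- list()
  for (ti in seq_along(targets)) {
    tname <- names(targets)[ti]
    y <- targets[[tname]]
    pred <- rep(NA_real_, length(y))
    shap_parts <- vector("list", k_folds)
    for (f in seq_len(k_folds)) {
      tr_rows <- which(fold_of != f)
      te_rows <- which(fold_of == f)
      if (!length(te_rows)) next
      imp <- if (fold_aware_imputation)
        impute_features(ft, strategy, training = tr_rows)
      else impute_features(ft, strategy)
      fit <- fit_cv_model(model, imp$X[tr_rows, , drop = FALSE], y[tr_rows],
                          ml_params, seed = fit_seeds[ti, f],
                          row_ids = key_ft[tr_rows])
      pred[te_rows] <- predict(fit, imp$X[te_rows, , drop = FALSE])
      shap_parts[[f]] <- shap_for_fold(fit, subset_feature_table(imp, te_rows),
                                       fold = f)
    }
    pooled <- pool_shap(shap_parts[!vapply(shap_parts, is.null, logical(1))])
    attr(pooled, "levels") <- ft$levels
    result[[tname]] <- list(pred = pred,
                            metrics = metrics_report(pred, y, fold_of),
                            pooled = pooled)
  }

  conc <- concentration_metrics(study, pop, result$cl$pred, result$v1$pred,
                                key_ft)

  curves <- list(); fits <- list(); ranking <- list()
  cont <- setdiff(covariate_names(), names(ft$levels))
  for (tname in names(result)) {
    pooled <- result[[tname]]$pooled
    ranking[[tname]] <- rank_covariates(pooled)
    curves[[tname]] <- lapply(setNames(cont, cont), function(cc)
      tryCatch(covariate_curve(pooled, cc, span = span),
               error = function(e) NULL))
    fits[[tname]] <- list(
      weight_power = tryCatch(fit_power_form(curves[[tname]]$weight),
                              error = function(e) NULL),
      weight_linear = tryCatch(fit_linear_form(curves[[tname]]$weight),
                               error = function(e) NULL),
      bmi_threshold = tryCatch(threshold_scan(curves[[tname]]$bmi),
                               error = function(e) NULL))
  }

  structure(list(study = study, ebe = ebe,
                 metrics = list(
                   cl = result$cl$metrics, v1 = result$v1$metrics,
                   concentration_rmse = conc),
                 predictions = data.frame(patient = ft$ids$patient,
                                          occasion = ft$ids$occasion,
                                          fold = fold_of,
                                          cl_ebe = ebe$cl_i,
                                          v1_ebe = ebe$v1_i,
                                          cl_pred = result$cl$pred,
                                          v1_pred = result$v1$pred),
                 pooled = list(cl = result$cl$pooled,
                               v1 = result$v1$pooled),
                 ranking = ranking, curves = curves, form_fits = fits,
                 plan = plan, model = model, seed = seed),
            class = "study_result")
}

# concentration RMSE with ML-predicted CL/V1 and fixed Q/V2, per patient
concentration_metrics <- function(study, pop, cl_pred, v1_pred, key_ft) {
  recs <- study_records(study)
  obs <- list(); prd <- list()
  for (r in recs) {
    key <- paste(r$patient, r$occasion, sep = ":")
    i <- match(key, key_ft)
    if (is.na(i) || is.na(cl_pred[i]) || length(r$times) == 0L) next
    params <- pk_params(cl_pred[i], v1_pred[i], pop$typical$q,
                        pop$typical$v2)
    f <- predict_concentration(params, r$doses, r$times, r$baseline)
    pid <- as.character(r$patient)
    obs[[pid]] <- c(obs[[pid]], r$dv)
    prd[[pid]] <- c(prd[[pid]], f)
  }
  res <- rmse_concentrations(obs, prd)
  list(mean = res$mean, sd = res$sd)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result: %s model, %d occasions, %d folds>\n",
              x$model, nrow(x$predictions), max(x$plan$fold)))
  cat(sprintf("  CL : MAE %.1f +/- %.1f ml/h (R2 = %.2f)\n",
              x$metrics$cl$mae_mean, x$metrics$cl$mae_sd, x$metrics$cl$r2))
  cat(sprintf("  V1 : MAE %.0f +/- %.0f ml (R2 = %.2f)\n",
              x$metrics$v1$mae_mean, x$metrics$v1$mae_sd, x$metrics$v1$r2))
  cat(sprintf("  concentration RMSE: %.3f +/- %.3f IU/ml\n",
              x$metrics$concentration_rmse$mean,
              x$metrics$concentration_rmse$sd))
  cat(sprintf("  top covariate (CL): %s; (V1): %s\n",
              x$ranking$cl$covariate[1L], x$ranking$v1$covariate[1L]))
  invisible(x)
}
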