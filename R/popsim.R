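#' @title Synthetic peri-operative hemophilia-A study generator
#'
#' @description Emulates the structure of the motivating study — 119 patients,
#'   197 surgical procedures, 13 covariates with realistic distributions and
#'   missingness fractions, peri-operative bolus/continuous FVIII dosing
#'   targeting guideline peak windows (0.80-1.00 IU/ml at 0-24 h, 0.50-0.80 at
#'   24-120 h, 0.30-0.50 beyond) — under a configurable, KNOWN ground-truth
#'   covariate model, so that every downstream stage (EBE, ML fit, SHAP,
#'   curve inference) can be validated by recovering the truth.
#'
#'   Missingness is injected completely at random, at the *measurement* level
#'   only: the true covariate model never sees a missing marker.
#'
#' @name popsim
NULL

#' Ground-truth covariate model for simulation
#'
#' Individual parameters are
#' \deqn{CL = TVCL\,(W/70)^{b_{CL}}\,(\max(age,12)/40)^{c_{age}}\,
#'   m_{O}\,m_{BDD}\,e^{\eta_{CL}}, \qquad
#'   V_1 = TVV_1\,(W/70)^{b_{V1}}\,m_{BMI>25}\,m_{BDD,V1}\,e^{\eta_{V1}}}
#' with Q and V2 fixed at typical values (no IIV, mirroring a base model with
#' random effects on CL and V1 only).
#'
#' @param cl,v1,q,v2 typical values (defaults: study base-model estimates).
#' @param b_cl,b_v1 allometric weight exponents on CL and V1.
#' @param age_exp age exponent on CL, applied as `(max(age,12)/40)^age_exp`
#'   (capped below 12 years so the model is continuous in age).
#' @param blood_o_cl CL multiplier for blood group O.
#' @param bdd_cl,bdd_v1 multipliers for B-domain-deleted concentrate.
#' @param bmi_threshold,bmi_v1 V1 multiplier applied above the BMI threshold.
#' @param omega_cl,omega_v1 residual (unexplained) log-scale IIV SDs; may
#'   instead be given as %CV fractions via `omega_cl_cv`/`omega_v1_cv`
#'   (converted exactly by [cv_to_omega()]).
#' @param omega_cl_cv,omega_v1_cv optional %CV alternatives to the omegas.
#' @param sigma_add,sigma_prop residual error SDs of the observation model
#'   `y = f (1 + eps2) + eps1`.
#' @return object of class `truth_model`.
#' @export
truth_model <- function(cl = 163, v1 = 3030, q = 56.9, v2 = 1270,
                        b_cl = 0.75, b_v1 = 1.0, age_exp = -0.2,
                        blood_o_cl = 1.2, bdd_cl = 1.1, bdd_v1 = 1.15,
                        bmi_threshold = 25, bmi_v1 = 0.8,
                        omega_cl = 0.25, omega_v1 = 0.42,
                        omega_cl_cv = NULL, omega_v1_cv = NULL,
                        sigma_add = 0.08, sigma_prop = 0.17) {
  if (!is.null(omega_cl_cv)) omega_cl <- cv_to_omega(omega_cl_cv)
  if (!is.null(omega_v1_cv)) omega_v1 <- cv_to_omega(omega_v1_cv)
  mult <- c(blood_o_cl, bdd_cl, bdd_v1, bmi_v1)
  if (any(mult <= 0)) stop("config error: multipliers must be > 0")
  if (omega_cl < 0 || omega_v1 < 0 || sigma_add < 0 || sigma_prop < 0)
    stop("config error: omega and sigma must be >= 0")
  structure(list(typical = pk_params(cl, v1, q, v2), b_cl = b_cl,
                 b_v1 = b_v1, age_exp = age_exp, blood_o_cl = blood_o_cl,
                 bdd_cl = bdd_cl, bdd_v1 = bdd_v1,
                 bmi_threshold = bmi_threshold, bmi_v1 = bmi_v1,
                 omega_cl = omega_cl, omega_v1 = omega_v1,
                 sigma_add = sigma_add, sigma_prop = sigma_prop),
            class = "truth_model")
}

#' Covariate sampling configuration
#'
#' Defaults emulate the motivating study's reported distributions: medians/ranges for the
#' continuous covariates, observed category frequencies, and missingness
#' fractions (BMI 10.7%, blood group 13.2%, concentrate 1.5%, VWF:Ag 40.1%,
#' VWF:Act 50.3%). Age, weight and BMI are drawn from a Gaussian copula with
#' the given correlation matrix over truncated-normal marginals.
#'
#' @param corr_awb 3x3 correlation matrix of the Gaussian-copula noise behind
#'   (age, weight, BMI); correlation beyond what the growth curves already
#'   induce.
#' @param age mixture marginal: a `p_child` fraction of procedures belongs to
#'   children (uniform on `child_min`-`child_max` years, emulating a
#'   paediatric-center contribution), the rest to adults (truncated normal).
#'   The study range (0.24-77.7 years, weights down to 5 kg) requires real
#'   paediatric mass.
#' @param weight growth-curve marginal: median weight
#'   `ref * (age/mature_age)^exponent` below `mature_age`, `ref` above, with
#'   log-normal noise `sdlog`, clamped to `lower`-`upper`.
#' @param bmi growth-curve marginal `base + span * min(age, mature_age) /
#'   mature_age` with log-normal noise, clamped.
#' @param center_probs probabilities of the five treatment centers (must sum
#'   to 1).
#' @param p_blood_o probability of blood group O among observed values.
#' @param p_bdd probability of B-domain-deleted concentrate among observed.
#' @param p_high_risk,p_severe,p_bleeding category probabilities.
#' @param miss_bmi,miss_blood,miss_conc,miss_vwf_ag,miss_vwf_act missingness
#'   fractions.
#' @param redraw_per_occasion draw occasion-level covariates anew per
#'   procedure (`TRUE`) or once per patient (`FALSE`).
#' @export
covariate_config <- function(
    corr_awb = matrix(c(1, 0.3, 0.2, 0.3, 1, 0.6, 0.2, 0.6, 1), 3, 3),
    age = list(p_child = 0.25, child_min = 0.24, child_max = 16,
               adult_mean = 45, adult_sd = 16, adult_max = 77.7),
    weight = list(ref = 72, exponent = 0.55, mature_age = 18, sdlog = 0.18,
                  lower = 5, upper = 111),
    bmi = list(base = 16, span = 8, mature_age = 30, sdlog = 0.12,
               lower = 13.6, upper = 32.8),
    center_probs = c(0.203, 0.228, 0.386, 0.081, 0.102),
    p_blood_o = 80 / 162, p_bdd = 28 / 194,
    p_high_risk = 0.492, p_severe = 0.746, p_bleeding = 0.152,
    miss_bmi = 0.107, miss_blood = 0.132, miss_conc = 0.015,
    miss_vwf_ag = 0.401, miss_vwf_act = 0.503,
    redraw_per_occasion = TRUE) {
  if (abs(sum(center_probs) - 1) > 1e-6)
    stop("config error: center_probs must sum to 1")
  probs <- c(p_blood_o, p_bdd, p_high_risk, p_severe, p_bleeding,
             miss_bmi, miss_blood, miss_conc, miss_vwf_ag, miss_vwf_act)
  if (any(probs < 0 | probs > 1))
    stop("config error: probabilities must lie in [0, 1]")
  ev <- eigen(corr_awb, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("config error: correlation matrix not positive semi-definite")
  as.list(environment())
}

# age from a copula draw: child/adult mixture through the quantile transform
age_from_z <- function(z, m) {
  u <- pnorm(z)
  child <- u < m$p_child
  age <- numeric(length(z))
  age[child] <- m$child_min +
    (u[child] / m$p_child) * (m$child_max - m$child_min)
  ua <- (u[!child] - m$p_child) / (1 - m$p_child)
  pl <- pnorm(m$child_max, m$adult_mean, m$adult_sd)
  pu <- pnorm(m$adult_max, m$adult_mean, m$adult_sd)
  age[!child] <- qnorm(pl + ua * (pu - pl), m$adult_mean, m$adult_sd)
  age
}

weight_from_age <- function(age, z, m) {
  med <- ifelse(age < m$mature_age,
                m$ref * (age / m$mature_age)^m$exponent, m$ref)
  pmin(pmax(med * exp(m$sdlog * z), m$lower), m$upper)
}

bmi_from_age <- function(age, z, m) {
  med <- m$base + m$span * pmin(age, m$mature_age) / m$mature_age
  pmin(pmax(med * exp(m$sdlog * z), m$lower), m$upper)
}

#' Names of the 13 analysis covariates
#' @export
covariate_names <- function() {
  c("weight", "age", "bmi", "center", "blood_group", "concentrate",
    "surgical_risk", "severity", "blood_loss", "bleeding_complication",
    "fviii_baseline", "vwf_ag", "vwf_act")
}

#' Sample a covariate table
#'
#' One row per procedure (occasion). Blood group, severity and treatment
#' center are drawn once per patient; the remaining covariates are drawn per
#' occasion (or per patient when `config$redraw_per_occasion` is `FALSE`).
#' The returned table carries the *observed* values (with `NA` where
#' missingness was injected); the complete pre-missingness table — which the
#' ground-truth model reads — is attached as `attr(, "complete")`.
#'
#' @param n_patients,n_procedures counts (`n_procedures >= n_patients`).
#' @param seed integer seed.
#' @param config a [covariate_config()].
#' @return data frame with patient, occasion and the 13 covariate columns.
#' @export
sample_covariates <- function(n_patients, n_procedures, seed,
                              config = covariate_config()) {
  if (n_procedures < n_patients)
    stop("config error: n_procedures must be >= n_patients")
  set.seed(as.integer(seed))
  extra <- if (n_procedures > n_patients)
    sample.int(n_patients, n_procedures - n_patients, replace = TRUE)
  else integer(0)
  patient <- sort(c(seq_len(n_patients), extra))
  occasion <- stats::ave(patient, patient, FUN = seq_along)
  n <- n_procedures

  # patient-level categoricals, repeated over occasions
  center_p <- sample(1:5, n_patients, replace = TRUE,
                     prob = config$center_probs)
  blood_p <- ifelse(runif(n_patients) < config$p_blood_o, "O", "non-O")
  severe_p <- ifelse(runif(n_patients) < config$p_severe,
                     "severe", "moderate")
  base_p <- ifelse(severe_p == "severe", runif(n_patients, 0, 0.005),
                   runif(n_patients, 0.01, 0.05))

  # occasion-level draws (possibly shared within patient)
  n_draw <- if (config$redraw_per_occasion) n else n_patients
  L <- chol(config$corr_awb)
  z <- matrix(rnorm(3 * n_draw), n_draw, 3) %*% L
  age_d <- age_from_z(z[, 1], config$age)
  weight_d <- weight_from_age(age_d, z[, 2], config$weight)
  bmi_d <- bmi_from_age(age_d, z[, 3], config$bmi)
  conc_d <- ifelse(runif(n_draw) < config$p_bdd, "BDD-rFVIII", "non-BDD")
  risk_d <- ifelse(runif(n_draw) < config$p_high_risk, "high", "low")
  bleed_d <- runif(n_draw) < config$p_bleeding
  loss_d <- ifelse(runif(n_draw) < 0.55, 0,
                   pmin(exp(rnorm(n_draw, log(300), 1.2)), 6700))
  idx <- if (config$redraw_per_occasion) seq_len(n) else patient

  # VWF levels, lower for blood group O (co-varying realism only; the truth
  # model never reads them)
  vwf_mean <- ifelse(blood_p[patient] == "O", 105, 130)
  vwf_ag_d <- pmin(pmax(rnorm(n, vwf_mean, 40), 25), 250)
  vwf_act_d <- pmin(pmax(vwf_ag_d * 1.08 * exp(rnorm(n, 0, 0.07)), 24), 270)

  complete <- data.frame(
    patient = patient, occasion = occasion,
    weight = weight_d[idx], age = age_d[idx], bmi = bmi_d[idx],
    center = center_p[patient], blood_group = blood_p[patient],
    concentrate = conc_d[idx], surgical_risk = risk_d[idx],
    severity = severe_p[patient], blood_loss = loss_d[idx],
    bleeding_complication = bleed_d[idx],
    fviii_baseline = base_p[patient],
    vwf_ag = vwf_ag_d, vwf_act = vwf_act_d,
    stringsAsFactors = FALSE)

  observed <- complete
  inject <- function(col, frac) {
    miss <- runif(n) < frac
    observed[[col]][miss] <<- NA
  }
  inject("bmi", config$miss_bmi)
  inject("blood_group", config$miss_blood)
  inject("concentrate", config$miss_conc)
  inject("vwf_ag", config$miss_vwf_ag)
  inject("vwf_act", config$miss_vwf_act)
  attr(observed, "complete") <- complete
  observed
}

#' Individual PK parameters under the ground truth
#'
#' @param truth a [truth_model()].
#' @param cov one covariate row (complete, pre-missingness values).
#' @param eta numeric pair `(eta_CL, eta_V1)` of log-scale random effects.
#' @return a [pk_params()] object.
#' @export
individual_parameters <- function(truth, cov, eta = c(0, 0)) {
  tv <- truth$typical
  cl <- tv$cl * (cov$weight / 70)^truth$b_cl *
    (pmax(cov$age, 12) / 40)^truth$age_exp *
    (if (identical(cov$blood_group, "O")) truth$blood_o_cl else 1) *
    (if (identical(cov$concentrate, "BDD-rFVIII")) truth$bdd_cl else 1) *
    exp(eta[1L])
  v1 <- tv$v1 * (cov$weight / 70)^truth$b_v1 *
    (if (cov$bmi > truth$bmi_threshold) truth$bmi_v1 else 1) *
    (if (identical(cov$concentrate, "BDD-rFVIII")) truth$bdd_v1 else 1) *
    exp(eta[2L])
  if (!is.finite(cl) || cl <= 0 || !is.finite(v1) || v1 <= 0)
    stop("config error: non-positive individual parameter")
  pk_params(cl, v1, tv$q, tv$v2)
}

#' Study design configuration
#'
#' Defaults mirror the study structure: 119 patients / 197 procedures, a
#' loading bolus sized to the 0-24 h peak target given individual V1,
#' maintenance boluses (or a continuous infusion for a fraction of occasions)
#' holding the declining guideline windows, and sampling denser over the
#' first 24 h (16 samples/occasion, close to the study's 3350/197 = 17).
#'
#' @param n_patients,n_procedures study size.
#' @param sample_times observation-time grid (h).
#' @param peak_target,maint_target,late_target guideline mid-window targets
#'   (IU/ml) for 0-24 h, 24-120 h and beyond.
#' @param redose_times maintenance bolus times (h) for bolus-only occasions.
#' @param infusion_fraction fraction of occasions managed with a continuous
#'   infusion after the loading bolus.
#' @param infusion_duration infusion length (h).
#' @param covariates a [covariate_config()].
#' @export
study_design <- function(n_patients = 119L, n_procedures = 197L,
                         sample_times = c(0.5, 1, 2, 4, 8, 12, 16, 24, 30,
                                          36, 48, 60, 72, 96, 120, 144),
                         peak_target = 0.9, maint_target = 0.65,
                         late_target = 0.4,
                         redose_times = c(24, 48, 72, 96, 120),
                         infusion_fraction = 0.3, infusion_duration = 120,
                         covariates = covariate_config()) {
  if (n_patients < 1L || n_procedures < n_patients)
    stop("config error: need n_procedures >= n_patients >= 1")
  if (length(sample_times) == 0L)
    stop("config error: empty sampling design")
  as.list(environment())
}

#' Simulate a complete synthetic study
#'
#' @param truth a [truth_model()].
#' @param design a [study_design()].
#' @param seed integer master seed; identical seeds give bit-identical
#'   studies.
#' @return object of class `study_data`: `records` (NONMEM-style rectangular
#'   data frame: ID, OCC, TIME, EVID, AMT, RATE, DV, MDV + covariate
#'   columns), `truth` (patient, occasion, true etas and parameters),
#'   `covariates` (observed covariate table), plus the generating configs.
#' @export
simulate_study <- function(truth = truth_model(), design = study_design(),
                           seed = 1L) {
  set.seed(as.integer(seed))
  cov_seed <- sample.int(2^30, 1)
  covs <- sample_covariates(design$n_patients, design$n_procedures,
                            seed = cov_seed, config = design$covariates)
  complete <- attr(covs, "complete")
  n_occ <- nrow(covs)
  set.seed(as.integer(seed) + 1L)

  eta <- cbind(rnorm(n_occ, 0, truth$omega_cl),
               rnorm(n_occ, 0, truth$omega_v1))
  use_inf <- runif(n_occ) < design$infusion_fraction

  rec_list <- vector("list", n_occ)
  truth_rows <- vector("list", n_occ)
  for (i in seq_len(n_occ)) {
    cc <- complete[i, , drop = FALSE]
    params <- individual_parameters(truth, cc, eta[i, ])
    baseline <- cc$fviii_baseline
    load_amt <- max((design$peak_target - baseline) * params$v1, 1)
    dt <- data.frame(time = 0, amount = load_amt, duration = 0)
    if (use_inf[i]) {
      dt <- rbind(dt, data.frame(time = 0,
                                 amount = design$maint_target * params$cl *
                                   design$infusion_duration,
                                 duration = design$infusion_duration))
    } else {
      for (tk in design$redose_times) {
        target <- if (tk < 120) design$maint_target else design$late_target
        c_pre <- predict_concentration(params, as_dose_events(dt), tk,
                                       baseline)
        amt <- (target - c_pre) * params$v1
        if (amt > 10) dt <- rbind(dt, data.frame(time = tk, amount = amt,
                                                 duration = 0))
      }
    }
    doses <- as_dose_events(dt)
    tt <- design$sample_times
    f <- predict_concentration(params, doses, tt, baseline)
    y <- f * (1 + rnorm(length(f), 0, truth$sigma_prop)) +
      rnorm(length(f), 0, truth$sigma_add)
    y <- pmax(y, 0)
    rec_list[[i]] <- list(patient = covs$patient[i],
                          occasion = covs$occasion[i],
                          doses = dt, times = tt, dv = y,
                          baseline = baseline)
    truth_rows[[i]] <- data.frame(
      patient = covs$patient[i], occasion = covs$occasion[i],
      eta_cl = eta[i, 1], eta_v1 = eta[i, 2],
      cl_true = params$cl, v1_true = params$v1)
  }

  records <- do.call(rbind, lapply(seq_len(n_occ), function(i) {
    r <- rec_list[[i]]
    dose_rows <- data.frame(
      ID = r$patient, OCC = r$occasion, TIME = r$doses$time, EVID = 1L,
      AMT = r$doses$amount,
      RATE = ifelse(r$doses$duration > 0,
                    r$doses$amount / r$doses$duration, 0),
      DV = NA_real_, MDV = 1L)
    obs_rows <- data.frame(
      ID = r$patient, OCC = r$occasion, TIME = r$times, EVID = 0L,
      AMT = NA_real_, RATE = 0, DV = r$dv, MDV = 0L)
    out <- rbind(dose_rows, obs_rows)
    out <- out[order(out$TIME, -out$EVID), , drop = FALSE]
    cbind(out, covs[i, covariate_names(), drop = FALSE], row.names = NULL)
  }))
  rownames(records) <- NULL

  structure(list(records = records,
                 truth = do.call(rbind, truth_rows),
                 covariates = covs,
                 truth_model = truth, design = design, seed = seed),
            class = "study_data")
}

as_dose_events <- function(df) {
  structure(df, class = c("dose_events", "data.frame"))
}

#' @export
print.study_data <- function(x, ...) {
  cat(sprintf(
    "<study_data: %d patients, %d procedures, %d observations>\n",
    length(unique(x$records$ID)),
    nrow(unique(x$records[, c("ID", "OCC")])),
    sum(x$records$EVID == 0L)))
  invisible(x)
}

#' Split a study into per-occasion subject records
#'
#' @param study a `study_data` object (simulated or read from CSV).
#' @return list of [subject_record()]s, one per occasion.
#' @export
study_records <- function(study) {
  rec <- if (inherits(study, "study_data")) study$records else study
  keys <- unique(rec[, c("ID", "OCC")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- rec[rec$ID == keys$ID[i] & rec$OCC == keys$OCC[i], , drop = FALSE]
    dr <- sub[sub$EVID == 1L, , drop = FALSE]
    obs <- sub[sub$EVID == 0L, , drop = FALSE]
    doses <- data.frame(
      time = dr$TIME, amount = dr$AMT,
      duration = ifelse(dr$RATE > 0, dr$AMT / dr$RATE, 0))
    bl <- if ("fviii_baseline" %in% names(sub))
      sub$fviii_baseline[1L] else 0
    if (is.na(bl)) bl <- 0
    subject_record(as_dose_events(doses), obs$TIME, obs$DV, baseline = bl,
                   patient = keys$ID[i], occasion = keys$OCC[i])
  })
}
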