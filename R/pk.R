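#' @title Two-compartment intravenous kinetics
#'
#' @description Analytic (bi-exponential) solution of the linear
#'   two-compartment model
#'   \deqn{dA_1/dt = in(t) - (k_{10}+k_{12})A_1 + k_{21}A_2, \quad
#'         dA_2/dt = k_{12}A_1 - k_{21}A_2}
#'   with \eqn{k_{10} = CL/V_1}, \eqn{k_{12} = Q/V_1}, \eqn{k_{21} = Q/V_2},
#'   under arbitrary bolus and constant-rate infusion schedules by
#'   superposition. Central concentration is `baseline + A1(t)/V1`
#'   (additive endogenous level). Units are fixed: ml, h, IU.
#'
#' @name pk_twocomp
NULL

#' Two-compartment parameter set
#'
#' @param cl clearance (ml/h, > 0).
#' @param v1 central volume (ml, > 0).
#' @param q inter-compartmental clearance (ml/h, >= 0; 0 degenerates to a
#'   one-compartment model).
#' @param v2 peripheral volume (ml, > 0).
#' @return object of class `pk_params`.
#' @export
pk_params <- function(cl, v1, q, v2) {
  vals <- c(cl = cl, v1 = v1, q = q, v2 = v2)
  if (!all(is.finite(vals))) stop("invalid input: non-finite PK parameters")
  if (cl <= 0 || v1 <= 0 || v2 <= 0 || q < 0)
    stop("invalid input: CL, V1, V2 must be > 0 and Q >= 0")
  structure(as.list(vals), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("<pk_params: CL = %g ml/h, V1 = %g ml, Q = %g ml/h, V2 = %g ml>\n",
              x$cl, x$v1, x$q, x$v2))
  invisible(x)
}

#' Dose events
#'
#' @param time start times (h, >= 0).
#' @param amount dose amounts (IU, > 0).
#' @param duration infusion durations (h, >= 0); 0 encodes a bolus, > 0 a
#'   constant-rate infusion of `amount/duration` IU/h.
#' @return data frame of class `dose_events`.
#' @export
dose_events <- function(time = numeric(0), amount = numeric(0),
                        duration = 0) {
  n <- max(length(time), length(amount))
  duration <- rep_len(duration, n)
  if (any(time < 0) || any(amount <= 0) || any(duration < 0))
    stop("invalid input: dose times/durations must be >= 0 and amounts > 0")
  structure(data.frame(time = as.numeric(time), amount = as.numeric(amount),
                       duration = as.numeric(duration)),
            class = c("dose_events", "data.frame"))
}

# macro-constants of the bi-exponential solution; the repeated-eigenvalue
# case (measure zero) is displaced by a 1e-12 relative perturbation of k10
twocomp_roots <- function(params) {
  k10 <- params$cl / params$v1
  k12 <- params$q / params$v1
  k21 <- params$q / params$v2
  s <- k10 + k12 + k21
  disc <- s^2 - 4 * k10 * k21
  if (disc < 1e-24 * s^2) {
    k10 <- k10 * (1 + 1e-12)
    s <- k10 + k12 + k21
    disc <- s^2 - 4 * k10 * k21
  }
  rt <- sqrt(max(disc, 0))
  alpha <- (s + rt) / 2
  beta <- (s - rt) / 2
  # unit-bolus central amount: c_a e^(-alpha t) + c_b e^(-beta t)
  if (alpha == beta) stop("degenerate eigenvalues after perturbation")
  c_a <- (alpha - k21) / (alpha - beta)
  c_b <- (k21 - beta) / (alpha - beta)
  list(alpha = alpha, beta = beta, c_a = c_a, c_b = c_b)
}

#' Predict central-compartment concentrations
#'
#' @param params a [pk_params()] set.
#' @param doses a [dose_events()] data frame (possibly empty).
#' @param times sampling times (h), sorted ascending.
#' @param baseline endogenous level added to the prediction (IU/ml, >= 0).
#' @return numeric vector of concentrations (IU/ml), one per time.
#' @examples
#' p <- pk_params(cl = 163, v1 = 3030, q = 56.9, v2 = 1270)
#' predict_concentration(p, dose_events(0, 3000), times = c(1, 6, 24, 48))
#' @export
predict_concentration <- function(params, doses, times, baseline = 0) {
  if (!inherits(params, "pk_params")) stop("invalid input: params")
  if (is.unsorted(times)) stop("invalid input: times must be sorted ascending")
  if (any(!is.finite(times)) || any(times < 0))
    stop("invalid input: times must be finite and non-negative")
  if (!is.finite(baseline) || baseline < 0)
    stop("invalid input: baseline must be >= 0")
  a1 <- rep(0, length(times))
  if (!is.null(doses) && nrow(doses) > 0) {
    rts <- twocomp_roots(params)
    for (i in seq_len(nrow(doses))) {
      t0 <- doses$time[i]
      amt <- doses$amount[i]
      dur <- doses$duration[i]
      on <- times >= t0
      if (!any(on)) next
      tau <- times[on] - t0
      if (dur == 0) {
        a1[on] <- a1[on] + amt * (rts$c_a * exp(-rts$alpha * tau) +
                                  rts$c_b * exp(-rts$beta * tau))
      } else {
        rate <- amt / dur
        m <- pmin(tau, dur)
        contrib <- 0
        if (rts$c_a != 0)
          contrib <- contrib + (rts$c_a / rts$alpha) *
            (exp(-rts$alpha * (tau - m)) - exp(-rts$alpha * tau))
        if (rts$c_b != 0)
          contrib <- contrib + (rts$c_b / rts$beta) *
            (exp(-rts$beta * (tau - m)) - exp(-rts$beta * tau))
        a1[on] <- a1[on] + rate * contrib
      }
    }
  }
  baseline + a1 / params$v1
}

#' Per-individual concentration RMSE, summarised across individuals
#'
#' RMSE is computed per individual first; the mean and SD are then taken
#' across individuals (never pooled over all observations).
#'
#' @param observed,predicted either named lists of matched numeric vectors
#'   (one element per subject) or data frames with columns `patient` and
#'   `value` on matched time grids.
#' @return list with `mean`, `sd` (IU/ml) and the per-subject `rmse` vector.
#' @export
rmse_concentrations <- function(observed, predicted) {
  to_list <- function(x) {
    if (is.data.frame(x)) split(x$value, x$patient) else x
  }
  obs <- to_list(observed)
  prd <- to_list(predicted)
  if (!identical(sort(names(obs)), sort(names(prd))))
    stop("observed and predicted must cover the same subjects")
  prd <- prd[names(obs)]
  keep <- vapply(obs, length, integer(1)) > 0L
  if (any(!keep)) {
    warning(sprintf("excluding %d subject(s) with zero observations",
                    sum(!keep)))
    obs <- obs[keep]; prd <- prd[keep]
  }
  rmse <- mapply(function(o, p) {
    if (length(o) != length(p)) stop("mismatched time grids for a subject")
    sqrt(mean((o - p)^2))
  }, obs, prd)
  list(mean = mean(rmse), sd = if (length(rmse) > 1L) sd(rmse) else 0,
       rmse = rmse)
}
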