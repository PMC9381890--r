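#' @title From pooled SHAP values to functional forms
#'
#' @description Turns pooled (covariate value, SHAP value) pairs into
#'   functional-form evidence: a LOESS smooth per continuous covariate,
#'   per-level summaries for categorical covariates, and parametric fits
#'   (power law \eqn{a\,(w/w_{ref})^b + c}, linear, two-segment threshold
#'   step) with their residual SSEs. Candidate fits are reported side by
#'   side; no winner is declared automatically.
#'
#' @name curve_inference
NULL

#' Locally estimated scatterplot smoothing (LOESS)
#'
#' At each grid point the `ceiling(span * n)` nearest neighbours are fit by
#' weighted least squares of the requested degree with tricube weights
#' \eqn{w = (1 - (d/d_{max})^3)^3}; exact zero-distance duplicates receive
#' full weight. No robustness iterations are applied. If all neighbours share
#' one x value (zero bandwidth) the fit falls back to degree 0 locally.
#'
#' @param x,y data pairs.
#' @param span neighbourhood fraction in (0, 1].
#' @param degree local polynomial degree, 0 or 1.
#' @param grid evaluation points; default 100 equally spaced points over the
#'   observed range (no extrapolation).
#' @return data frame with columns `grid` and `smooth`.
#' @export
loess_curve <- function(x, y, span = 0.75, degree = 1L, grid = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (!degree %in% c(0L, 1L)) stop("degree must be 0 or 1")
  q <- ceiling(span * n)
  if (n < max(5L, q)) stop("too few points for LOESS")
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 100L)
  smooth <- vapply(grid, function(g) {
    d <- abs(x - g)
    dmax <- sort(d, partial = q)[q]
    nb <- which(d <= dmax)
    if (dmax == 0) return(mean(y[nb]))
    w <- (1 - (d[nb] / dmax)^3)^3
    if (sum(w) <= 0) w <- rep(1, length(nb))
    xs <- x[nb]; ys <- y[nb]
    if (degree == 0L) return(sum(w * ys) / sum(w))
    sw <- sum(w)
    xbar <- sum(w * xs) / sw
    sxx <- sum(w * (xs - xbar)^2)
    if (sxx <= 1e-12 * max(1, xbar^2))  # zero bandwidth: local degree 0
      return(sum(w * ys) / sw)
    beta <- sum(w * (xs - xbar) * ys) / sxx
    alpha <- sum(w * ys) / sw
    alpha + beta * (g - xbar)
  }, numeric(1))
  data.frame(grid = grid, smooth = smooth)
}

#' Covariate-SHAP curve for one continuous covariate
#'
#' Pools the (covariate value, SHAP value) pairs of one covariate, excludes
#' rows whose covariate was missing before imputation (their count is
#' recorded), and overlays a LOESS smooth on a 100-point grid over the
#' observed range.
#'
#' @param pooled a `pooled_shap` long table.
#' @param covariate covariate name.
#' @param span,degree LOESS settings (see [loess_curve()]).
#' @return object of class `covariate_curve`: raw `x`/`y` pairs, `grid`
#'   data frame, `span`, and `n_missing_excluded`.
#' @export
covariate_curve <- function(pooled, covariate, span = 0.75, degree = 1L) {
  rows <- pooled[pooled$covariate == covariate, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown covariate: ", covariate)
  miss <- rows$missing_flag | is.na(rows$covariate_value)
  kept <- rows[!miss, , drop = FALSE]
  grid <- loess_curve(kept$covariate_value, kept$shap_value, span = span,
                      degree = degree)
  structure(list(covariate = covariate, x = kept$covariate_value,
                 y = kept$shap_value, grid = grid, span = span,
                 n_missing_excluded = sum(miss)),
            class = "covariate_curve")
}

#' @export
print.covariate_curve <- function(x, ...) {
  cat(sprintf(
    "<covariate_curve: %s, %d points (%d missing excluded), span %.2f>\n",
    x$covariate, length(x$x), x$n_missing_excluded, x$span))
  invisible(x)
}

#' Per-level SHAP summary for a categorical covariate
#'
#' @param pooled a `pooled_shap` long table carrying a `levels` attribute
#'   (attached by [shap_for_fold()] via the feature table), or supply
#'   `levels` explicitly.
#' @param covariate covariate name (must be categorical).
#' @param levels optional character vector of level labels for codes 1..k.
#' @return data frame: level (including the dedicated `"missing"` level),
#'   mean_shap, sd_shap, n.
#' @export
categorical_effect <- function(pooled, covariate, levels = NULL) {
  lev_map <- attr(pooled, "levels")
  if (is.null(levels)) {
    if (is.null(lev_map) || !covariate %in% names(lev_map))
      stop("type error: '", covariate,
           "' is not a categorical covariate (no level map)")
    levels <- lev_map[[covariate]]
  }
  rows <- pooled[pooled$covariate == covariate, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown covariate: ", covariate)
  code <- rows$covariate_value
  lab <- ifelse(is.na(code) | code == 0, "missing", levels[pmax(code, 1L)])
  agg_m <- tapply(rows$shap_value, lab, mean)
  agg_s <- tapply(rows$shap_value, lab, function(v)
    if (length(v) > 1L) sd(v) else 0)
  agg_n <- tapply(rows$shap_value, lab, length)
  out <- data.frame(level = names(agg_m), mean_shap = as.numeric(agg_m),
                    sd_shap = as.numeric(agg_s),
                    n = as.integer(agg_n), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

power_sse <- function(b, w, y, w_ref) {
  z <- (w / w_ref)^b
  fit <- lm(y ~ z)
  list(sse = sum(fit$residuals^2), a = unname(coef(fit)[2L]),
       c = unname(coef(fit)[1L]))
}

#' Fit a power-law form to a covariate-SHAP curve
#'
#' Least squares of \eqn{a\,(w/w_{ref})^b + c} to the raw pooled pairs
#' (default) or the LOESS grid. For fixed exponent `b` the problem is linear
#' in `(a, c)`, so the exponent is profiled: a multi-start grid over `b`
#' (including 0.25, 0.75, 1, 1.5) followed by a 1-d refinement.
#'
#' @param curve a [covariate_curve()] (strictly positive covariate values).
#' @param w_ref reference covariate value (70 kg for body weight).
#' @param on fit on `"raw"` pairs or the `"grid"` smooth.
#' @return object of class `form_fit`: form `"power"`, parameters `a`, `b`,
#'   `c`, `sse`, `w_ref`.
#' @export
fit_power_form <- function(curve, w_ref = 70, on = c("raw", "grid")) {
  on <- match.arg(on)
  w <- if (on == "raw") curve$x else curve$grid$grid
  y <- if (on == "raw") curve$y else curve$grid$smooth
  if (any(w <= 0)) stop("power form needs strictly positive covariate values")
  bs <- sort(unique(c(0.25, 0.75, 1, 1.5, seq(0.05, 3, by = 0.05))))
  sses <- vapply(bs, function(b) power_sse(b, w, y, w_ref)$sse, numeric(1))
  b0 <- bs[which.min(sses)]
  opt <- optimize(function(b) power_sse(b, w, y, w_ref)$sse,
                  lower = max(b0 - 0.2, 1e-3), upper = b0 + 0.2,
                  tol = 1e-9)
  best <- power_sse(opt$minimum, w, y, w_ref)
  structure(list(form = "power", a = best$a, b = opt$minimum, c = best$c,
                 sse = best$sse, w_ref = w_ref),
            class = "form_fit")
}

#' Fit a straight line to a covariate-SHAP curve
#'
#' @inheritParams fit_power_form
#' @return object of class `form_fit`: form `"linear"`, `slope`,
#'   `intercept`, `sse`.
#' @export
fit_linear_form <- function(curve, on = c("raw", "grid")) {
  on <- match.arg(on)
  w <- if (on == "raw") curve$x else curve$grid$grid
  y <- if (on == "raw") curve$y else curve$grid$smooth
  fit <- lm(y ~ w)
  structure(list(form = "linear", slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 sse = sum(fit$residuals^2)),
            class = "form_fit")
}

#' @export
print.form_fit <- function(x, ...) {
  if (x$form == "power")
    cat(sprintf("<form_fit power: a=%.4g b=%.4g c=%.4g (ref %.4g), SSE %.4g>\n",
                x$a, x$b, x$c, x$w_ref, x$sse))
  else if (x$form == "linear")
    cat(sprintf("<form_fit linear: slope=%.4g intercept=%.4g, SSE %.4g>\n",
                x$slope, x$intercept, x$sse))
  else
    cat(sprintf("<form_fit threshold-step: break=%.4g step=%.4g, SSE %.4g>\n",
                x$breakpoint, x$step, x$sse))
  invisible(x)
}

#' Exhaustive breakpoint scan for a threshold (step) effect
#'
#' Scans candidate breakpoints minimising the SSE of a two-segment constant
#' fit (one mean on each side).
#'
#' @param curve a [covariate_curve()] with at least 20 points.
#' @param candidates candidate breakpoints; default: midpoints between
#'   consecutive distinct observed covariate values.
#' @param on fit on `"raw"` pairs or the `"grid"` smooth.
#' @return object of class `form_fit`: form `"threshold-step"`,
#'   `breakpoint`, `step` (right minus left mean), `sse`.
#' @export
threshold_scan <- function(curve, candidates = NULL,
                           on = c("raw", "grid")) {
  on <- match.arg(on)
  x <- if (on == "raw") curve$x else curve$grid$grid
  y <- if (on == "raw") curve$y else curve$grid$smooth
  if (length(x) < 20L) stop("threshold scan needs at least 20 points")
  ux <- sort(unique(x))
  if (length(ux) < 2L)
    stop("degenerate covariate: a single distinct value")
  if (is.null(candidates)) candidates <- (head(ux, -1) + ux[-1]) / 2
  best <- NULL
  for (cand in candidates) {
    l <- y[x <= cand]; r <- y[x > cand]
    if (length(l) == 0L || length(r) == 0L) next
    sse <- sum((l - mean(l))^2) + sum((r - mean(r))^2)
    if (is.null(best) || sse < best$sse)
      best <- list(breakpoint = cand, step = mean(r) - mean(l), sse = sse)
  }
  if (is.null(best)) stop("no admissible breakpoint among candidates")
  structure(c(list(form = "threshold-step"), best), class = "form_fit")
}
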