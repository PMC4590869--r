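#' Exoiohexol dose in micrograms
#'
#' The HPLC assay quantifies the exo stereoisomer only, so the administered
#' iohexol dose is corrected by the exoiohexol fraction (85% by default)
#' before it enters the dose/AUC clearance computation.
#'
#' @param dose_mg Total administered iohexol dose, mg.
#' @param exo_fraction Exoiohexol fraction of the formulation, in (0, 1].
#' @return Dose of exoiohexol in ug.
#' @examples
#' exo_dose(258.8)  # 4 kg cat at 64.7 mg/kg -> 219980 ug
#' @export
exo_dose <- function(dose_mg, exo_fraction = 0.85) {
  if (any(dose_mg <= 0)) abort("`dose_mg` must be strictly positive")
  if (any(exo_fraction <= 0 | exo_fraction > 1))
    abort("`exo_fraction` must lie in (0, 1]")
  dose_mg * exo_fraction * 1000
}

#' Back-extrapolated concentration at time zero
#'
#' An IV-bolus curve needs a concentration at t = 0 to close the area
#' between dosing and the first sample. C0 is taken from the log-linear
#' line through the first two (time, ln C) points; if the first two
#' concentrations do not decay, the first observed concentration is used
#' unchanged.
#'
#' @param times,conc Sampling times (min) and concentrations (ug/mL); only
#'   the first two points are used.
#' @return C0 in ug/mL.
#' @examples
#' back_extrapolate_c0(c(5, 30), c(432, 111))  # ~ 567
#' @export
back_extrapolate_c0 <- function(times, conc) {
  if (length(conc) < 2 || any(!is.finite(conc[1:2])) || any(conc[1:2] <= 0))
    abort("need two positive leading concentrations to back-extrapolate C0")
  if (conc[1] <= conc[2]) return(conc[1])
  lam <- log(conc[1] / conc[2]) / (times[2] - times[1])
  conc[1] * exp(lam * times[1])
}

#' Fit the terminal elimination slope
#'
#' Unweighted least squares on (t, ln C) over a tail of the profile gives
#' the terminal rate constant lambda_z. In `"auto"` mode every tail of
#' 3 to n-1 points ending at the last sample is fitted and the one with the
#' largest adjusted R-squared wins (ties go to the shortest tail); profiles
#' with only 3 points use their last 2, and 2-point profiles use both.
#' A fit is valid only if lambda_z > 0.
#'
#' @param times,conc Sampling times (min) and positive concentrations
#'   (ug/mL), censored values already removed.
#' @param n_terminal `"auto"` or an integer number of terminal points.
#' @return One-row tibble: `lambda_z` (1/min), `intercept_log` (ln ug/mL),
#'   `n_points_used`, `r_squared_adj`, `t_last` (min), `c_last` (ug/mL),
#'   `valid_fit` (logical). An all-tails-invalid profile returns
#'   `valid_fit = FALSE` with `lambda_z = NA`.
#' @examples
#' terminal_slope(c(240, 360, 480), 100 * exp(-0.02 * c(240, 360, 480)))
#' @export
terminal_slope <- function(times, conc, n_terminal = "auto") {
  n <- length(times)
  if (n < 2 || any(conc <= 0))
    abort("terminal fit needs at least 2 positive concentrations")
  candidate_sizes <- if (identical(n_terminal, "auto")) {
    if (n == 2) 2L else if (n == 3) 2L else seq(3L, n - 1L)
  } else {
    k <- as.integer(n_terminal)
    if (k < 2 || k > n) abort("`n_terminal` out of range")
    k
  }
  fits <- lapply(candidate_sizes, function(k) {
    idx <- seq(n - k + 1L, n)
    fit_loglinear_tail(times[idx], conc[idx])
  })
  ok <- vapply(fits, function(f) is.finite(f$lambda_z) && f$lambda_z > 0,
               logical(1))
  if (!any(ok)) {
    return(tibble(lambda_z = NA_real_, intercept_log = NA_real_,
                  n_points_used = NA_integer_, r_squared_adj = NA_real_,
                  t_last = times[n], c_last = conc[n], valid_fit = FALSE))
  }
  best <- fits[ok][[which.max(vapply(fits[ok], `[[`, numeric(1),
                                     "r_squared_adj"))]]
  tibble(lambda_z = best$lambda_z, intercept_log = best$intercept_log,
         n_points_used = best$n_points_used,
         r_squared_adj = best$r_squared_adj,
         t_last = times[n], c_last = conc[n], valid_fit = TRUE)
}

fit_loglinear_tail <- function(t, c) {
  y <- log(c)
  n <- length(t)
  fit <- lm(y ~ t)
  b <- coef(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  adj <- if (n > 2) 1 - (1 - r2) * (n - 1) / (n - 2) else r2
  list(lambda_z = unname(-b[2]), intercept_log = unname(b[1]),
       n_points_used = n, r_squared_adj = adj)
}

#' Linear trapezoidal AUC with a t = 0 anchor
#'
#' Classic linear trapezoid over \[0, t_last\] with the back-extrapolated
#' C0 prepended at t = 0. On a convex decay (any sum of decaying
#' exponentials) the linear rule overestimates the true area at finite n
#' and converges to it as the grid refines.
#'
#' @param times,conc Strictly increasing times (> 0, min) and
#'   concentrations (ug/mL).
#' @param c0 Concentration at t = 0, ug/mL.
#' @return AUC(0 - t_last), ug.min/mL.
#' @examples
#' auc_trapezoid(c(10, 20), c(5, 2.5), c0 = 10)  # 112.5
#' @export
auc_trapezoid <- function(times, conc, c0) {
  grid <- prepend_c0(times, conc, c0)
  sum((grid$c[-1] + grid$c[-length(grid$c)]) / 2 * diff(grid$t))
}

# Linear-up/log-down rule: logarithmic trapezoid on strictly decreasing
# positive segments (exact for a mono-exponential), linear elsewhere.
auc_linlog <- function(times, conc, c0) {
  grid <- prepend_c0(times, conc, c0)
  t <- grid$t; c <- grid$c
  total <- 0
  for (i in seq_len(length(t) - 1)) {
    dt <- t[i + 1] - t[i]
    if (c[i + 1] < c[i] && c[i + 1] > 0) {
      total <- total + (c[i] - c[i + 1]) / log(c[i] / c[i + 1]) * dt
    } else {
      total <- total + (c[i] + c[i + 1]) / 2 * dt
    }
  }
  total
}

prepend_c0 <- function(times, conc, c0) {
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing")
  if (times[1] <= 0) abort("all sampling times must be > 0 (C0 is prepended)")
  list(t = c(0, times), c = c(c0, conc))
}

#' Extrapolated AUC beyond the last sample
#'
#' The tail area from t_last to infinity is `c_last / lambda_z`, anchored
#' at the last observed concentration (not the fitted value at t_last).
#'
#' @param c_last Last observed concentration, ug/mL (>= 0).
#' @param lambda_z Terminal rate constant, 1/min (> 0).
#' @return Tail area, ug.min/mL.
#' @examples
#' auc_extrapolate(53.9, 0.0241)
#' @export
auc_extrapolate <- function(c_last, lambda_z) {
  if (!is.finite(lambda_z) || lambda_z <= 0)
    abort("`lambda_z` must be a positive finite rate", class = "ioxgfr_fit_error")
  c_last / lambda_z
}

#' Noncompartmental clearance for one concentration-time profile
#'
#' The full dose/AUC pipeline for a single subject under a single sampling
#' model: censored observations are dropped, C0 is back-extrapolated from
#' the first two points, the terminal slope is fitted, AUC(0-inf) is
#' assembled as trapezoid area plus `c_last / lambda_z`, and plasma
#' clearance is `exo_dose / AUC(0-inf) / BW` in mL/min/kg (numerically GFR
#' for a freely filtered marker).
#'
#' @param profile Data frame with columns `time_min`, `conc_ug_ml` and
#'   optionally `censored` (logical; censored rows are excluded).
#' @param dose_mg Total administered iohexol dose, mg.
#' @param bw_kg Body weight, kg.
#' @param exo_fraction Exoiohexol fraction of the dose.
#' @param model_name Label stored in the result (e.g. `"reference"`).
#' @param auc_method `"linlog"` (linear-up/log-down, default) or
#'   `"linear"` (plain linear trapezoid).
#' @param n_terminal Passed to [terminal_slope()].
#' @return One-row tibble: `model`, `gfr_ml_min_kg`, `auc_0_last`,
#'   `auc_extrap`, `auc_inf` (ug.min/mL), `extrap_pct` (%), `lambda_z`
#'   (1/min), `c0_ug_ml`, `n_terminal`, `r_squared_adj`, `n_obs`,
#'   `valid_fit`. When the terminal fit fails, the clearance and AUC
#'   fields are `NA` and `valid_fit` is `FALSE`.
#' @examples
#' prof <- tibble::tibble(time_min = c(5, 30, 60, 120, 240, 360, 480),
#'                        conc_ug_ml = 500 * exp(-0.01 * c(5, 30, 60, 120, 240, 360, 480)))
#' nca_clearance(prof, dose_mg = 258.8, bw_kg = 4)
#' @export
nca_clearance <- function(profile, dose_mg, bw_kg, exo_fraction = 0.85,
                          model_name = "reference",
                          auc_method = c("linlog", "linear"),
                          n_terminal = "auto") {
  auc_method <- match.arg(auc_method)
  if (bw_kg <= 0) abort("`bw_kg` must be strictly positive")
  stopifnot(all(c("time_min", "conc_ug_ml") %in% names(profile)))
  keep <- if ("censored" %in% names(profile)) !profile$censored else
    rep(TRUE, nrow(profile))
  keep <- keep & profile$conc_ug_ml > 0
  times <- profile$time_min[keep]
  conc <- profile$conc_ug_ml[keep]
  ord <- order(times)
  times <- times[ord]; conc <- conc[ord]
  invalid <- function() tibble(
    model = model_name, gfr_ml_min_kg = NA_real_, auc_0_last = NA_real_,
    auc_extrap = NA_real_, auc_inf = NA_real_, extrap_pct = NA_real_,
    lambda_z = NA_real_, c0_ug_ml = NA_real_, n_terminal = NA_integer_,
    r_squared_adj = NA_real_, n_obs = length(times), valid_fit = FALSE)
  if (length(times) < 2) return(invalid())
  fit <- terminal_slope(times, conc, n_terminal)
  if (!fit$valid_fit) return(invalid())
  c0 <- back_extrapolate_c0(times, conc)
  auc_last <- switch(auc_method,
                     linear = auc_trapezoid(times, conc, c0),
                     linlog = auc_linlog(times, conc, c0))
  auc_tail <- auc_extrapolate(fit$c_last, fit$lambda_z)
  auc_inf <- auc_last + auc_tail
  tibble(
    model = model_name,
    gfr_ml_min_kg = exo_dose(dose_mg, exo_fraction) / auc_inf / bw_kg,
    auc_0_last = auc_last,
    auc_extrap = auc_tail,
    auc_inf = auc_inf,
    extrap_pct = 100 * auc_tail / auc_inf,
    lambda_z = fit$lambda_z,
    c0_ug_ml = c0,
    n_terminal = fit$n_points_used,
    r_squared_adj = fit$r_squared_adj,
    n_obs = length(times),
    valid_fit = TRUE)
}

#' Flag results whose extrapolated AUC fraction is too large
#'
#' Clearance estimates relying heavily on the extrapolated tail are less
#' trustworthy; the conventional ceiling for the extrapolated share of
#' AUC(0-inf) is 25% (some guidelines use 20%). The comparison is
#' inclusive: a fraction exactly at the threshold passes. Failing subjects
#' are reported, not discarded.
#'
#' @param extrap_pct Extrapolated AUC percentage(s), or a tibble from
#'   [nca_clearance()] / [estimate_gfr()] with an `extrap_pct` column.
#' @param threshold Ceiling in percent (default 25).
#' @return Logical vector (`TRUE` = pass), or the input tibble with an
#'   `extrap_ok` column appended.
#' @examples
#' extrapolation_check(c(11.8, 25, 34.9))
#' @export
extrapolation_check <- function(extrap_pct, threshold = 25) {
  if (is.data.frame(extrap_pct)) {
    extrap_pct$extrap_ok <- extrap_pct$extrap_pct <= threshold
    return(extrap_pct)
  }
  extrap_pct <= threshold
}
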