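test_that("exoiohexol dose correction", {
  expect_equal(exo_dose(258.8), 219980)
  expect_equal(exo_dose(100, exo_fraction = 1), 100000)
  expect_error(exo_dose(0), "positive")
  expect_error(exo_dose(100, exo_fraction = 0), "exo_fraction")
})

test_that("C0 back-extrapolation through the first two log-linear points", {
  lam <- log(432 / 111) / 25
  expect_equal(back_extrapolate_c0(c(5, 30), c(432, 111)), 432 * exp(5 * lam))
  expect_equal(back_extrapolate_c0(c(5, 30), c(432, 111)), 567, tolerance = 1e-3)
  # exact exponential is recovered exactly
  expect_equal(back_extrapolate_c0(c(5, 30), 100 * exp(-0.01 * c(5, 30))), 100)
  # non-decaying leading pair falls back to the first observation
  expect_equal(back_extrapolate_c0(c(5, 30), c(100, 100)), 100)
  expect_equal(back_extrapolate_c0(c(5, 30), c(90, 100)), 90)
  expect_error(back_extrapolate_c0(5, 42), "two positive")
})

test_that("terminal slope is exact on log-linear data", {
  t <- c(240, 360, 480)
  fit <- terminal_slope(t, 100 * exp(-0.02 * t))
  expect_true(fit$valid_fit)
  expect_equal(fit$lambda_z, 0.02, tolerance = 1e-12)
  expect_equal(fit$r_squared_adj, 1, tolerance = 1e-9)
  expect_equal(fit$n_points_used, 2L)  # 3-point profile uses its last 2
  expect_equal(fit$c_last, 100 * exp(-0.02 * 480))

  # two-point mode, hand value ln(111/53.9)/30
  fit2 <- terminal_slope(c(30, 60), c(111, 53.9))
  expect_equal(fit2$lambda_z, log(111 / 53.9) / 30, tolerance = 1e-12)

  # generating rate recovered to machine precision over many tails
  set.seed(21)
  for (i in 1:20) {
    k <- runif(1, 0.001, 0.05)
    tt <- sort(runif(6, 60, 600))
    fit <- terminal_slope(tt, 50 * exp(-k * tt))
    expect_equal(fit$lambda_z, k, tolerance = 1e-10)
  }
})

test_that("a rising tail is flagged invalid rather than fitted", {
  fit <- terminal_slope(c(240, 360, 480), c(10, 12, 15))
  expect_false(fit$valid_fit)
  expect_true(is.na(fit$lambda_z))
})

test_that("auto tail selection maximises adjusted R-squared", {
  # biexponential: early points curve on the log scale, late points don't;
  # the chosen tail must exclude the distribution phase
  mk <- oracle_macro(3.4, 90, 160, 3, 64.7 * 1000 * 0.85)
  t <- c(5, 30, 60, 120, 240, 360, 480)
  fit <- terminal_slope(t, oracle_biexp(mk, t))
  expect_true(fit$valid_fit)
  expect_equal(fit$lambda_z, mk$beta, tolerance = 0.02)
  expect_lte(fit$n_points_used, 5)
})

test_that("linear trapezoid matches hand sums and elementary cases", {
  expect_equal(auc_trapezoid(c(10, 20), c(5, 2.5), c0 = 10), 112.5)
  expect_equal(auc_trapezoid(10, 5, c0 = 5), 50)       # constant over [0, 10]
  expect_equal(auc_trapezoid(10, 0, c0 = 0), 0)
  expect_error(auc_trapezoid(c(10, 5), c(1, 2), c0 = 3), "increasing")
})

test_that("linear trapezoid overestimates a convex decay and converges", {
  k <- 0.01; c0 <- 100
  f <- function(t) c0 * exp(-k * t)
  truth <- oracle_auc(f, 0, 480)
  for (n in c(8, 20, 50, 200)) {
    t <- seq(480 / n, 480, length.out = n)
    approx_auc <- auc_trapezoid(t, f(t), c0 = c0)
    expect_gt(approx_auc, truth)
  }
  t200 <- seq(480 / 200, 480, length.out = 200)
  expect_lt(abs(auc_trapezoid(t200, f(t200), c0 = c0) - truth) / truth, 0.005)
})

test_that("splitting a grid at an interior point leaves the AUC unchanged", {
  set.seed(31)
  for (i in 1:10) {
    t <- sort(runif(6, 1, 400))
    c <- runif(6, 1, 100)
    full <- auc_trapezoid(t, c, c0 = 120)
    mid <- runif(1, t[3], t[4])
    ci <- approx(c(0, t), c(120, c), xout = mid)$y
    t2 <- sort(c(t, mid)); c2 <- c(c[t < mid], ci, c[t > mid])
    expect_equal(auc_trapezoid(t2, c2, c0 = 120), full, tolerance = 1e-12)
  }
})

test_that("tail extrapolation is c_last over lambda_z", {
  expect_equal(auc_extrapolate(53.9, 0.0241), 53.9 / 0.0241)
  expect_equal(auc_extrapolate(0, 0.01), 0)
  expect_error(auc_extrapolate(10, 0), "positive")
  # equals the quadrature of the fitted exponential tail
  truth <- oracle_auc(function(t) 53.9 * exp(-0.0241 * (t - 480)), 480, Inf)
  expect_equal(auc_extrapolate(53.9, 0.0241), truth, tolerance = 1e-6)
})

test_that("plasma clearance is dose / AUC indexed to body weight", {
  # mono-exponential profile: every piece known in closed form
  k <- 0.01; c0 <- 100
  t <- seq(5, 2000, length.out = 400)
  prof <- tibble::tibble(time_min = t, conc_ug_ml = c0 * exp(-k * t))
  res <- nca_clearance(prof, dose_mg = 258.8, bw_kg = 4)
  expect_true(res$valid_fit)
  expect_equal(res$lambda_z, k, tolerance = 1e-8)
  # AUCinf of the exact curve is c0 / k
  expect_equal(res$auc_inf, c0 / k, tolerance = 1e-4)
  expect_equal(res$gfr_ml_min_kg, 219980 / (c0 / k) / 4, tolerance = 1e-4)
  expect_equal(res$auc_inf, res$auc_0_last + res$auc_extrap)
  # doubling the dose doubles the clearance estimate
  res2 <- nca_clearance(prof, dose_mg = 2 * 258.8, bw_kg = 4)
  expect_equal(res2$gfr_ml_min_kg, 2 * res$gfr_ml_min_kg)
})

test_that("dense-grid NCA recovers true clearance within 2% across the GFR range", {
  t <- seq(1, 2000, length.out = 200)
  for (gfr in c(1.2, 2.5, 4.3, 6.1, 8.6)) {
    mk <- oracle_macro(gfr, 90, 160, 3, 64.7 * 1000 * 0.85)
    prof <- tibble::tibble(time_min = t, conc_ug_ml = oracle_biexp(mk, t))
    res <- nca_clearance(prof, dose_mg = 64.7 * 4, bw_kg = 4)
    expect_lt(abs(res$gfr_ml_min_kg - gfr) / gfr, 0.02)
  }
})

test_that("log-down default beats the plain linear rule on the 7-point schedule", {
  gfrs <- exp(seq(log(1.21), log(8.62), length.out = 25))
  err <- sapply(c("linlog", "linear"), function(m) {
    median(vapply(gfrs, function(g) {
      res <- nca_clearance(noisefree_profile(g), dose_mg = 64.7 * 4,
                           bw_kg = 4, auc_method = m)
      abs(res$gfr_ml_min_kg - g) / g
    }, numeric(1)))
  })
  # the 5 -> 30 min gap spans a steep distribution phase: linear
  # interpolation over-covers it, log-down does not
  expect_lt(err[["linlog"]], 0.05)
  expect_gt(err[["linear"]], 0.05)
  expect_lt(err[["linlog"]], err[["linear"]])
})

test_that("censored observations are excluded from fitting and AUC", {
  t <- c(5, 30, 60, 120, 240, 360, 480)
  mk <- oracle_macro(3.4, 90, 160, 3, 64.7 * 1000 * 0.85)
  conc <- oracle_biexp(mk, t)
  with_flag <- tibble::tibble(time_min = t, conc_ug_ml = conc,
                              censored = c(rep(FALSE, 6), TRUE))
  dropped <- tibble::tibble(time_min = t[-7], conc_ug_ml = conc[-7])
  expect_equal(nca_clearance(with_flag, 258.8, 4)[-1],
               nca_clearance(dropped, 258.8, 4)[-1])
})

test_that("profiles whose every tail rises are excluded with an invalid fit", {
  prof <- tibble::tibble(time_min = c(60, 120, 240, 480),
                         conc_ug_ml = c(5, 6, 8, 11))
  res <- nca_clearance(prof, 258.8, 4)
  expect_false(res$valid_fit)
  expect_true(is.na(res$gfr_ml_min_kg))
})

test_that("extrapolation flag is inclusive at the threshold", {
  expect_true(extrapolation_check(11.8))
  expect_true(extrapolation_check(25.0))
  expect_false(extrapolation_check(34.9))
  expect_false(extrapolation_check(25.0, threshold = 20))
  tab <- tibble::tibble(extrap_pct = c(10, 30))
  expect_equal(extrapolation_check(tab)$extrap_ok, c(TRUE, FALSE))
})
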