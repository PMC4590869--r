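# Independent cross-checks used across the suite.

# Two-compartment macro constants via eigen-decomposition of the amount
# system (a different route than the package's closed-form quadratic):
#   a1' = -(k10 + k12) a1 + k21 a2 ;  a2' = k12 a1 - k21 a2
oracle_macro <- function(cl, vc, vp, cld, dose) {
  k10 <- cl / vc; k12 <- cld / vc; k21 <- cld / vp
  M <- matrix(c(-(k10 + k12), k12, k21, -k21), 2, 2)
  ev <- eigen(M)
  s <- solve(ev$vectors, c(dose, 0))
  coefs <- ev$vectors[1, ] * s / vc
  rates <- -ev$values
  ord <- order(rates, decreasing = TRUE)
  list(A = coefs[ord][1], alpha = rates[ord][1],
       B = coefs[ord][2], beta = rates[ord][2])
}

oracle_biexp <- function(mk, t) mk$A * exp(-mk$alpha * t) + mk$B * exp(-mk$beta * t)

# Quadrature oracle for areas under arbitrary decay curves.
oracle_auc <- function(f, lower, upper) {
  stats::integrate(f, lower, upper, rel.tol = 1e-12)$value
}

# Noise-free seven-point profile for a given true clearance under the
# default disposition and dosing.
noisefree_profile <- function(gfr, times = c(5, 30, 60, 120, 240, 360, 480),
                              bw = 4) {
  dose_per_kg_exo <- 64.7 * 1000 * 0.85
  mk <- oracle_macro(gfr, 90, 160, 3, dose_per_kg_exo)
  tibble::tibble(time_min = times, conc_ug_ml = oracle_biexp(mk, times))
}
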