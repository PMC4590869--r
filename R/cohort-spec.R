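#' Specify a synthetic iohexol clearance cohort
#'
#' Bundles the generative parameters for a simulated feline GFR study:
#' group sizes, true GFR ranges, dosing, body-weight range, assay noise,
#' limit of quantification (LOQ), the sampling schedule, and the
#' two-compartment disposition parameters shared by all subjects.
#'
#' Defaults reproduce the study conditions the package emulates: 35
#' nonazotaemic and 15 azotaemic cats, a 64.7 mg/kg IV bolus of iohexol
#' (85% exoiohexol), sampling at 5, 30, 60, 120, 240, 360 and 480 minutes,
#' 4% proportional assay noise and an LOQ of 0.1 ug/mL. True GFR is drawn
#' log-uniformly within each group's range (1.21--8.62 and 1.36--3.47
#' mL/min/kg).
#'
#' @param n_nonazotaemic,n_azotaemic Group sizes (counts, may be 0).
#' @param gfr_range_nonazotaemic,gfr_range_azotaemic Length-2 numeric,
#'   min/max true renal clearance in mL/min/kg.
#' @param dose_per_kg Total iohexol dose, mg/kg.
#' @param exo_fraction Fraction of the dose that is exoiohexol (the measured
#'   isomer); in (0, 1].
#' @param bw_range Length-2 numeric, body-weight range in kg.
#' @param noise_cv Proportional assay noise as a coefficient of variation
#'   (fraction, in [0, 0.2]).
#' @param loq Limit of quantification, ug/mL; observations below it are
#'   flagged censored.
#' @param sampling_times Strictly increasing sampling times in minutes, all
#'   > 0.
#' @param vc_per_kg,vp_per_kg Central and peripheral distribution volumes,
#'   mL/kg.
#' @param cld_per_kg Inter-compartmental distribution clearance, mL/min/kg.
#' @param seed Master integer seed; per-subject streams are derived from it
#'   so that changing one group's size does not reshuffle the other group.
#'
#' @return An object of class `cohort_spec` (a validated named list).
#' @seealso [simulate_cohort()]
#' @examples
#' spec <- cohort_spec(seed = 42)
#' spec
#' @export
cohort_spec <- function(n_nonazotaemic = 35,
                        n_azotaemic = 15,
                        gfr_range_nonazotaemic = c(1.21, 8.62),
                        gfr_range_azotaemic = c(1.36, 3.47),
                        dose_per_kg = 64.7,
                        exo_fraction = 0.85,
                        bw_range = c(2, 5.5),
                        noise_cv = 0.04,
                        loq = 0.1,
                        sampling_times = NOMINAL_TIMES,
                        vc_per_kg = 90,
                        vp_per_kg = 160,
                        cld_per_kg = 3,
                        seed = 1L) {
  spec <- list(
    n_nonazotaemic = as.integer(n_nonazotaemic),
    n_azotaemic = as.integer(n_azotaemic),
    gfr_range_nonazotaemic = as.numeric(gfr_range_nonazotaemic),
    gfr_range_azotaemic = as.numeric(gfr_range_azotaemic),
    dose_per_kg = as.numeric(dose_per_kg),
    exo_fraction = as.numeric(exo_fraction),
    bw_range = as.numeric(bw_range),
    noise_cv = as.numeric(noise_cv),
    loq = as.numeric(loq),
    sampling_times = as.numeric(sampling_times),
    vc_per_kg = as.numeric(vc_per_kg),
    vp_per_kg = as.numeric(vp_per_kg),
    cld_per_kg = as.numeric(cld_per_kg),
    seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  stop_if <- function(cond, msg) if (cond) abort(msg, class = "ioxgfr_spec_error")
  stop_if(spec$n_nonazotaemic < 0 || spec$n_azotaemic < 0,
          "group sizes must be non-negative")
  for (fld in c("gfr_range_nonazotaemic", "gfr_range_azotaemic", "bw_range")) {
    r <- spec[[fld]]
    stop_if(length(r) != 2 || any(!is.finite(r)) || r[1] <= 0 || r[1] >= r[2],
            paste0("`", fld, "` must be a positive (min, max) pair with min < max"))
  }
  stop_if(spec$dose_per_kg <= 0, "`dose_per_kg` must be positive")
  stop_if(spec$exo_fraction <= 0 || spec$exo_fraction > 1,
          "`exo_fraction` must lie in (0, 1]")
  stop_if(spec$noise_cv < 0 || spec$noise_cv > 0.2,
          "`noise_cv` must lie in [0, 0.2]")
  stop_if(spec$loq <= 0, "`loq` must be positive")
  ts <- spec$sampling_times
  stop_if(length(ts) < 2 || any(ts <= 0) || any(diff(ts) <= 0),
          "`sampling_times` must be strictly increasing and all > 0")
  stop_if(spec$vc_per_kg <= 0 || spec$vp_per_kg < 0 || spec$cld_per_kg < 0,
          "compartmental parameters must be non-negative (Vc strictly positive)")
  stop_if(is.na(spec$seed), "`seed` must be an integer")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  subjects: %d nonazotaemic + %d azotaemic\n",
              x$n_nonazotaemic, x$n_azotaemic))
  cat(sprintf("  true GFR: %.2f-%.2f (nonazot.), %.2f-%.2f (azot.) mL/min/kg\n",
              x$gfr_range_nonazotaemic[1], x$gfr_range_nonazotaemic[2],
              x$gfr_range_azotaemic[1], x$gfr_range_azotaemic[2]))
  cat(sprintf("  dose: %.1f mg/kg (exo fraction %.2f), BW %.1f-%.1f kg\n",
              x$dose_per_kg, x$exo_fraction, x$bw_range[1], x$bw_range[2]))
  cat(sprintf("  sampling (min): %s\n", paste(x$sampling_times, collapse = ", ")))
  cat(sprintf("  noise CV %.1f%%, LOQ %.2g ug/mL, seed %d\n",
              100 * x$noise_cv, x$loq, x$seed))
  cat(sprintf("  disposition: Vc %.0f mL/kg, Vp %.0f mL/kg, CLd %.1f mL/min/kg\n",
              x$vc_per_kg, x$vp_per_kg, x$cld_per_kg))
  invisible(x)
}
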