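#' Built-in limited-sampling models
#'
#' The reference protocol draws blood at 5, 30, 60, 120, 240, 360 and 480
#' minutes after the bolus; the four validated simplifications keep an
#' early-phase subset:
#' \describe{
#'   \item{reference}{5, 30, 60, 120, 240, 360, 480 min}
#'   \item{A}{5, 30, 60, 240 min}
#'   \item{B}{5, 30, 60, 120 min}
#'   \item{C}{5, 60, 120, 240 min}
#'   \item{D}{5, 30, 60 min}
#' }
#'
#' @return Named list of numeric time vectors (minutes), each a subset of
#'   the reference schedule.
#' @examples
#' sampling_models()$D
#' @export
sampling_models <- function() {
  list(
    reference = NOMINAL_TIMES,
    A = c(5, 30, 60, 240),
    B = c(5, 30, 60, 120),
    C = c(5, 60, 120, 240),
    D = c(5, 30, 60)
  )
}

resolve_models <- function(models) {
  builtin <- sampling_models()
  if (identical(models, "all")) return(builtin)
  if (is.character(models)) {
    missing <- setdiff(models, names(builtin))
    if (length(missing))
      abort(paste0("unknown sampling model(s): ", paste(missing, collapse = ", ")))
    return(builtin[models])
  }
  if (is.list(models) && !is.null(names(models)) && all(nzchar(names(models)))) {
    lapply(models, function(ts) {
      ts <- as.numeric(ts)
      if (length(ts) < 3 || any(diff(ts) <= 0) || any(ts <= 0))
        abort("custom sampling models need >= 3 strictly increasing times > 0")
      ts
    })
  } else {
    abort("`models` must be \"all\", model names, or a named list of time vectors")
  }
}

#' Restrict a profile to a sampling model's times
#'
#' @param profile Data frame with `time_min` (plus any other columns, kept).
#' @param times Numeric vector of model times, minutes.
#' @param tolerance_min Matching tolerance in minutes; 0 (exact) for
#'   nominal-grid data, larger for real draws with clock jitter. Each model
#'   time must match exactly one observed time.
#' @return The profile rows matching the model times, in time order.
#' @examples
#' prof <- tibble::tibble(time_min = c(5, 30, 60, 120, 240, 360, 480),
#'                        conc_ug_ml = 7:1)
#' subset_profile(prof, sampling_models()$D)
#' @export
subset_profile <- function(profile, times, tolerance_min = 0) {
  stopifnot("time_min" %in% names(profile))
  idx <- vapply(times, function(tt) {
    hit <- which(abs(profile$time_min - tt) <= tolerance_min)
    if (length(hit) == 0)
      abort(sprintf("profile has no sample at %g min (tolerance %g)",
                    tt, tolerance_min), class = "ioxgfr_subset_error")
    if (length(hit) > 1)
      abort(sprintf("multiple samples match %g min at tolerance %g",
                    tt, tolerance_min))
    hit
  }, integer(1))
  profile[idx[order(profile$time_min[idx])], , drop = FALSE]
}

#' GFR under every sampling model for one subject
#'
#' Runs the identical noncompartmental pipeline ([nca_clearance()]) on each
#' model's subset of the profile; the terminal slope is refitted per subset.
#' A fit failure under one model leaves the other models untouched.
#'
#' @inheritParams nca_clearance
#' @param models `"all"`, a character vector of built-in model names, or a
#'   named list of time vectors.
#' @param tolerance_min Time-matching tolerance, minutes.
#' @return Tibble with one row per model (columns as [nca_clearance()]).
#' @export
gfr_all_models <- function(profile, dose_mg, bw_kg, exo_fraction = 0.85,
                           models = "all",
                           auc_method = c("linlog", "linear"),
                           tolerance_min = 0) {
  auc_method <- match.arg(auc_method)
  models <- resolve_models(models)
  purrr::map_dfr(names(models), function(mn) {
    sub <- subset_profile(profile, models[[mn]], tolerance_min)
    n_term <- if (length(models[[mn]]) == 3) 2L else "auto"
    nca_clearance(sub, dose_mg, bw_kg, exo_fraction, model_name = mn,
                  auc_method = auc_method, n_terminal = n_term)
  })
}

#' Estimate GFR for a whole cohort under one or more sampling models
#'
#' Data-frame-first wrapper over [gfr_all_models()]: joins each subject's
#' metadata to its profile and returns the stacked per-subject, per-model
#' noncompartmental results.
#'
#' @param profiles Long table: `subject_id`, `time_min`, `conc_ug_ml`,
#'   optional `censored`.
#' @param subjects Per-subject table: `subject_id`, `bw_kg`, `dose_mg`
#'   (other columns ignored here).
#' @param models,auc_method,tolerance_min See [gfr_all_models()].
#' @param exo_fraction Exoiohexol fraction of the administered dose.
#' @return Tibble: `subject_id` plus the [nca_clearance()] columns, one row
#'   per subject x model. Subjects whose terminal fit fails under a model
#'   keep their row with `valid_fit = FALSE` and `NA` estimates.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_nonazotaemic = 2, n_azotaemic = 1))
#' estimate_gfr(cohort$profiles, cohort$subjects, models = c("reference", "D"))
#' @export
estimate_gfr <- function(profiles, subjects, models = "all",
                         exo_fraction = 0.85,
                         auc_method = c("linlog", "linear"),
                         tolerance_min = 0) {
  auc_method <- match.arg(auc_method)
  check_columns(profiles, c("subject_id", "time_min", "conc_ug_ml"), "profiles")
  check_columns(subjects, c("subject_id", "bw_kg", "dose_mg"), "subjects")
  check_profile_times(profiles)
  purrr::map_dfr(seq_len(nrow(subjects)), function(i) {
    sub <- subjects[i, ]
    prof <- dplyr::arrange(
      dplyr::filter(profiles, .data$subject_id == sub$subject_id),
      .data$time_min)
    res <- gfr_all_models(prof, sub$dose_mg, sub$bw_kg, exo_fraction,
                          models = models, auc_method = auc_method,
                          tolerance_min = tolerance_min)
    dplyr::bind_cols(tibble(subject_id = sub$subject_id), res)
  })
}
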