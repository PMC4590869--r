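check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "ioxgfr_io_error")
  invisible(df)
}

check_profile_times <- function(profiles) {
  bad <- profiles |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(dup = anyDuplicated(.data$time_min) > 0) |>
    dplyr::filter(.data$dup)
  if (nrow(bad))
    abort(sprintf("duplicate sampling times for subject(s): %s",
                  paste(bad$subject_id, collapse = ", ")),
          class = "ioxgfr_io_error")
  invisible(profiles)
}

#' Read / write the pipeline's CSV tables
#'
#' Plain-CSV I/O with schema validation. `read_profiles()` requires
#' `subject_id`, `time_min`, `conc_ug_ml` (a missing `censored` column is
#' added as all-`FALSE`); `read_subjects()` requires `subject_id`,
#' `bw_kg`, `dose_mg`. Unknown columns are preserved, row order is
#' irrelevant (analysis sorts by subject and time), and duplicate times
#' within a subject are rejected with the subject named.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_profiles <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("subject_id", "time_min", "conc_ug_ml"), "profiles")
  if (!"censored" %in% names(df)) df$censored <- FALSE
  df$censored <- as.logical(df$censored)
  check_profile_times(df)
  df
}

#' @rdname read_profiles
#' @export
read_subjects <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("subject_id", "bw_kg", "dose_mg"), "subjects")
  df
}

#' @rdname read_profiles
#' @param x Table to write.
#' @export
write_results <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Group-wise GFR summary table
#'
#' Per group and per sampling model: n, mean, SD, SEM, minimum and maximum
#' of the GFR estimates — the layout of a clearance-study summary table
#' (each estimator's mean and range in each clinical group).
#'
#' @param results Output of [estimate_gfr()].
#' @param subjects Subject table with `subject_id` and `group`.
#' @return Tibble: `group`, `model`, `n`, `mean`, `sd`, `sem`, `min`,
#'   `max` (GFR in mL/min/kg).
#' @export
gfr_summary_table <- function(results, subjects) {
  check_columns(subjects, c("subject_id", "group"), "subjects")
  results |>
    dplyr::filter(.data$valid_fit) |>
    dplyr::left_join(subjects[, c("subject_id", "group")], by = "subject_id") |>
    dplyr::group_by(.data$group, .data$model) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$gfr_ml_min_kg),
      sd = sd(.data$gfr_ml_min_kg),
      sem = sd(.data$gfr_ml_min_kg) / sqrt(dplyr::n()),
      min = min(.data$gfr_ml_min_kg),
      max = max(.data$gfr_ml_min_kg),
      .groups = "drop")
}

#' Accuracy table (P15/P30/P50 per model and group)
#'
#' @param agreement A `gfr_agreement` object from [compare_models()].
#' @return Tibble: `model`, `group`, `n`, one column per threshold
#'   (`p15`, `p30`, `p50`, ...), excluding the pooled "overall" rows.
#' @export
accuracy_table <- function(agreement) {
  stopifnot(inherits(agreement, "gfr_agreement"))
  cols <- c("model", "group", "n", paste0("p", agreement$thresholds))
  agreement$agreement |>
    dplyr::filter(.data$group != "overall") |>
    dplyr::select(dplyr::all_of(cols))
}

#' Run the full simulate - estimate - compare pipeline
#'
#' End-to-end reproducible run: simulate a cohort from `spec`, estimate
#' GFR under every requested sampling model, and compute the agreement
#' battery plus the group-wise summary, accuracy and t-test tables. With
#' `dir` set, all artifacts are written out (profiles.csv, subjects.csv,
#' results.csv, gfr_summary.csv, accuracy.csv, report.json and a
#' manifest.json echoing the spec, models and package version); the same
#' spec always reproduces byte-identical artifacts. If any stage fails,
#' partially written files are removed.
#'
#' @param spec A [cohort_spec()].
#' @param models Sampling models, as in [estimate_gfr()].
#' @param auc_method AUC rule, `"linlog"` or `"linear"`.
#' @param thresholds Accuracy thresholds in percent.
#' @param extrap_threshold Extrapolated-AUC ceiling in percent for the
#'   diagnostic flag.
#' @param dir Optional output directory (created if needed).
#' @return List of class `gfr_run`: `cohort`, `results` (with `extrap_ok`
#'   column), `agreement` (`gfr_agreement` or `NULL` when only the
#'   reference model is run), `gfr_summary`, `accuracy`, `group_tests`,
#'   `manifest`.
#' @examples
#' run <- run_gfr_pipeline(cohort_spec(n_nonazotaemic = 4, n_azotaemic = 3))
#' run$gfr_summary
#' @export
run_gfr_pipeline <- function(spec = cohort_spec(), models = "all",
                             auc_method = c("linlog", "linear"),
                             thresholds = c(15, 30, 50),
                             extrap_threshold = 25,
                             dir = NULL) {
  auc_method <- match.arg(auc_method)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(dir)) unlink(file.path(dir, PIPELINE_FILES), force = TRUE)
      abort(sprintf("pipeline stage \"%s\" failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
  }
  cohort <- stage("simulate", simulate_cohort(spec))
  results <- stage("gfr", {
    r <- estimate_gfr(cohort$profiles, cohort$subjects, models = models,
                      exo_fraction = spec$exo_fraction,
                      auc_method = auc_method)
    extrapolation_check(r, extrap_threshold)
  })
  model_names <- unique(results$model)
  agreement <- NULL
  acc <- NULL
  if (length(setdiff(model_names, "reference")) > 0 &&
      "reference" %in% model_names) {
    agreement <- stage("compare",
                       compare_models(results, cohort$subjects,
                                      thresholds = thresholds))
    acc <- accuracy_table(agreement)
  }
  summary_tab <- stage("summarise", gfr_summary_table(results, cohort$subjects))
  gt <- NULL
  if (length(unique(cohort$subjects$group)) == 2) {
    wide <- results |>
      dplyr::filter(.data$valid_fit) |>
      dplyr::select("subject_id", "model", "gfr_ml_min_kg") |>
      tidyr::pivot_wider(names_from = "model",
                         values_from = "gfr_ml_min_kg",
                         names_prefix = "gfr_") |>
      dplyr::inner_join(cohort$subjects, by = "subject_id")
    vars <- c(paste0("gfr_", model_names), "pcr_umol_l", "pu_mmol_l", "bw_kg")
    vars <- vars[vapply(vars, function(v)
      v %in% names(wide) && all(!is.na(wide[[v]])), logical(1))]
    gt <- stage("t-tests", group_t_tests(wide, vars))
  }
  manifest <- list(
    package = "ioxgfr",
    version = as.character(utils::packageVersion("ioxgfr")),
    spec = unclass(spec),
    models = model_names,
    auc_method = auc_method,
    thresholds = thresholds,
    extrap_threshold = extrap_threshold)
  run <- structure(list(cohort = cohort, results = results,
                        agreement = agreement, gfr_summary = summary_tab,
                        accuracy = acc, group_tests = gt,
                        manifest = manifest),
                   class = "gfr_run")
  if (!is.null(dir)) stage("write", write_run(run, dir))
  run
}

PIPELINE_FILES <- c("profiles.csv", "subjects.csv", "results.csv",
                    "gfr_summary.csv", "accuracy.csv", "report.json",
                    "manifest.json")

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$cohort$profiles, file.path(dir, "profiles.csv"))
  readr::write_csv(run$cohort$subjects, file.path(dir, "subjects.csv"))
  readr::write_csv(run$results, file.path(dir, "results.csv"))
  readr::write_csv(run$gfr_summary, file.path(dir, "gfr_summary.csv"))
  if (!is.null(run$accuracy))
    readr::write_csv(run$accuracy, file.path(dir, "accuracy.csv"))
  report <- list(
    agreement = if (!is.null(run$agreement)) run$agreement$agreement,
    chi_square = if (!is.null(run$agreement)) run$agreement$chi_square,
    group_tests = run$group_tests,
    excluded = if (!is.null(run$agreement)) run$agreement$excluded)
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                       file.path(dir, "report.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.gfr_run <- function(x, ...) {
  cat("<gfr_run>\n")
  print(x$cohort)
  cat(sprintf("  models: %s (%s AUC)\n",
              paste(unique(x$results$model), collapse = ", "),
              x$manifest$auc_method))
  cat(sprintf("  invalid fits: %d / %d\n",
              sum(!x$results$valid_fit), nrow(x$results)))
  invisible(x)
}
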