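#' Classify azotaemia from plasma creatinine
#'
#' Cats with plasma creatinine below 141 umol/L are nonazotaemic, above it
#' azotaemic (IRIS-style cut-off). A value exactly at the cut-off is not
#' covered by either strict inequality; it is assigned to the azotaemic
#' group conservatively, with a warning.
#'
#' @param pcr Plasma creatinine, umol/L (strictly positive).
#' @return Character vector: `"nonazotaemic"` or `"azotaemic"`.
#' @examples
#' classify_azotaemia(c(106, 160))
#' @export
classify_azotaemia <- function(pcr) {
  if (any(!is.finite(pcr)) || any(pcr <= 0))
    abort("`pcr` must be strictly positive")
  if (any(pcr == PCR_CUTOFF))
    warn(sprintf("PCr exactly %g umol/L is on the group boundary; assigned azotaemic",
                 PCR_CUTOFF))
  ifelse(pcr < PCR_CUTOFF, "nonazotaemic", "azotaemic")
}

#' Accuracy within percentage thresholds (P15/P30/P50)
#'
#' For each threshold X, the percentage of estimates whose relative
#' deviation from the reference value, |model - ref| / ref, is at most
#' X% (inclusive: a deviation of exactly X% counts as accurate). The
#' reference method's value is always the denominator.
#'
#' @param reference,model Equal-length GFR vectors; `reference` must be
#'   strictly positive.
#' @param thresholds Percent thresholds, default `c(15, 30, 50)`.
#' @return Named numeric vector of percentages (names `p15`, `p30`, ...).
#' @examples
#' accuracy_within(c(2, 3, 4), c(2.2, 4.2, 4.0))
#' @export
accuracy_within <- function(reference, model, thresholds = c(15, 30, 50)) {
  if (length(reference) != length(model) || length(reference) < 1)
    abort("`reference` and `model` must be equal-length, non-empty")
  if (any(reference <= 0))
    abort("reference GFR values must be strictly positive")
  dev <- abs(model - reference) / reference
  out <- vapply(thresholds, function(x) 100 * mean(dev <= x / 100), numeric(1))
  names(out) <- paste0("p", thresholds)
  out
}

#' Bland-Altman agreement analysis
#'
#' Differences are oriented model - reference; bias is their mean and the
#' 95% limits of agreement are bias +/- 1.96 times their sample standard
#' deviation.
#'
#' @param reference,model Equal-length numeric vectors, n >= 2.
#' @return List of class `bland_altman`: `bias`, `loa_lower`, `loa_upper`,
#'   `sd_diff`, `n`, and `pairs` (tibble of per-pair `average` and
#'   `difference`).
#' @examples
#' ba <- bland_altman(c(3.0, 3.4), c(3.1, 3.3))
#' ba$bias
#' @export
bland_altman <- function(reference, model) {
  if (length(reference) != length(model) || length(reference) < 2)
    abort("Bland-Altman needs equal-length vectors with n >= 2")
  d <- model - reference
  s <- sd(d)
  structure(list(
    bias = mean(d),
    loa_lower = mean(d) - 1.96 * s,
    loa_upper = mean(d) + 1.96 * s,
    sd_diff = s,
    n = length(d),
    pairs = tibble(average = (model + reference) / 2, difference = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d\n  bias %.4g, 95%% LoA [%.4g, %.4g]\n",
              x$n, x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Pearson correlation and ordinary least-squares regression
#'
#' Regresses the simplified model's GFR on the reference GFR and reports
#' the Pearson correlation alongside the OLS slope and intercept;
#' `r_squared` is exactly the squared Pearson r.
#'
#' @param reference,model Equal-length numeric vectors, n >= 3; the
#'   reference must have non-zero variance.
#' @return One-row tibble: `pearson_r`, `r_squared`, `slope`, `intercept`,
#'   `n`.
#' @export
pearson_and_regression <- function(reference, model) {
  if (length(reference) != length(model) || length(reference) < 3)
    abort("need equal-length vectors with n >= 3")
  if (stats::var(reference) == 0 || stats::var(model) == 0)
    abort("zero-variance input: correlation undefined")
  r <- cor(reference, model)
  b <- coef(lm(model ~ reference))
  tibble(pearson_r = r, r_squared = r^2,
         slope = unname(b[2]), intercept = unname(b[1]),
         n = length(reference))
}

#' Chi-square homogeneity test of accuracy proportions
#'
#' Compares the accurate / not-accurate counts of k sampling models at one
#' threshold with Pearson's chi-square test on the k x 2 table (no
#' continuity correction, df = k - 1).
#'
#' @param counts A k x 2 matrix or data frame; column 1 = subjects within
#'   the threshold, column 2 = subjects outside it. Row names label the
#'   models.
#' @return One-row tibble: `chi_squared`, `df`, `p_value`.
#' @examples
#' chi_square_accuracy(rbind(A = c(10, 0), B = c(0, 10)))
#' @export
chi_square_accuracy <- function(counts) {
  m <- as.matrix(counts)
  if (nrow(m) < 2 || ncol(m) != 2)
    abort("`counts` must be a k x 2 table with k >= 2")
  if (any(m < 0) || sum(m) == 0) abort("counts must be non-negative")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0))
    abort(paste("a table margin is empty so an expected cell is 0;",
                "use an exact test (e.g. fisher.test) instead"),
          class = "ioxgfr_chisq_error")
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(chi_squared = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value))
}

#' Two-group Student's t-tests over several variables
#'
#' Classic equal-variance (pooled) two-sample t-tests between the
#' nonazotaemic and azotaemic groups, one per variable, two-sided, with a
#' significance flag at alpha = 0.05.
#'
#' @param data Data frame holding `group_col` and the `variables`.
#' @param variables Character vector of numeric column names to test.
#' @param group_col Name of the two-level grouping column.
#' @param alpha Significance level for the flag.
#' @return Tibble: `variable`, `mean_a`, `mean_b` (in the group levels'
#'   sorted order, reported in `group_a`/`group_b`), `t_statistic`,
#'   `p_value`, `significant`.
#' @export
group_t_tests <- function(data, variables, group_col = "group",
                          alpha = 0.05) {
  check_columns(data, c(group_col, variables), "data")
  g <- data[[group_col]]
  levels <- sort(unique(g))
  if (length(levels) != 2) abort("`group_col` must have exactly two levels")
  if (any(table(g) < 2)) abort("each group needs n >= 2 for a t-test")
  purrr::map_dfr(variables, function(v) {
    a <- data[[v]][g == levels[1]]
    b <- data[[v]][g == levels[2]]
    tt <- t.test(a, b, var.equal = TRUE)
    tibble(variable = v, group_a = levels[1], group_b = levels[2],
           mean_a = mean(a), mean_b = mean(b),
           t_statistic = unname(tt$statistic),
           p_value = tt$p.value,
           significant = tt$p.value < alpha)
  })
}

#' Agreement of limited-sampling GFR estimates with the reference method
#'
#' For each simplified sampling model (and, when `by_group = TRUE`, within
#' each azotaemia group as well as overall) this computes the full
#' validation battery against the seven-point reference estimate:
#' Pearson correlation and OLS regression, Bland-Altman bias and 95%
#' limits of agreement, and P15/P30/P50 accuracy. Accuracy proportions are
#' compared across models with a chi-square homogeneity test per threshold.
#' Subjects lacking a valid estimate under a model are dropped from that
#' model's statistics (the per-model `n` makes this explicit).
#'
#' @param results Per-subject, per-model estimates from [estimate_gfr()]
#'   (needs `subject_id`, `model`, `gfr_ml_min_kg`, `valid_fit`).
#' @param subjects Subject metadata with `subject_id` and `group`
#'   (`"nonazotaemic"` / `"azotaemic"`); optional when `by_group = FALSE`.
#' @param reference Name of the reference model (default `"reference"`).
#' @param thresholds Accuracy thresholds in percent, ascending.
#' @return Object of class `gfr_agreement`: list with `agreement` (tibble,
#'   one row per model x group), `chi_square` (tibble, one row per
#'   threshold x group), `excluded` (subjects without valid fits), and the
#'   call parameters. Has [tidy()], [glance()] and [ggplot2::autoplot()]
#'   methods.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_nonazotaemic = 6, n_azotaemic = 4))
#' res <- estimate_gfr(cohort$profiles, cohort$subjects)
#' compare_models(res, cohort$subjects)
#' @export
compare_models <- function(results, subjects = NULL, reference = "reference",
                           thresholds = c(15, 30, 50)) {
  check_columns(results, c("subject_id", "model", "gfr_ml_min_kg", "valid_fit"),
                "results")
  if (is.unsorted(thresholds, strictly = TRUE))
    abort("`thresholds` must be strictly ascending")
  if (!reference %in% results$model)
    abort(sprintf("reference model \"%s\" absent from `results`", reference))

  wide <- results |>
    dplyr::filter(.data$valid_fit) |>
    dplyr::select("subject_id", "model", "gfr_ml_min_kg") |>
    tidyr::pivot_wider(names_from = "model", values_from = "gfr_ml_min_kg")
  excluded <- results |>
    dplyr::filter(!.data$valid_fit) |>
    dplyr::select("subject_id", "model")

  groups <- list(overall = wide$subject_id)
  if (!is.null(subjects)) {
    check_columns(subjects, c("subject_id", "group"), "subjects")
    for (g in sort(unique(subjects$group)))
      groups[[g]] <- subjects$subject_id[subjects$group == g]
  }
  model_names <- setdiff(intersect(unique(results$model), names(wide)),
                         reference)

  agreement <- purrr::map_dfr(names(groups), function(gname) {
    gw <- wide[wide$subject_id %in% groups[[gname]], ]
    purrr::map_dfr(model_names, function(mn) {
      ok <- !is.na(gw[[reference]]) & !is.na(gw[[mn]])
      ref <- gw[[reference]][ok]; mod <- gw[[mn]][ok]
      if (length(ref) < 3) {
        return(tibble(model = mn, group = gname, n = length(ref)))
      }
      reg <- pearson_and_regression(ref, mod)
      ba <- bland_altman(ref, mod)
      acc <- accuracy_within(ref, mod, thresholds)
      dplyr::bind_cols(
        tibble(model = mn, group = gname, n = length(ref)),
        reg[, c("pearson_r", "r_squared", "slope", "intercept")],
        tibble(bias = ba$bias, loa_lower = ba$loa_lower,
               loa_upper = ba$loa_upper),
        tibble::as_tibble_row(acc))
    })
  })

  chi <- purrr::map_dfr(names(groups), function(gname) {
    gw <- wide[wide$subject_id %in% groups[[gname]], ]
    purrr::map_dfr(thresholds, function(th) {
      counts <- t(vapply(model_names, function(mn) {
        ok <- !is.na(gw[[reference]]) & !is.na(gw[[mn]])
        dev <- abs(gw[[mn]][ok] - gw[[reference]][ok]) / gw[[reference]][ok]
        within <- sum(dev <= th / 100)
        c(within = within, outside = sum(ok) - within)
      }, numeric(2)))
      res <- tryCatch(chi_square_accuracy(counts),
                      error = function(e) tibble(chi_squared = NA_real_,
                                                 df = NA_real_,
                                                 p_value = NA_real_))
      dplyr::bind_cols(tibble(group = gname, threshold_pct = th), res)
    })
  })

  structure(list(agreement = agreement, chi_square = chi,
                 excluded = excluded, reference = reference,
                 thresholds = thresholds,
                 data = wide, groups = groups),
            class = "gfr_agreement")
}

#' @export
print.gfr_agreement <- function(x, ...) {
  cat(sprintf("<gfr_agreement> %d model(s) vs \"%s\"\n",
              length(unique(x$agreement$model)), x$reference))
  print(as.data.frame(x$agreement), digits = 3, row.names = FALSE)
  if (nrow(x$excluded))
    cat(sprintf("  %d subject-model estimate(s) excluded (invalid fit)\n",
                nrow(x$excluded)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an agreement object
#'
#' @param x A `gfr_agreement` object.
#' @param ... Unused.
#' @return The per-model, per-group agreement tibble (correlation,
#'   regression, Bland-Altman, accuracy columns).
#' @method tidy gfr_agreement
#' @export
tidy.gfr_agreement <- function(x, ...) x$agreement

#' One-line-per-test summary of an agreement object
#'
#' @param x A `gfr_agreement` object.
#' @param ... Unused.
#' @return The chi-square homogeneity tibble (one row per group x
#'   threshold).
#' @method glance gfr_agreement
#' @export
glance.gfr_agreement <- function(x, ...) x$chi_square
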