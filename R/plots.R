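#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_abline facet_wrap labs scale_y_log10
#' @export
ggplot2::autoplot

#' Plot a Bland-Altman analysis
#'
#' Differences (model - reference) against pair averages, with the bias and
#' the 95% limits of agreement as horizontal lines.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot(object$pairs, aes(x = .data$average, y = .data$difference)) +
    geom_point() +
    geom_hline(yintercept = object$bias, linetype = "solid") +
    geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
               linetype = "dashed") +
    labs(x = "Average GFR (mL/min/kg)",
         y = "Difference, model - reference (mL/min/kg)",
         title = sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f]",
                         object$bias, object$loa_lower, object$loa_upper))
}

#' Plot agreement of all limited-sampling models with the reference
#'
#' One Bland-Altman panel per simplified model, pooled over groups, with
#' per-model bias and limits of agreement.
#'
#' @param object A `gfr_agreement` object from [compare_models()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gfr_agreement
#' @export
autoplot.gfr_agreement <- function(object, ...) {
  wide <- object$data
  models <- setdiff(names(wide), c("subject_id", object$reference))
  pairs <- purrr::map_dfr(models, function(mn) {
    ok <- !is.na(wide[[object$reference]]) & !is.na(wide[[mn]])
    tibble(model = mn,
           average = (wide[[mn]][ok] + wide[[object$reference]][ok]) / 2,
           difference = wide[[mn]][ok] - wide[[object$reference]][ok])
  })
  lines <- object$agreement |>
    dplyr::filter(.data$group == "overall")
  ggplot(pairs, aes(x = .data$average, y = .data$difference)) +
    geom_point() +
    geom_hline(data = lines, aes(yintercept = .data$bias)) +
    geom_hline(data = lines, aes(yintercept = .data$loa_lower),
               linetype = "dashed") +
    geom_hline(data = lines, aes(yintercept = .data$loa_upper),
               linetype = "dashed") +
    facet_wrap(~model) +
    labs(x = "Average GFR (mL/min/kg)",
         y = "Difference, model - reference (mL/min/kg)")
}

#' Scatter of limited-sampling GFR against the reference GFR
#'
#' @param agreement A `gfr_agreement` object.
#' @return A ggplot with the identity line and per-model OLS fits.
#' @export
plot_gfr_scatter <- function(agreement) {
  stopifnot(inherits(agreement, "gfr_agreement"))
  wide <- agreement$data
  models <- setdiff(names(wide), c("subject_id", agreement$reference))
  long <- purrr::map_dfr(models, function(mn)
    tibble(model = mn, reference = wide[[agreement$reference]],
           estimate = wide[[mn]]))
  fits <- agreement$agreement |> dplyr::filter(.data$group == "overall")
  ggplot(long, aes(x = .data$reference, y = .data$estimate)) +
    geom_point() +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    geom_abline(data = fits,
                aes(slope = .data$slope, intercept = .data$intercept)) +
    facet_wrap(~model) +
    labs(x = "Reference GFR (mL/min/kg)",
         y = "Limited-sampling GFR (mL/min/kg)")
}

#' Spaghetti plot of simulated concentration-time profiles
#'
#' @param object A `gfr_cohort`.
#' @param ... Unused.
#' @return A ggplot (log concentration scale, one line per subject).
#' @method autoplot gfr_cohort
#' @export
autoplot.gfr_cohort <- function(object, ...) {
  ggplot(object$profiles,
         aes(x = .data$time_min, y = .data$conc_ug_ml,
             group = .data$subject_id)) +
    geom_line(alpha = 0.4) +
    geom_point(aes(shape = .data$censored), size = 1) +
    scale_y_log10() +
    labs(x = "Time after bolus (min)",
         y = "Plasma exoiohexol (ug/mL, log scale)")
}
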