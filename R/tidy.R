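# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @describeIn scan_family Tidy method: the post-filter call table, one row
#'   per displacement call.
#' @param x An `ogd_scan`.
#' @param ... Unused.
#' @export
tidy.ogd_scan <- function(x, ...) x$calls

#' @describeIn scan_family Glance method: one-row scan summary.
#' @export
glance.ogd_scan <- function(x, ...) {
  tibble(
    n_families = length(x$families),
    n_branches = length(unique(x$evaluations$recipient)),
    n_candidates = nrow(x$evaluations),
    n_calls = nrow(x$calls),
    n_filtered = nrow(x$all_calls) - nrow(x$calls),
    elw_cutoff = x$config$elw_cutoff,
    distance_cutoff = x$config$distance_cutoff
  )
}

#' @describeIn rate_linearity Tidy method: coefficient table of the linear
#'   fit.
#' @param x An `ogd_rate_fit`.
#' @param ... Unused.
#' @export
tidy.ogd_rate_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1L], std_error = sm[, 2L],
         statistic = sm[, 3L], p_value = sm[, 4L])
}

#' @describeIn rate_linearity Glance method: slope, intercept and the three
#'   companion test p-values.
#' @export
glance.ogd_rate_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, fit_p = x$fit_p,
         linearity_p = x$linearity_p, runs_p = x$runs_p,
         degenerate = x$degenerate, n = nrow(x$points))
}

#' @describeIn scan_family Autoplot method: each evaluated branch's best
#'   non-original placement in the ELW-distance plane, with the calling
#'   cutoffs drawn as guides.
#' @param object An `ogd_scan`.
#' @export
autoplot.ogd_scan <- function(object, ...) {
  smry <- summarise_evaluations(object$evaluations)
  cfg <- object$config
  smry$called <- cutoff_met(smry$elw, cfg$elw_cutoff, cfg$inclusive) &
    cutoff_met(smry$distance, cfg$distance_cutoff, cfg$inclusive)
  ggplot2::ggplot(smry, ggplot2::aes(x = .data$distance, y = .data$elw,
                                     colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = cfg$elw_cutoff, linetype = 2) +
    ggplot2::geom_vline(xintercept = cfg$distance_cutoff, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "distance from original position (substitutions/site)",
                  y = "ELW of best non-original placement",
                  colour = "called",
                  title = "Best alternative placement per branch") +
    ggplot2::theme_minimal()
}

#' @describeIn parameter_grid Autoplot method: the cutoff-grid surface as a
#'   tile plot with call counts.
#' @param object An `ogd_grid`.
#' @param ... Unused.
#' @export
autoplot.ogd_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance_cutoff,
                                       y = .data$elw_cutoff,
                                       fill = .data$n_ogds)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_ogds), size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "distance cutoff (substitutions/site)",
                  y = "ELW cutoff", fill = "OGDs",
                  title = "Displacements detected across cutoff combinations") +
    ggplot2::theme_minimal()
}

#' @describeIn rate_linearity Autoplot method: rate points with the fitted
#'   line.
#' @param object An `ogd_rate_fit` or `ogd_rate_points` tibble.
#' @export
autoplot.ogd_rate_fit <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$total_length, y = .data$n_ogds)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(x = "total branch length in clade (substitutions/site)",
                  y = "displacements accepted into clade",
                  title = "Rate of displacement vs evolutionary opportunity") +
    ggplot2::theme_minimal()
}
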