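#' Plot a threshold-versus-noise table
#'
#' Group-mean log thresholds against external-noise contrast, one panel per
#' difficulty level, error bars at +/- 1 SEM. Zero external noise is drawn
#' at half the smallest nonzero level so the log axis stays finite.
#'
#' @param object A [tvn_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tvn_table
#' @export
autoplot.tvn_table <- function(object, ...) {
  nz <- min(object$n_ext[object$n_ext > 0])
  df <- dplyr::mutate(
    object,
    noise_pct = 100 * ifelse(.data$n_ext == 0, nz / 2, .data$n_ext),
    threshold_pct = exp(.data$mean_log_threshold),
    lo = exp(.data$mean_log_threshold - .data$sem_log_threshold),
    hi = exp(.data$mean_log_threshold + .data$sem_log_threshold),
    difficulty = paste0("target accuracy ", round(100 * .data$q, 2), "%"))
  ggplot2::ggplot(df, ggplot2::aes(.data$noise_pct, .data$threshold_pct,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.05) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~difficulty) +
    ggplot2::labs(x = "external noise RMS contrast (%)",
                  y = "contrast threshold (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot population posteriors from a hierarchical fit
#'
#' Density of the population-mean posterior draws per parameter and group,
#' with 95% credible intervals marked as horizontal segments.
#'
#' @param object A `hier_fit`.
#' @param parameters Which parameters to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hier_fit
#' @export
autoplot.hier_fit <- function(object,
                              parameters = c("n_add", "n_mul", "w_ext"),
                              ...) {
  d <- dplyr::filter(object$population_draws,
                     .data$parameter %in% parameters)
  ci <- d |>
    dplyr::group_by(.data$group, .data$parameter) |>
    dplyr::summarise(lo = stats::quantile(.data$mean, 0.025),
                     hi = stats::quantile(.data$mean, 0.975),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$mean, colour = .data$group,
                                  fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.25) +
    ggplot2::geom_segment(data = ci,
                          ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       y = 0, yend = 0),
                          inherit.aes = FALSE, linewidth = 1.2) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "population mean", y = "posterior density",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-trial accuracy against contrast for one participant
#'
#' Binned empirical accuracy (quantile bins of log contrast) per
#' external-noise level — a quick visual check that simulated or observed
#' psychometric data behave monotonically.
#'
#' @param trials One participant's trial tibble.
#' @param bins Number of contrast bins per noise level.
#' @return A ggplot object.
#' @export
plot_psychometric <- function(trials, bins = 6) {
  df <- trials |>
    dplyr::group_by(.data$noise_index) |>
    dplyr::mutate(bin = dplyr::ntile(log(.data$contrast), bins)) |>
    dplyr::group_by(.data$noise_index, .data$bin) |>
    dplyr::summarise(contrast = exp(mean(log(.data$contrast))),
                     accuracy = mean(.data$correct), n = dplyr::n(),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(100 * .data$contrast, .data$accuracy)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~noise_index, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "contrast (%)", y = "proportion correct",
                  size = "trials") +
    ggplot2::theme_minimal()
}
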