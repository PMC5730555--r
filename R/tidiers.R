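#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL

#' Tidy a conventional group-coefficient PTM fit
#'
#' @param x A `ptm_group_fit`.
#' @param ... Unused.
#' @return One row per estimated parameter: `term`, `estimate`, `free`
#'   (whether the term is a freed group coefficient).
#' @method tidy ptm_group_fit
#' @export
tidy.ptm_group_fit <- function(x, ...) {
  est <- x$estimates
  tibble::tibble(term = names(est), estimate = unlist(est),
                 free = names(est) %in% x$free |
                   names(est) %in% c("n_add", "n_mul", "beta", "gamma"))
}

#' @rdname tidy.ptm_group_fit
#' @return `glance()`: a one-row model summary with `k`, `r_squared`,
#'   `sse`, and the freed coefficients.
#' @method glance ptm_group_fit
#' @export
glance.ptm_group_fit <- function(x, ...) {
  tibble::tibble(
    model = if (length(x$free) == 0) "null" else
      paste(x$free, collapse = "+"),
    k = x$k, r_squared = x$r_squared, sse = x$sse,
    ref_group = x$ref_group)
}

#' Tidy the eight-model comparison of the conventional PTM
#'
#' @param x A `ptm_model_set`.
#' @param ... Unused.
#' @return The comparison tibble (one row per candidate model, without the
#'   list-column of fits).
#' @method tidy ptm_model_set
#' @export
tidy.ptm_model_set <- function(x, ...) {
  dplyr::select(x$comparison, -"fit")
}

#' Tidy a hierarchical PTM fit
#'
#' @param x A `hier_fit`.
#' @param ... Unused.
#' @return Population-level summary: one row per (group, parameter) with
#'   the MAP of the population mean and SD and the 95% credible interval on
#'   the population mean.
#' @method tidy hier_fit
#' @export
tidy.hier_fit <- function(x, ...) {
  x$population_draws |>
    dplyr::group_by(.data$group, .data$parameter) |>
    dplyr::summarise(
      map_mean = map_from_draws(.data$mean),
      map_sd = map_from_draws(.data$sd),
      ci95_lo = stats::quantile(.data$mean, 0.025),
      ci95_hi = stats::quantile(.data$mean, 0.975),
      .groups = "drop")
}

#' @rdname tidy.hier_fit
#' @return `glance()`: a one-row fit summary with draw counts and the worst
#'   convergence statistic.
#' @method glance hier_fit
#' @export
glance.hier_fit <- function(x, ...) {
  tibble::tibble(
    chains = x$mcmc$chains,
    draws_per_chain = x$mcmc$draws_per_chain,
    participants = nrow(x$individual_map),
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    max_lag1 = max(abs(x$diagnostics$lag1_autocorrelation)))
}

#' Tidy a Weibull threshold fit
#'
#' @param x A `weibull_fit`.
#' @param ... Unused.
#' @return One row per difficulty level with the MAP parameters and the
#'   percent-contrast threshold.
#' @method tidy weibull_fit
#' @export
tidy.weibull_fit <- function(x, ...) {
  dplyr::mutate(x$thresholds, map_alpha = x$map_alpha,
                map_eta = x$map_eta)
}

#' @rdname tidy.weibull_fit
#' @method glance weibull_fit
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble::tibble(map_alpha = x$map_alpha, map_eta = x$map_eta,
                 n_trials = x$n_trials,
                 max_rhat = suppressWarnings(
                   max(x$diagnostics$rhat, na.rm = TRUE)))
}

#' Tidy a severity regression
#'
#' @param x A `severity_regression`.
#' @param ... Unused.
#' @return The coefficient tibble.
#' @method tidy severity_regression
#' @export
tidy.severity_regression <- function(x, ...) x$coefficients

#' @rdname tidy.severity_regression
#' @method glance severity_regression
#' @export
glance.severity_regression <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared,
                 adj_r_squared = x$adj_r_squared, f = x$f, df1 = x$df1,
                 df2 = x$df2, p = x$p, n = x$n)
}
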