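#' Link d-prime to two-alternative forced-choice proportion correct
#'
#' The linking function used throughout the package is `P = pnorm(d_prime / 2)`,
#' the standard 2AFC mapping for an unbiased observer. It reproduces the two
#' study difficulty levels, d' = 1.089 -> 70.71% and d' = 1.634 -> 79.37%, to
#' within 0.1%.
#'
#' @param d_prime Sensitivity (vectorized, >= 0).
#' @return Proportion correct in `[0.5, 1)`.
#' @examples
#' dprime_to_pc(c(0, 1.089, 1.634))
#' @export
dprime_to_pc <- function(d_prime) {
  if (any(d_prime < 0)) stop("`d_prime` must be >= 0", call. = FALSE)
  stats::pnorm(d_prime / 2)
}

#' @rdname dprime_to_pc
#' @param p Proportion correct, strictly inside `(0.5, 1)`.
#' @export
pc_to_dprime <- function(p) {
  if (any(p <= 0.5) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0.5, 1)", call. = FALSE)
  }
  2 * stats::qnorm(p)
}

#' Weibull psychometric function on log contrast
#'
#' Proportion correct for a 2AFC trial at stimulus contrast `contrast`
#' (percent units, so `log(contrast) > 0` over the operating range):
#' `P(c) = 1 - 0.5 * 2^(-(log(c) / alpha)^eta)`. `alpha` is the natural-log
#' contrast at which performance is exactly 75% (for any slope), and `eta`
#' is the slope.
#'
#' @param contrast Stimulus contrast in percent units (> 1, vectorized).
#' @param alpha Log-contrast threshold (natural log of percent contrast,
#'   > 0).
#' @param eta Slope (> 0).
#' @return Proportion correct in `(0.5, 1)`.
#' @examples
#' weibull_pc(exp(log(5)), alpha = log(5), eta = 2) # 0.75 exactly
#' @export
weibull_pc <- function(contrast, alpha, eta) {
  if (any(contrast <= 1)) {
    stop("`contrast` must exceed 1 (percent units; log must be positive)",
         call. = FALSE)
  }
  if (any(alpha <= 0) || any(eta <= 0)) {
    stop("`alpha` and `eta` must be strictly positive", call. = FALSE)
  }
  1 - 0.5 * 2^(-(log(contrast) / alpha)^eta)
}

#' Contrast threshold of a fitted Weibull at an arbitrary accuracy level
#'
#' Closed-form inverse of [weibull_pc()]: the percent contrast at which the
#' Weibull with parameters `(alpha, eta)` crosses proportion correct `q`.
#' At `q = 0.75` this is `exp(alpha)` for any slope.
#'
#' @param alpha Log-contrast threshold (natural-log percent units).
#' @param eta Slope (> 0).
#' @param q Target proportion correct, strictly inside `(0.5, 1)`.
#' @return Contrast in percent units.
#' @examples
#' weibull_threshold(log(4), 3, 0.75)   # = 4
#' weibull_threshold(log(4), 3, 0.7937) # the harder difficulty level
#' @export
weibull_threshold <- function(alpha, eta, q) {
  if (any(q <= 0.5) || any(q >= 1)) {
    stop("`q` must lie strictly inside (0.5, 1)", call. = FALSE)
  }
  exp(alpha * log2(0.5 / (1 - q))^(1 / eta))
}

#' Trial-level probability correct given a PTM threshold
#'
#' The trial-level psychometric function of the hierarchical model: a Weibull
#' on the ratio of log contrasts, anchored so that performance is exactly `q`
#' when the stimulus contrast equals the PTM threshold `c_tau` for that
#' difficulty level. Equivalently
#' `theta(x) = 1 - 0.5 * ((1 - q) / 0.5)^((log(x) / log(c_tau))^eta)`.
#' As `x` falls to 1 (percent units; log to 0) performance falls to chance,
#' and it saturates at 1 for large contrasts.
#'
#' @param x Stimulus contrast in percent units (> 1, vectorized).
#' @param c_tau Threshold contrast in percent units (> 1).
#' @param eta Slope (> 0).
#' @param q Difficulty level: the accuracy attained at threshold, strictly
#'   inside `(0.5, 1)`. The study's two levels are 0.7071 and 0.7937.
#' @return Probability of a correct response in `(0.5, 1)`.
#' @examples
#' trial_pc(x = 5, c_tau = 5, eta = 2, q = 0.7071) # exactly 0.7071
#' @export
trial_pc <- function(x, c_tau, eta, q) {
  if (any(q <= 0.5) || any(q >= 1)) {
    stop("`q` must lie strictly inside (0.5, 1)", call. = FALSE)
  }
  if (any(x <= 1) || any(c_tau <= 1)) {
    stop("`x` and `c_tau` must exceed 1 (percent units)", call. = FALSE)
  }
  if (any(eta <= 0)) stop("`eta` must be strictly positive", call. = FALSE)
  1 - 0.5 * ((1 - q) / 0.5)^((log(x) / log(c_tau))^eta)
}
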