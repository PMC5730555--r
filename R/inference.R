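#' Two-sample JZS default Bayes factor
#'
#' Evidence for the alternative over the null (`BF10`) for a two-sample t
#' statistic, with a Cauchy prior of scale `scale` on the standardized
#' effect size. Computed by adaptive quadrature over the equivalent
#' inverse-gamma mixture representation of the Cauchy prior (the scaled-g
#' form), with effective sample size `n1 * n2 / (n1 + n2)` and
#' `n1 + n2 - 2` degrees of freedom. By the conventional interpretation
#' bands, values below 0.33 support the null and above 3 the alternative;
#' between them the data are insensitive.
#'
#' @param t Observed t statistic.
#' @param n1,n2 Group sizes (each >= 2).
#' @param scale Cauchy prior scale on effect size (default 0.707).
#' @param rel_tol Relative tolerance of the quadrature.
#' @return A tibble of class `jzs_bf`: `bf10`, `t`, `n1`, `n2`, `scale`.
#' @examples
#' jzs_bf_two_sample(t = 0.34, n1 = 21, n2 = 20) # ~ 0.32
#' @export
jzs_bf_two_sample <- function(t, n1, n2, scale = 0.707, rel_tol = 1e-9) {
  stopifnot(n1 >= 2, n2 >= 2, scale > 0)
  n_eff <- n1 * n2 / (n1 + n2)
  nu <- n1 + n2 - 2
  r2 <- scale^2
  # g ~ InverseGamma(1/2, r^2/2) <=> Cauchy(0, r) on effect size
  integrand <- function(g) {
    (1 + n_eff * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n_eff * g) * nu))^(-(nu + 1) / 2) *
      sqrt(r2 / 2) / gamma(1 / 2) * g^(-3 / 2) * exp(-r2 / (2 * g))
  }
  alt <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = rel_tol,
                     subdivisions = 500L),
    error = function(e) stop("JZS quadrature failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  null <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  out <- tibble::tibble(bf10 = alt$value / null, t = t, n1 = n1, n2 = n2,
                        scale = scale)
  class(out) <- c("jzs_bf", class(out))
  out
}

#' Pearson correlation test
#'
#' Pearson's r with its t statistic (`t = r * sqrt(df / (1 - r^2))`,
#' `df = n - 2`) and two-sided p value.
#'
#' @param x,y Equal-length numeric vectors (n >= 3, both with nonzero
#'   variance).
#' @return A tibble: `r`, `t`, `df`, `p`, `n`.
#' @examples
#' pearson_test(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in `x` or `y`", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), t = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value, n = length(x))
}

#' Regress symptom severity on noise parameters
#'
#' Ordinary least squares of a severity score on a set of noise-parameter
#' predictors (typically internal additive noise and external-noise
#' filtering, optionally IQ), with per-coefficient t tests, overall variance
#' explained, and the overall F test.
#'
#' @param data Tibble containing the response and predictors.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names.
#' @return A list of class `severity_regression`: `coefficients` tibble
#'   (`term`, `estimate`, `std_error`, `t`, `p`), `r_squared`,
#'   `adj_r_squared`, `f`, `df1`, `df2`, `p`, `n`, and the underlying `lm`
#'   fit.
#' @export
ols_regression <- function(data, response = "severity",
                           predictors = c("n_add", "w_ext")) {
  stopifnot(all(c(response, predictors) %in% names(data)))
  n <- nrow(data)
  if (n <= length(predictors) + 1) {
    stop("need more rows than coefficients", call. = FALSE)
  }
  x <- stats::model.matrix(
    stats::reformulate(predictors), data = data)
  if (qr(x)$rank < ncol(x)) stop("predictors are rank deficient",
                                 call. = FALSE)
  fit <- stats::lm(stats::reformulate(predictors, response), data = data)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(coefficients = tibble::tibble(
           term = rownames(co), estimate = unname(co[, 1]),
           std_error = unname(co[, 2]), t = unname(co[, 3]),
           p = unname(co[, 4])),
         r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
         f = unname(sm$fstatistic[1]),
         df1 = unname(sm$fstatistic[2]), df2 = unname(sm$fstatistic[3]),
         p = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                       sm$fstatistic[3], lower.tail = FALSE),
         n = n, fit = fit),
    class = "severity_regression")
}
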