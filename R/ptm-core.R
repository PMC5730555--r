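#' Observer parameters for the Perceptual Template Model
#'
#' Bundles the noise and gain parameters that characterize a single PTM
#' observer: internal additive noise, internal multiplicative noise, an
#' external-noise filtering coefficient, template gain, and the transducer
#' exponent.
#'
#' @param n_add Internal additive noise, in contrast-proportion units.
#'   Signal-independent; sets the flat (low-noise) portion of the TvN curve.
#' @param n_mul Internal multiplicative noise (dimensionless). Proportional to
#'   response strength; alters the ratio between thresholds at different
#'   difficulty levels.
#' @param w_ext External-noise filtering coefficient (dimensionless multiplier
#'   on the external-noise contrast). 1 means the template passes external
#'   noise unattenuated; larger values mean worse filtering.
#' @param beta Template gain (> 0).
#' @param gamma Transducer exponent (> 0).
#'
#' @return A list of class `ptm_params`.
#' @examples
#' ptm_params(n_add = 0.0027, n_mul = 0.26, w_ext = 0.69)
#' @export
ptm_params <- function(n_add, n_mul = 0, w_ext = 1, beta = 1.25, gamma = 2) {
  vals <- c(n_add = n_add, n_mul = n_mul, w_ext = w_ext,
            beta = beta, gamma = gamma)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all PTM parameters must be finite and non-negative", call. = FALSE)
  }
  if (beta <= 0 || gamma <= 0) {
    stop("`beta` and `gamma` must be strictly positive", call. = FALSE)
  }
  structure(as.list(vals), class = "ptm_params")
}

#' Group coefficient multipliers for the group-level PTM
#'
#' The group-comparison form of the PTM multiplies each noise source by a
#' group coefficient: `a_m` on multiplicative noise, `a_a` on additive noise,
#' `a_e` on external noise. The reference group has all three fixed at 1;
#' coefficients above 1 for the comparison group mean more of that noise
#' source relative to the reference.
#'
#' @param a_m,a_a,a_e Positive multipliers on `n_mul`, `n_add`, and the
#'   external-noise contrast respectively.
#' @return A list of class `group_coefficients`.
#' @examples
#' unit_coefficients()
#' group_coefficients(a_a = 1.7, a_e = 1.13)
#' @export
group_coefficients <- function(a_m = 1, a_a = 1, a_e = 1) {
  if (any(!is.finite(c(a_m, a_a, a_e))) || any(c(a_m, a_a, a_e) <= 0)) {
    stop("group coefficients must be finite and strictly positive",
         call. = FALSE)
  }
  structure(list(a_m = a_m, a_a = a_a, a_e = a_e),
            class = "group_coefficients")
}

#' @rdname group_coefficients
#' @export
unit_coefficients <- function() group_coefficients(1, 1, 1)

#' PTM contrast threshold
#'
#' Forward model of the Perceptual Template Model: the signal contrast needed
#' to reach sensitivity `d_prime` in the presence of external noise of RMS
#' contrast `n_ext`, for an observer with parameters `params` and (optionally)
#' group coefficient multipliers `coeffs`. The external-noise term enters as
#' `a_e * w_ext * n_ext`, i.e. filtering and the group coefficient both scale
#' the nominal external-noise contrast.
#'
#' @param params A [ptm_params()] object.
#' @param coeffs A [group_coefficients()] object; defaults to the reference
#'   group (all 1).
#' @param d_prime Target sensitivity (scalar, > 0).
#' @param n_ext External-noise RMS contrast as a proportion (vectorized,
#'   >= 0).
#' @return Contrast threshold(s) as proportions, same length as `n_ext`.
#' @details The sensitivity must be attainable: multiplicative noise bounds
#'   d-prime above by `1 / (a_m * n_mul)`; requesting a d-prime at or beyond
#'   that bound is an error because no finite contrast reaches it.
#' @examples
#' p <- ptm_params(n_add = 0.0027, n_mul = 0.26, w_ext = 0.69)
#' ptm_threshold(p, d_prime = 1.089, n_ext = c(0, 0.051, 0.21))
#' @export
ptm_threshold <- function(params, coeffs = unit_coefficients(), d_prime,
                          n_ext) {
  stopifnot(inherits(params, "ptm_params"),
            inherits(coeffs, "group_coefficients"))
  if (any(n_ext < 0)) stop("`n_ext` must be >= 0", call. = FALSE)
  if (length(d_prime) != 1L || d_prime <= 0) {
    stop("`d_prime` must be a single positive value", call. = FALSE)
  }
  m <- coeffs$a_m * params$n_mul
  denom <- 1 / d_prime^2 - m^2
  if (denom <= 0) {
    stop("infeasible sensitivity: d_prime * (a_m * n_mul) >= 1, ",
         "no finite contrast achieves this d-prime", call. = FALSE)
  }
  a <- coeffs$a_a * params$n_add
  e <- coeffs$a_e * params$w_ext * n_ext
  g2 <- 2 * params$gamma
  num <- (1 + m^2) * e^g2 + a^2
  (1 / params$beta) * (num / denom)^(1 / g2)
}

#' PTM sensitivity at a given contrast
#'
#' Inverse of [ptm_threshold()]: the d-prime an observer attains at signal
#' contrast `contrast` under external noise `n_ext`. With multiplicative
#' noise present, d-prime saturates at `1 / n_mul` as contrast grows.
#'
#' @param params A [ptm_params()] object.
#' @param contrast Signal contrast as a proportion (vectorized, >= 0).
#' @param n_ext External-noise RMS contrast as a proportion (scalar or same
#'   length as `contrast`).
#' @return Sensitivity d-prime, >= 0.
#' @examples
#' p <- ptm_params(n_add = 0.0027, n_mul = 0.26, w_ext = 0.69)
#' ct <- ptm_threshold(p, d_prime = 1.634, n_ext = 0.103)
#' ptm_dprime(p, ct, 0.103) # recovers 1.634
#' @export
ptm_dprime <- function(params, contrast, n_ext) {
  stopifnot(inherits(params, "ptm_params"))
  if (any(contrast < 0)) stop("`contrast` must be >= 0", call. = FALSE)
  if (any(n_ext < 0)) stop("`n_ext` must be >= 0", call. = FALSE)
  g <- params$gamma
  s <- (params$beta * contrast)^g
  e <- params$w_ext * n_ext
  s / sqrt((1 + params$n_mul^2) * e^(2 * g) + params$n_add^2 +
             params$n_mul^2 * s^2)
}
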