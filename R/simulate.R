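# Truncated-at-zero Gaussian draws via the inverse-CDF; sd = 0 collapses to
# the mean (which must itself be >= 0 for a valid spec).
rnorm_trunc0 <- function(n, mean, sd, upper = Inf) {
  if (sd == 0) return(rep(min(mean, upper), n))
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Draw a population of PTM observers from a group specification
#'
#' Samples `spec$n` participants, each parameter independently from a
#' Gaussian with the group's population mean and SD, truncated at zero
#' (negative noise is non-physical in the forward model).
#'
#' @param spec A [group_spec()].
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @param n_mul_max Optional upper truncation for multiplicative noise, used
#'   by [simulate_study()] to guarantee every sampled observer can attain the
#'   design's hardest d-prime (`n_mul < 1 / max(d')`).
#' @return A tibble with one row per participant: `participant_id`, `group`,
#'   `n_add`, `n_mul`, `w_ext`, `eta`.
#' @examples
#' sample_population(control_group_spec(), seed = 1)
#' @export
sample_population <- function(spec, seed = NULL, n_mul_max = Inf) {
  stopifnot(inherits(spec, "group_spec"))
  draw <- function() {
    tibble::tibble(
      participant_id = paste0(spec$label, "_", seq_len(spec$n)),
      group = spec$label,
      n_add = rnorm_trunc0(spec$n, spec$n_add_mean, spec$n_add_sd),
      n_mul = rnorm_trunc0(spec$n, spec$n_mul_mean, spec$n_mul_sd,
                           upper = n_mul_max),
      w_ext = rnorm_trunc0(spec$n, spec$w_ext_mean, spec$w_ext_sd),
      eta = rnorm_trunc0(spec$n, spec$eta_mean, spec$eta_sd)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Contrast placement for one (structure, level) cell, in percent units.
# The oracle grid spans 0.25x-4x the observer's true threshold on a log
# grid, floored at 1.05% so log contrast stays positive.
schedule_contrasts <- function(schedule, c_tau_pct, n_trials, params, eta,
                               n_ext, q) {
  floor_pct <- 1.05
  if (schedule == "oracle-grid") {
    lo <- max(floor_pct, 0.25 * c_tau_pct)
    hi <- max(4 * c_tau_pct, lo * 1.5)
    return(exp(seq(log(lo), log(hi), length.out = n_trials)))
  }
  n_down <- if (schedule == "staircase-2down1up") 2L else 3L
  step <- 0.1 # log-contrast step
  x <- log(max(2 * c_tau_pct, floor_pct * 2))
  out <- numeric(n_trials)
  streak <- 0L
  for (k in seq_len(n_trials)) {
    out[k] <- exp(x)
    p <- dprime_to_pc(ptm_dprime(params, exp(x) / 100, n_ext))
    correct <- stats::runif(1) < p
    if (correct) {
      streak <- streak + 1L
      if (streak >= n_down) {
        x <- x - step
        streak <- 0L
      }
    } else {
      x <- x + step
      streak <- 0L
    }
    x <- min(max(x, log(floor_pct)), log(99))
  }
  out
}

#' Simulate one participant's equivalent-noise session
#'
#' Generates trial-level 2AFC data for a single PTM observer under a design:
#' for each (difficulty structure, noise level) cell the schedule places
#' `trials_per_level_per_structure` stimulus contrasts, and each response is
#' drawn Bernoulli with success probability
#' `dprime_to_pc(ptm_dprime(params, contrast, n_ext))`.
#'
#' @param params A [ptm_params()] observer.
#' @param eta Psychometric slope carried with the observer (recorded per
#'   trial for downstream fitting; the generative response path runs through
#'   the PTM d-prime, not the slope).
#' @param design A [design_spec()].
#' @param seed Optional integer seed.
#' @param participant_id,group Labels stamped on every trial.
#' @return A tibble of trials: `participant_id`, `group`, `structure`,
#'   `noise_index`, `n_ext`, `contrast` (proportion), `correct` (0/1).
#' @examples
#' p <- ptm_params(n_add = 0.0027, n_mul = 0.26, w_ext = 0.69)
#' trials <- simulate_session(p, eta = 2, design_spec(), seed = 7)
#' dplyr::count(trials, noise_index)
#' @export
simulate_session <- function(params, eta, design = design_spec(), seed = NULL,
                             participant_id = "p1", group = "none") {
  stopifnot(inherits(params, "ptm_params"), inherits(design, "design_spec"))
  run <- function() {
    cells <- tidyr::expand_grid(
      structure = seq_along(design$d_primes),
      noise_index = seq_along(design$noise_levels)
    )
    purrr::pmap_dfr(cells, function(structure, noise_index) {
      dp <- design$d_primes[structure]
      ne <- design$noise_levels[noise_index]
      c_tau_pct <- 100 * ptm_threshold(params, d_prime = dp, n_ext = ne)
      x_pct <- schedule_contrasts(design$contrast_schedule, c_tau_pct,
                                  design$trials_per_level_per_structure,
                                  params, eta, ne,
                                  design$q_levels[structure])
      pcorr <- dprime_to_pc(ptm_dprime(params, x_pct / 100, ne))
      tibble::tibble(
        participant_id = participant_id, group = group,
        structure = structure, noise_index = noise_index, n_ext = ne,
        contrast = x_pct / 100,
        correct = as.integer(stats::runif(length(x_pct)) < pcorr)
      )
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Severity-score link specification
#'
#' Linear link from internal additive noise to an integer symptom-severity
#' score: `severity = round(clip(intercept + slope * n_add + N(0, sd), 4, 9))`
#' for case-group participants. The defaults are calibrated so that the
#' default study scenario yields a Pearson correlation of about 0.59 between
#' additive noise and severity; the slope matches the regression coefficient
#' scale of the severity-on-noise analysis.
#'
#' @param intercept,slope,residual_sd Link parameters.
#' @return A list of class `severity_link`.
#' @export
severity_link <- function(intercept = 4.3, slope = 555.88,
                          residual_sd = 1.0) {
  stopifnot(residual_sd >= 0)
  structure(list(intercept = intercept, slope = slope,
                 residual_sd = residual_sd),
            class = "severity_link")
}

#' Simulate a complete two-group equivalent-noise study
#'
#' Draws case and control populations, simulates every participant's session,
#' and assigns integer severity scores (range 4-9) to case participants via
#' the severity link. The returned truth table retains every sampled
#' parameter for recovery testing, including a flag for severity scores that
#' hit the clipping bounds.
#'
#' @param case_spec,control_spec [group_spec()]s for the two groups.
#' @param link A [severity_link()].
#' @param design A [design_spec()].
#' @param seed Integer seed (required: a study is a reproducible unit).
#' @param case_coeffs Optional [group_coefficients()] applied to case-group
#'   observers on top of their sampled parameters (used to inject known group
#'   effects, e.g. `group_coefficients(a_a = 1.7, a_e = 1.13)`, for recovery
#'   experiments). Applied as `n_add * a_a`, `w_ext * a_e`, `n_mul * a_m`.
#' @return A list of class `en_study` with tibbles `trials`, `truth`, and
#'   `severity` (case participants only).
#' @examples
#' \donttest{
#' study <- simulate_study(seed = 42)
#' dplyr::count(study$trials, group)
#' }
#' @export
simulate_study <- function(case_spec = case_group_spec(),
                           control_spec = control_group_spec(),
                           link = severity_link(),
                           design = design_spec(),
                           seed,
                           case_coeffs = unit_coefficients()) {
  stopifnot(inherits(link, "severity_link"), inherits(design, "design_spec"))
  n_mul_max <- 0.99 / max(design$d_primes)
  withr::with_seed(seed, {
    pops <- dplyr::bind_rows(
      sample_population(case_spec, n_mul_max = n_mul_max / case_coeffs$a_m),
      sample_population(control_spec, n_mul_max = n_mul_max)
    )
    is_case <- pops$group == case_spec$label
    pops$n_add[is_case] <- pops$n_add[is_case] * case_coeffs$a_a
    pops$n_mul[is_case] <- pops$n_mul[is_case] * case_coeffs$a_m
    pops$w_ext[is_case] <- pops$w_ext[is_case] * case_coeffs$a_e

    trials <- purrr::pmap_dfr(pops, function(participant_id, group, n_add,
                                             n_mul, w_ext, eta) {
      simulate_session(ptm_params(n_add, n_mul, w_ext), eta, design,
                       participant_id = participant_id, group = group)
    })

    case <- pops[is_case, ]
    raw <- link$intercept + link$slope * case$n_add +
      stats::rnorm(nrow(case), 0, link$residual_sd)
    severity <- tibble::tibble(
      participant_id = case$participant_id,
      severity = as.integer(round(pmin(pmax(raw, 4), 9)))
    )
    truth <- dplyr::left_join(pops, severity, by = "participant_id")
    truth$severity_clipped <- !is.na(truth$severity) &
      (raw[match(truth$participant_id, case$participant_id)] < 4 |
         raw[match(truth$participant_id, case$participant_id)] > 9)

    structure(list(trials = trials, truth = truth, severity = severity,
                   design = design, seed = seed),
              class = "en_study")
  })
}
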