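#' Prior ranges for the Weibull threshold stage
#'
#' Broad uniform priors over the practically possible range: the log-contrast
#' threshold `alpha` spans contrasts 1.05% to 100% (natural-log percent
#' units; the lower edge keeps log contrast positive, which the log-Weibull
#' form requires), and the slope `eta` spans 0.1 to 10.
#'
#' @param alpha_range,eta_range Length-2 numeric ranges.
#' @return A list of class `weibull_prior`.
#' @export
weibull_prior <- function(alpha_range = c(log(1.05), log(100)),
                          eta_range = c(0.1, 10)) {
  stopifnot(alpha_range[1] > 0, diff(alpha_range) > 0, eta_range[1] > 0,
            diff(eta_range) > 0)
  structure(list(alpha_range = alpha_range, eta_range = eta_range),
            class = "weibull_prior")
}

#' Bayesian Weibull threshold fit for one external-noise level
#'
#' Fits the log-contrast Weibull psychometric function to the pooled trials
#' of one participant at one external-noise level, by random-walk Metropolis
#' sampling of the posterior under a Bernoulli likelihood and broad uniform
#' priors. Point estimates are maximum a posteriori, taken as the mode of the
#' pooled thinned draws ([map_from_draws()]); contrast thresholds at the two
#' study difficulty levels are computed from the MAP parameters by the
#' closed-form inverse ([weibull_threshold()]).
#'
#' @param trials Tibble with columns `contrast` (proportion, all > 0.0105 so
#'   percent log-contrast is positive) and `correct` (0/1). At least 20
#'   trials, not all identical responses.
#' @param mcmc An [mcmc_config()]; the study protocol default is
#'   `mcmc_config(chains = 10, burn_in = 15000, thin = 200,
#'   draws_per_chain = 1000)`. Examples and simulations use lighter settings.
#' @param seed Integer seed.
#' @param prior A [weibull_prior()].
#' @param q_levels Accuracy levels at which to report thresholds.
#' @param rhat_warn Warn when any split statistic exceeds this value.
#' @return An object of class `weibull_fit`: MAP estimates `map_alpha`,
#'   `map_eta`, a `thresholds` tibble (percent units), the labeled `draws`
#'   tibble (chain, iteration, alpha, eta) and convergence `diagnostics`.
#' @examples
#' p <- ptm_params(n_add = 0.0027, n_mul = 0.26, w_ext = 0.69)
#' tr <- simulate_session(p, 2, design_spec(), seed = 1)
#' one <- dplyr::filter(tr, noise_index == 1)
#' fit <- fit_weibull(one, mcmc_config(2, 300, 2, 300), seed = 1)
#' fit$map_alpha
#' @export
fit_weibull <- function(trials, mcmc = mcmc_config(draws_per_chain = 1000),
                        seed = 1, prior = weibull_prior(),
                        q_levels = c(0.7071, 0.7937), rhat_warn = 1.2) {
  stopifnot(inherits(mcmc, "mcmc_config"), inherits(prior, "weibull_prior"))
  if (nrow(trials) < 20) stop("need at least 20 trials", call. = FALSE)
  y <- trials$correct
  if (all(y == 1) || all(y == 0)) {
    stop("degenerate data: all responses identical", call. = FALSE)
  }
  x_pct <- trials$contrast * 100
  if (any(x_pct <= 1)) {
    stop("all contrasts must exceed 1% (positive log contrast)",
         call. = FALSE)
  }
  lx <- log(x_pct)
  ar <- prior$alpha_range
  er <- prior$eta_range
  log_post <- function(th) {
    a <- th[1]
    e <- th[2]
    if (a <= ar[1] || a >= ar[2] || e <= er[1] || e >= er[2]) return(-Inf)
    # floor/ceiling guards against underflow of the tail probabilities
    p <- pmin(pmax(1 - 0.5 * 2^(-(lx / a)^e), 1e-12), 1 - 1e-12)
    sum(log(ifelse(y == 1, p, 1 - p)))
  }
  mats <- lapply(seq_len(mcmc$chains), function(ch) {
    withr::with_seed(derive_seed(seed, paste0("weibull_chain", ch)), {
      init <- function() {
        c(stats::runif(1, ar[1] + 0.1 * diff(ar), ar[2] - 0.4 * diff(ar)),
          stats::runif(1, 0.5, 4))
      }
      metropolis_chain(log_post, init, step = c(0.15, 0.3), cfg = mcmc)
    })
  })
  pooled <- do.call(rbind, mats)
  map_alpha <- map_from_draws(pooled[, 1])
  map_eta <- map_from_draws(pooled[, 2])
  diag <- chain_diagnostics(mats)
  names(diag$rhat) <- names(diag$lag1_autocorrelation) <- c("alpha", "eta")
  if (mcmc$chains > 1 && any(diag$rhat > rhat_warn, na.rm = TRUE)) {
    warning("Weibull fit may not have converged: split statistic ",
            sprintf("%.2f", max(diag$rhat, na.rm = TRUE)),
            " exceeds ", rhat_warn, call. = FALSE)
  }
  draws <- tibble::tibble(
    chain = rep(seq_len(mcmc$chains), each = mcmc$draws_per_chain),
    iteration = rep(seq_len(mcmc$draws_per_chain), mcmc$chains),
    alpha = pooled[, 1], eta = pooled[, 2])
  structure(
    list(map_alpha = map_alpha, map_eta = map_eta,
         thresholds = tibble::tibble(
           q = q_levels,
           threshold = weibull_threshold(map_alpha, map_eta, q_levels)),
         draws = draws, diagnostics = diag, n_trials = nrow(trials)),
    class = "weibull_fit")
}

#' Per-participant, per-noise-level threshold estimation
#'
#' The first stage of the conventional pipeline: pools the two difficulty
#' structures at each external-noise level (60 trials per level under the
#' default design) and fits an independent Weibull to each
#' (participant, level) cell, returning thresholds at the two difficulty
#' accuracies.
#'
#' @param trials Trial tibble as produced by [simulate_session()] /
#'   [simulate_study()] or read by [read_trials()].
#' @param mcmc An [mcmc_config()] applied to every cell.
#' @param seed Integer seed; each cell gets a derived sub-seed.
#' @inheritParams fit_weibull
#' @return A tibble with one row per (participant, noise level, q):
#'   `participant_id`, `group`, `noise_index`, `n_ext`, `map_alpha`,
#'   `map_eta`, `q`, `threshold` (percent units).
#' @export
fit_weibull_thresholds <- function(trials,
                                   mcmc = mcmc_config(draws_per_chain = 1000),
                                   seed = 1,
                                   prior = weibull_prior(),
                                   q_levels = c(0.7071, 0.7937),
                                   rhat_warn = 1.2) {
  cells <- dplyr::distinct(trials, .data$participant_id, .data$group,
                           .data$noise_index, .data$n_ext)
  purrr::pmap_dfr(cells, function(participant_id, group, noise_index,
                                  n_ext) {
    cell <- trials[trials$participant_id == participant_id &
                     trials$noise_index == noise_index, ]
    fit <- fit_weibull(cell, mcmc,
                       seed = derive_seed(seed, paste0(participant_id, "_",
                                                       noise_index)),
                       prior = prior, q_levels = q_levels,
                       rhat_warn = rhat_warn)
    dplyr::mutate(fit$thresholds,
                  participant_id = participant_id, group = group,
                  noise_index = noise_index, n_ext = n_ext,
                  map_alpha = fit$map_alpha, map_eta = fit$map_eta,
                  .before = 1)
  })
}
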