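#' Population specification for one participant group
#'
#' Describes the group-level Gaussian population distributions from which
#' individual observer parameters are drawn: a mean and SD for each of the
#' three noise parameters and for the psychometric slope. Draws are truncated
#' at zero, since negative noise is non-physical in the forward model.
#'
#' Defaults mirror the two study groups: the control (typically developing)
#' group with population means n_add = 0.0027, n_mul = 0.26, w_ext = 0.69, and
#' the case (autism) group with n_add = 0.004, n_mul = 0.11, w_ext = 0.86 and
#' roughly twice the between-participant spread in n_add and w_ext.
#'
#' @param label Group name (character scalar).
#' @param n Number of participants (>= 2).
#' @param n_add_mean,n_add_sd Population mean / SD of internal additive noise
#'   (contrast-proportion units).
#' @param n_mul_mean,n_mul_sd Population mean / SD of internal multiplicative
#'   noise.
#' @param w_ext_mean,w_ext_sd Population mean / SD of the external-noise
#'   filtering coefficient.
#' @param eta_mean,eta_sd Population mean / SD of the psychometric slope.
#' @return A list of class `group_spec`.
#' @examples
#' control_group_spec()
#' case_group_spec()
#' @export
group_spec <- function(label, n,
                       n_add_mean, n_add_sd,
                       n_mul_mean, n_mul_sd,
                       w_ext_mean, w_ext_sd,
                       eta_mean = 2, eta_sd = 0.3) {
  stopifnot(is.character(label), length(label) == 1L, n >= 2)
  sds <- c(n_add_sd, n_mul_sd, w_ext_sd, eta_sd)
  if (any(sds < 0)) stop("population SDs must be >= 0", call. = FALSE)
  structure(
    list(label = label, n = as.integer(n),
         n_add_mean = n_add_mean, n_add_sd = n_add_sd,
         n_mul_mean = n_mul_mean, n_mul_sd = n_mul_sd,
         w_ext_mean = w_ext_mean, w_ext_sd = w_ext_sd,
         eta_mean = eta_mean, eta_sd = eta_sd),
    class = "group_spec")
}

#' @rdname group_spec
#' @export
control_group_spec <- function(label = "control", n = 20) {
  group_spec(label, n,
             n_add_mean = 0.0027, n_add_sd = 0.0008,
             n_mul_mean = 0.26, n_mul_sd = 0.10,
             w_ext_mean = 0.69, w_ext_sd = 0.08)
}

#' @rdname group_spec
#' @export
case_group_spec <- function(label = "case", n = 21) {
  group_spec(label, n,
             n_add_mean = 0.004, n_add_sd = 0.0016,
             n_mul_mean = 0.11, n_mul_sd = 0.10,
             w_ext_mean = 0.86, w_ext_sd = 0.16)
}

#' Experimental design for a simulated equivalent-noise session
#'
#' Fixes the external-noise levels, trial counts, difficulty levels, and
#' contrast-placement schedule of a simulated session. The defaults reproduce
#' the study design: 8 external-noise RMS contrasts (0 to 21%), two
#' interleaved difficulty structures (d' = 1.089 and 1.634, i.e. accuracy
#' targets 70.71% and 79.37%), and 30 trials per level per structure for 480
#' trials in total (60 per noise level after pooling structures).
#'
#' @param noise_levels External-noise RMS contrasts as proportions.
#' @param trials_per_level_per_structure Trials at each (noise level,
#'   difficulty structure) cell.
#' @param d_primes Sensitivity targets of the two interleaved structures.
#' @param contrast_schedule `"oracle-grid"` (log-spaced contrasts spanning
#'   0.25x to 4x the observer's true threshold for that cell — concentrating
#'   trials near threshold as an adaptive procedure would), or
#'   `"staircase-2down1up"` / `"staircase-3down1up"` for standard staircases
#'   on log contrast.
#' @return A list of class `design_spec`.
#' @examples
#' design_spec()
#' @export
design_spec <- function(noise_levels = c(0, 0.003, 0.0061, 0.0124, 0.0251,
                                         0.051, 0.103, 0.21),
                        trials_per_level_per_structure = 30,
                        d_primes = c(1.089, 1.634),
                        contrast_schedule = c("oracle-grid",
                                              "staircase-2down1up",
                                              "staircase-3down1up")) {
  contrast_schedule <- match.arg(contrast_schedule)
  stopifnot(all(noise_levels >= 0), trials_per_level_per_structure >= 1,
            length(d_primes) >= 1, all(d_primes > 0))
  structure(
    list(noise_levels = noise_levels,
         trials_per_level_per_structure =
           as.integer(trials_per_level_per_structure),
         d_primes = d_primes,
         q_levels = dprime_to_pc(d_primes),
         contrast_schedule = contrast_schedule),
    class = "design_spec")
}

#' MCMC protocol configuration
#'
#' Chain protocol for the Bayesian fitting stages. The defaults follow the
#' study protocol: 15,000 burn-in iterations, thinning to every 200th sample,
#' and 10 parallel chains (2,000 retained draws per chain for the hierarchical
#' model; pass `draws_per_chain = 1000` for the Weibull stage). Recovery
#' simulations and examples use much lighter settings.
#'
#' @param chains Number of chains.
#' @param burn_in Iterations discarded before retention.
#' @param thin Keep every `thin`-th iteration after burn-in.
#' @param draws_per_chain Retained draws per chain.
#' @param adapt Iterations of step-size adaptation at the start of burn-in
#'   (must not exceed `burn_in`; adaptation is frozen afterwards so the
#'   retained chain is a valid Metropolis sample).
#' @return A list of class `mcmc_config`.
#' @examples
#' mcmc_config()                                 # full study protocol
#' mcmc_config(chains = 2, burn_in = 500, thin = 2, draws_per_chain = 500)
#' @export
mcmc_config <- function(chains = 10, burn_in = 15000, thin = 200,
                        draws_per_chain = 2000,
                        adapt = min(burn_in, 500)) {
  stopifnot(chains >= 1, burn_in >= 0, thin >= 1, draws_per_chain >= 1,
            adapt <= burn_in)
  structure(list(chains = as.integer(chains), burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 draws_per_chain = as.integer(draws_per_chain),
                 adapt = as.integer(adapt)),
            class = "mcmc_config")
}
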