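#' Hyperprior bounds for the hierarchical PTM
#'
#' The population mean and SD of each individual-level parameter carry broad
#' uniform hyperpriors; these bounds make "broad" concrete and configurable.
#' Parameter order everywhere is `n_add`, `n_mul`, `w_ext`, `eta`.
#'
#' @param mean_lo,mean_hi,sd_lo,sd_hi Length-4 numeric bounds.
#' @return A list of class `hier_bounds`.
#' @export
hier_bounds <- function(mean_lo = c(1e-4, 0, 0, 0.1),
                        mean_hi = c(1, 3, 5, 10),
                        sd_lo = c(0, 0, 0, 0),
                        sd_hi = c(0.5, 2, 2, 5)) {
  stopifnot(length(mean_lo) == 4, length(mean_hi) == 4, length(sd_lo) == 4,
            length(sd_hi) == 4, all(mean_hi > mean_lo), all(sd_hi > sd_lo))
  structure(list(mean_lo = mean_lo, mean_hi = mean_hi, sd_lo = sd_lo,
                 sd_hi = sd_hi, params = c("n_add", "n_mul", "w_ext", "eta")),
            class = "hier_bounds")
}

# Per-participant trial bundle with everything the likelihood needs
# precomputed: log percent contrasts, cell index into the (structure x
# level) threshold grid, the per-trial log((1-q)/0.5) base, and index sets
# of correct / incorrect trials.
prep_hier_data <- function(trials, d_primes, q_levels) {
  needed <- c("participant_id", "group", "structure", "noise_index",
              "n_ext", "contrast", "correct")
  if (!all(needed %in% names(trials))) {
    stop("trials are missing columns: ",
         paste(setdiff(needed, names(trials)), collapse = ", "),
         call. = FALSE)
  }
  if (any(trials$contrast * 100 <= 1)) {
    stop("all contrasts must exceed 1% for the trial-level model",
         call. = FALSE)
  }
  lev <- dplyr::distinct(trials, .data$noise_index, .data$n_ext) |>
    dplyr::arrange(.data$noise_index)
  noise_levels <- lev$n_ext
  n_lev <- nrow(lev)
  participants <- dplyr::distinct(trials, .data$participant_id, .data$group)
  parts <- lapply(seq_len(nrow(participants)), function(i) {
    tr <- trials[trials$participant_id == participants$participant_id[i], ]
    list(lx = log(tr$contrast * 100),
         cell = (tr$structure - 1L) * n_lev + tr$noise_index,
         lbase = log((1 - q_levels[tr$structure]) / 0.5),
         ci = which(tr$correct == 1L),
         cw = which(tr$correct == 0L))
  })
  list(parts = parts, participants = participants,
       noise_levels = noise_levels, d_primes = d_primes,
       q_levels = q_levels)
}

# Log percent thresholds for every (structure, level) cell; NULL signals an
# out-of-support parameter vector (infeasible d-prime or threshold <= 1%).
cell_log_thresholds <- function(th, beta, gamma, d_primes, noise_levels) {
  n_mul2 <- th[2]^2
  e2g <- (th[3] * noise_levels)^(2 * gamma)
  num <- (1 + n_mul2) * e2g + th[1]^2
  out <- numeric(length(d_primes) * length(noise_levels))
  for (s in seq_along(d_primes)) {
    denom <- 1 / d_primes[s]^2 - n_mul2
    if (denom <= 0) return(NULL)
    idx <- (s - 1L) * length(noise_levels) + seq_along(noise_levels)
    out[idx] <- log(100 / beta) + log(num / denom) / (2 * gamma)
  }
  if (any(out <= 0)) return(NULL)
  out
}

# Bernoulli log likelihood of one participant's trials given raw parameters
# th = (n_add, n_mul, w_ext, eta).
part_loglik <- function(pd, th, beta, gamma, d_primes, noise_levels) {
  if (any(th < 0) || th[4] <= 0) return(-Inf)
  lct <- cell_log_thresholds(th, beta, gamma, d_primes, noise_levels)
  if (is.null(lct)) return(-Inf)
  r <- (pd$lx / lct[pd$cell])^th[4]
  l1m <- log(0.5) + pd$lbase * r # log(1 - theta), always <= log(0.5)
  sum(log1p(-exp(l1m[pd$ci]))) + sum(l1m[pd$cw])
}

# Gaussian population density truncated at zero, in log form.
ltrunc_norm <- function(x, m, s) {
  stats::dnorm(x, m, s, log = TRUE) -
    stats::pnorm(0, m, s, lower.tail = FALSE, log.p = TRUE)
}

#' Maximum-likelihood PTM fit for a single participant
#'
#' Fits the four individual-level parameters of the trial-level PTM
#' (`n_add`, `n_mul`, `w_ext`, `eta`) to one participant's raw trials by
#' maximizing the Bernoulli likelihood, with the template gain and
#' transducer exponent fixed. Used both as a flat (non-hierarchical)
#' baseline and to initialize the hierarchical sampler.
#'
#' @param trials One participant's trials.
#' @param beta,gamma Fixed template gain and transducer exponent.
#' @param d_primes,q_levels Difficulty structure: target sensitivities and
#'   the accuracies attained at threshold.
#' @return A tibble row: `participant_id`, `group`, `n_add`, `n_mul`,
#'   `w_ext`, `eta`, `loglik`.
#' @export
fit_ptm_mle <- function(trials, beta = 1.25, gamma = 2,
                        d_primes = c(1.089, 1.634),
                        q_levels = c(0.7071, 0.7937)) {
  hd <- prep_hier_data(trials, d_primes, q_levels)
  if (nrow(hd$participants) != 1) {
    stop("`trials` must contain exactly one participant", call. = FALSE)
  }
  pd <- hd$parts[[1]]
  obj <- function(z) {
    ll <- part_loglik(pd, exp(z), beta, gamma, d_primes, hd$noise_levels)
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- stats::optim(log(c(0.003, 0.12, 0.8, 2)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  th <- exp(opt$par)
  tibble::tibble(participant_id = hd$participants$participant_id,
                 group = hd$participants$group,
                 n_add = th[1], n_mul = th[2], w_ext = th[3], eta = th[4],
                 loglik = -opt$value)
}

#' Log posterior density of the hierarchical PTM
#'
#' The full joint log density: Bernoulli trial likelihoods through the
#' trial-level psychometric function with PTM thresholds, plus
#' truncated-Gaussian population terms linking each individual parameter to
#' its group's population mean and SD, plus uniform hyperpriors on those
#' population parameters. Returns `-Inf` for any state outside the support.
#'
#' @param state A list with `individual` (tibble: `participant_id`, `group`,
#'   `n_add`, `n_mul`, `w_ext`, `eta`) and `population` (tibble: `group`,
#'   `parameter`, `mean`, `sd`).
#' @param trials Trial tibble covering the same participants.
#' @param beta,gamma Fixed template gain and transducer exponent.
#' @param d_primes,q_levels Difficulty structure.
#' @param bounds A [hier_bounds()].
#' @return Scalar log density.
#' @export
hier_log_posterior <- function(state, trials, beta = 1.25, gamma = 2,
                               d_primes = c(1.089, 1.634),
                               q_levels = c(0.7071, 0.7937),
                               bounds = hier_bounds()) {
  hd <- prep_hier_data(trials, d_primes, q_levels)
  ind <- state$individual[match(hd$participants$participant_id,
                                state$individual$participant_id), ]
  pop <- state$population
  pnames <- bounds$params
  total <- 0
  for (g in unique(ind$group)) {
    pg <- pop[pop$group == g, ]
    mu <- pg$mean[match(pnames, pg$parameter)]
    sg <- pg$sd[match(pnames, pg$parameter)]
    if (any(mu < bounds$mean_lo | mu > bounds$mean_hi) ||
        any(sg <= bounds$sd_lo | sg > bounds$sd_hi)) {
      return(-Inf)
    }
    rows <- which(ind$group == g)
    for (j in seq_along(pnames)) {
      x <- ind[[pnames[j]]][rows]
      if (any(x < 0)) return(-Inf)
      total <- total + sum(ltrunc_norm(x, mu[j], sg[j]))
    }
  }
  for (i in seq_len(nrow(ind))) {
    th <- c(ind$n_add[i], ind$n_mul[i], ind$w_ext[i], ind$eta[i])
    ll <- part_loglik(hd$parts[[i]], th, beta, gamma, d_primes,
                      hd$noise_levels)
    if (!is.finite(ll)) return(-Inf)
    total <- total + ll
  }
  total
}

#' Fit the trial-level hierarchical Bayesian PTM
#'
#' Samples the joint posterior over individual parameters (`n_add`, `n_mul`,
#' `w_ext`, `eta` per participant) and group-level population means and SDs
#' by Metropolis-within-Gibbs: each participant's block is updated with a
#' log-scale random walk against their own trial likelihood and population
#' prior, then each (group, parameter) population block is updated against
#' its individuals and the uniform hyperpriors. Step sizes adapt only during
#' burn-in. Chains are initialized from jittered per-participant
#' maximum-likelihood fits.
#'
#' @param trials Trial tibble (two or more participants per group).
#' @param mcmc An [mcmc_config()]; the study protocol default is heavy
#'   (10 chains, 15,000 burn-in, thin 200, 2,000 draws per chain) — pass
#'   lighter settings for simulations and examples.
#' @param seed Integer seed.
#' @param beta,gamma Fixed template gain and transducer exponent.
#' @param d_primes,q_levels Difficulty structure.
#' @param bounds A [hier_bounds()].
#' @param rhat_warn Warn when the split statistic of any population mean
#'   exceeds this value (only meaningful with >= 2 chains).
#' @return An object of class `hier_fit`: `population_draws` (chain,
#'   iteration, group, parameter, mean, sd), `individual_draws`,
#'   `population_map` and `individual_map` MAP tables, `diagnostics`, and
#'   the fit configuration.
#' @examples
#' \donttest{
#' study <- simulate_study(seed = 11,
#'   case_spec = case_group_spec(n = 4), control_spec = control_group_spec(n = 4),
#'   design = design_spec(trials_per_level_per_structure = 10))
#' fit <- fit_hierarchical(study$trials,
#'   mcmc_config(chains = 2, burn_in = 200, thin = 1, draws_per_chain = 200),
#'   seed = 1)
#' fit$population_map
#' }
#' @export
fit_hierarchical <- function(trials, mcmc = mcmc_config(), seed = 1,
                             beta = 1.25, gamma = 2,
                             d_primes = c(1.089, 1.634),
                             q_levels = c(0.7071, 0.7937),
                             bounds = hier_bounds(), rhat_warn = 1.2) {
  stopifnot(inherits(mcmc, "mcmc_config"), inherits(bounds, "hier_bounds"))
  hd <- prep_hier_data(trials, d_primes, q_levels)
  participants <- hd$participants
  groups <- unique(participants$group)
  if (any(table(participants$group) < 2)) {
    stop("need at least two participants per group", call. = FALSE)
  }
  n_part <- nrow(participants)
  pnames <- bounds$params
  grp_idx <- lapply(groups, function(g) which(participants$group == g))
  names(grp_idx) <- groups

  # flat per-participant MLEs: shared across chains, jittered per chain
  mle <- do.call(rbind, lapply(seq_len(n_part), function(i) {
    tr <- trials[trials$participant_id == participants$participant_id[i], ]
    f <- fit_ptm_mle(tr, beta, gamma, d_primes, q_levels)
    c(f$n_add, f$n_mul, f$w_ext, f$eta)
  }))
  # keep initial states strictly inside the support
  mle[, 1] <- pmin(pmax(mle[, 1], 2e-4), 0.5)
  mle[, 2] <- pmin(pmax(mle[, 2], 0.01), 0.9 / max(d_primes))
  mle[, 3] <- pmin(pmax(mle[, 3], 0.05), 4)
  mle[, 4] <- pmin(pmax(mle[, 4], 0.3), 8)

  run_chain <- function(chain_seed) {
    withr::with_seed(chain_seed, {
      ind <- mle * matrix(exp(stats::rnorm(length(mle), 0, 0.05)),
                          nrow = n_part)
      ind[, 1] <- pmin(pmax(ind[, 1], 2e-4), 0.5)
      ind[, 2] <- pmin(pmax(ind[, 2], 0.005), 0.92 / max(d_primes))
      ind[, 3] <- pmin(pmax(ind[, 3], 0.05), 4)
      ind[, 4] <- pmin(pmax(ind[, 4], 0.3), 8)
      pop_mean <- matrix(NA_real_, length(groups), 4)
      pop_sd <- matrix(NA_real_, length(groups), 4)
      for (g in seq_along(groups)) {
        x <- ind[grp_idx[[g]], , drop = FALSE]
        pop_mean[g, ] <- pmin(pmax(colMeans(x), bounds$mean_lo * 1.001),
                              bounds$mean_hi * 0.999)
        pop_sd[g, ] <- pmin(pmax(apply(x, 2, stats::sd),
                                 0.05 * pop_mean[g, ] + 1e-6),
                            bounds$sd_hi * 0.9)
      }
      lik <- vapply(seq_len(n_part), function(i) {
        part_loglik(hd$parts[[i]], ind[i, ], beta, gamma, d_primes,
                    hd$noise_levels)
      }, numeric(1))
      if (any(!is.finite(lik))) {
        stop("initialization outside the likelihood support", call. = FALSE)
      }
      ind_prior <- function(i) {
        g <- match(participants$group[i], groups)
        sum(ltrunc_norm(ind[i, ], pop_mean[g, ], pop_sd[g, ]))
      }
      step_ind <- rep(0.12, n_part)
      step_pop <- matrix(0.1, length(groups), 4)
      acc_ind <- integer(n_part)
      acc_pop <- matrix(0L, length(groups), 4)
      window <- 25L
      total <- mcmc$burn_in + mcmc$thin * mcmc$draws_per_chain
      keep_pop <- array(NA_real_, c(mcmc$draws_per_chain, length(groups), 8))
      keep_ind <- array(NA_real_, c(mcmc$draws_per_chain, n_part, 4))
      kept <- 0L
      for (it in seq_len(total)) {
        # individual blocks: multiplicative random walk (log-scale RW with
        # Jacobian correction)
        for (i in seq_len(n_part)) {
          prop <- ind[i, ] * exp(stats::rnorm(4, 0, step_ind[i]))
          g <- match(participants$group[i], groups)
          lp_new <- part_loglik(hd$parts[[i]], prop, beta, gamma, d_primes,
                                hd$noise_levels)
          if (is.finite(lp_new)) {
            num <- lp_new + sum(ltrunc_norm(prop, pop_mean[g, ],
                                            pop_sd[g, ])) +
              sum(log(prop))
            den <- lik[i] + ind_prior(i) + sum(log(ind[i, ]))
            if (log(stats::runif(1)) < num - den) {
              ind[i, ] <- prop
              lik[i] <- lp_new
              acc_ind[i] <- acc_ind[i] + 1L
            }
          }
        }
        # population blocks: (mean, sd) per group x parameter
        for (g in seq_along(groups)) {
          xg <- ind[grp_idx[[g]], , drop = FALSE]
          for (j in 1:4) {
            m_new <- pop_mean[g, j] + stats::rnorm(1, 0, step_pop[g, j] *
                                                     max(pop_sd[g, j], 1e-8))
            s_new <- pop_sd[g, j] * exp(stats::rnorm(1, 0, step_pop[g, j]))
            if (m_new >= bounds$mean_lo[j] && m_new <= bounds$mean_hi[j] &&
                s_new > bounds$sd_lo[j] && s_new <= bounds$sd_hi[j]) {
              num <- sum(ltrunc_norm(xg[, j], m_new, s_new)) + log(s_new)
              den <- sum(ltrunc_norm(xg[, j], pop_mean[g, j],
                                     pop_sd[g, j])) + log(pop_sd[g, j])
              if (log(stats::runif(1)) < num - den) {
                pop_mean[g, j] <- m_new
                pop_sd[g, j] <- s_new
                acc_pop[g, j] <- acc_pop[g, j] + 1L
              }
            }
          }
        }
        if (it <= mcmc$adapt && it %% window == 0L) {
          step_ind <- step_ind * exp(acc_ind / window - 0.3)
          step_ind <- pmin(pmax(step_ind, 0.005), 1)
          step_pop <- step_pop * exp(acc_pop / window - 0.3)
          step_pop <- pmin(pmax(step_pop, 0.01), 2)
          acc_ind[] <- 0L
          acc_pop[] <- 0L
        }
        if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L) {
          kept <- kept + 1L
          keep_pop[kept, , ] <- cbind(pop_mean, pop_sd)
          keep_ind[kept, , ] <- ind
        }
      }
      list(pop = keep_pop, ind = keep_ind)
    })
  }

  chains <- lapply(seq_len(mcmc$chains), function(ch) {
    run_chain(derive_seed(seed, paste0("hier_chain", ch)))
  })

  nd <- mcmc$draws_per_chain
  population_draws <- purrr::map_dfr(seq_along(chains), function(ch) {
    purrr::map_dfr(seq_along(groups), function(g) {
      purrr::map_dfr(1:4, function(j) {
        tibble::tibble(chain = ch, iteration = seq_len(nd),
                       group = groups[g], parameter = pnames[j],
                       mean = chains[[ch]]$pop[, g, j],
                       sd = chains[[ch]]$pop[, g, j + 4])
      })
    })
  })
  individual_draws <- purrr::map_dfr(seq_along(chains), function(ch) {
    purrr::map_dfr(seq_len(n_part), function(i) {
      tibble::tibble(chain = ch, iteration = seq_len(nd),
                     participant_id = participants$participant_id[i],
                     group = participants$group[i],
                     n_add = chains[[ch]]$ind[, i, 1],
                     n_mul = chains[[ch]]$ind[, i, 2],
                     w_ext = chains[[ch]]$ind[, i, 3],
                     eta = chains[[ch]]$ind[, i, 4])
    })
  })
  population_map <- population_draws |>
    dplyr::group_by(.data$group, .data$parameter) |>
    dplyr::summarise(map_mean = map_from_draws(.data$mean),
                     map_sd = map_from_draws(.data$sd), .groups = "drop")
  individual_map <- individual_draws |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(dplyr::across(c("n_add", "n_mul", "w_ext", "eta"),
                                   map_from_draws), .groups = "drop")
  mats <- lapply(chains, function(cc) {
    m <- do.call(cbind, lapply(seq_along(groups), function(g) cc$pop[, g, 1:4]))
    colnames(m) <- paste(rep(groups, each = 4), pnames, sep = ".")
    m
  })
  diag <- chain_diagnostics(mats)
  names(diag$rhat) <- names(diag$lag1_autocorrelation) <- colnames(mats[[1]])
  if (mcmc$chains > 1 && any(diag$rhat > rhat_warn, na.rm = TRUE)) {
    warning("hierarchical fit may not have converged: max split statistic ",
            sprintf("%.2f", max(diag$rhat, na.rm = TRUE)), " exceeds ",
            rhat_warn, call. = FALSE)
  }
  structure(
    list(population_draws = population_draws,
         individual_draws = individual_draws,
         population_map = population_map, individual_map = individual_map,
         diagnostics = diag, groups = groups, mcmc = mcmc,
         beta = beta, gamma = gamma, d_primes = d_primes,
         q_levels = q_levels, bounds = bounds, seed = seed),
    class = "hier_fit")
}

#' Credible-interval group comparison on population posteriors
#'
#' Computes the case-minus-control difference on paired population-mean
#' draws for one parameter and summarizes it: MAP of the difference, 95% and
#' 90% equal-tailed credible intervals, and the fraction of posterior draws
#' above zero (draws exactly at zero count half, so identical groups report
#' 0.5). The difference is called significant when the 95% interval excludes
#' zero and marginal when the 90% interval does.
#'
#' @param fit A `hier_fit`, or a population-draws tibble of the same shape.
#' @param parameter One of `"n_add"`, `"n_mul"`, `"w_ext"`, `"eta"`.
#' @param case,control Group labels; default to the first and second group
#'   of the fit.
#' @return A one-row tibble: `parameter`, `delta_map`, `ci95_lo`, `ci95_hi`,
#'   `ci90_lo`, `ci90_hi`, `fraction_above_zero`, `significant`, `marginal`.
#' @export
group_difference <- function(fit, parameter, case = NULL, control = NULL) {
  draws <- if (inherits(fit, "hier_fit")) fit$population_draws else fit
  if (!parameter %in% unique(draws$parameter)) {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  groups <- unique(draws$group)
  if (is.null(case)) case <- groups[1]
  if (is.null(control)) control <- groups[2]
  if (!all(c(case, control) %in% groups)) {
    stop("both groups must be present in the draws", call. = FALSE)
  }
  d <- draws[draws$parameter == parameter, ]
  wide <- tidyr::pivot_wider(d[, c("chain", "iteration", "group", "mean")],
                             names_from = "group", values_from = "mean")
  delta <- wide[[case]] - wide[[control]]
  ci95 <- stats::quantile(delta, c(0.025, 0.975), names = FALSE)
  ci90 <- stats::quantile(delta, c(0.05, 0.95), names = FALSE)
  frac <- (sum(delta > 0) + 0.5 * sum(delta == 0)) / length(delta)
  tibble::tibble(
    parameter = parameter, delta_map = map_from_draws(delta),
    ci95_lo = ci95[1], ci95_hi = ci95[2],
    ci90_lo = ci90[1], ci90_hi = ci90[2],
    fraction_above_zero = frac,
    significant = ci95[1] > 0 | ci95[2] < 0,
    marginal = ci90[1] > 0 | ci90[2] < 0)
}
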