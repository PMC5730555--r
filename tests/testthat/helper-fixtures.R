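# Shared fixtures and independent oracles for the test suite.

# Reference observer: control-group population means.
td_params <- function() {
  ptm_params(n_add = 0.0027, n_mul = 0.26, w_ext = 0.69,
             beta = 1.25, gamma = 2)
}

study_noise_levels <- function() {
  c(0, 0.003, 0.0061, 0.0124, 0.0251, 0.051, 0.103, 0.21)
}

# Step-by-step evaluation of the group-coefficient threshold equation,
# written independently of the package internals (scalar arithmetic, no
# shared helpers).
oracle_threshold <- function(n_add, n_mul, w_ext, beta, gamma, d_prime,
                             n_ext, a_m = 1, a_a = 1, a_e = 1) {
  m <- a_m * n_mul
  numerator <- (1 + m^2) * (a_e * w_ext * n_ext)^(2 * gamma) +
    (a_a * n_add)^2
  denominator <- 1 / d_prime^2 - m^2
  (1 / beta) * (numerator / denominator)^(1 / (2 * gamma))
}

# Noiseless TvN table generated directly from the threshold equation.
oracle_tvn <- function(n_add = 0.0027, n_mul = 0.26, beta = 1.25,
                       gamma = 2, a_m = 1, a_a = 1, a_e = 1,
                       groups = c("case", "control"),
                       qs = c(0.7071, 0.7937),
                       noise = study_noise_levels()) {
  tvn <- tidyr::expand_grid(group = groups, q = qs,
                            noise_index = seq_along(noise))
  tvn$n_ext <- noise[tvn$noise_index]
  tvn$mean_log_threshold <- vapply(seq_len(nrow(tvn)), function(i) {
    case <- tvn$group[i] == "case"
    log(100 * oracle_threshold(
      n_add, n_mul, 1, beta, gamma,
      d_prime = 2 * qnorm(tvn$q[i]), n_ext = tvn$n_ext[i],
      a_m = if (case) a_m else 1, a_a = if (case) a_a else 1,
      a_e = if (case) a_e else 1))
  }, numeric(1))
  tvn$sem_log_threshold <- 0
  tvn$n <- 1L
  class(tvn) <- c("tvn_table", class(tvn))
  tvn
}

# Small simulated session cached per test file run.
quick_mcmc <- function(chains = 2, burn_in = 400, thin = 1,
                       draws_per_chain = 400) {
  mcmc_config(chains = chains, burn_in = burn_in, thin = thin,
              draws_per_chain = draws_per_chain)
}
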