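small_study <- function(seed = 77, n_per_group = 4, trials = 10) {
  simulate_study(
    seed = seed,
    case_spec = case_group_spec(n = n_per_group),
    control_spec = control_group_spec(n = n_per_group),
    design = design_spec(trials_per_level_per_structure = trials))
}

test_that("the joint log posterior equals an independent term-by-term sum", {
  study <- simulate_study(
    seed = 3,
    case_spec = case_group_spec(n = 2),
    control_spec = control_group_spec(n = 2),
    design = design_spec(noise_levels = c(0, 0.051, 0.21),
                         trials_per_level_per_structure = 4))
  # collapse to a 3-participant single-group toy
  trials <- study$trials
  trials$group <- "g"
  ids <- utils::head(unique(trials$participant_id), 3)
  trials <- trials[trials$participant_id %in% ids, ]
  state <- list(
    individual = tibble::tibble(
      participant_id = ids, group = "g",
      n_add = c(0.003, 0.004, 0.0025), n_mul = c(0.2, 0.1, 0.3),
      w_ext = c(0.8, 0.9, 0.7), eta = c(2, 2.5, 1.8)),
    population = tibble::tibble(
      group = "g", parameter = c("n_add", "n_mul", "w_ext", "eta"),
      mean = c(0.003, 0.2, 0.8, 2), sd = c(0.001, 0.1, 0.1, 0.5)))

  # oracle: direct summation with scalar arithmetic, coded independently
  oracle <- 0
  for (i in seq_along(ids)) {
    ind <- state$individual[i, ]
    tr <- trials[trials$participant_id == ids[i], ]
    for (k in seq_len(nrow(tr))) {
      dp <- c(1.089, 1.634)[tr$structure[k]]
      q <- c(0.7071, 0.7937)[tr$structure[k]]
      ct <- 100 * oracle_threshold(ind$n_add, ind$n_mul, ind$w_ext, 1.25, 2,
                                   dp, tr$n_ext[k])
      theta <- 1 - 0.5 * ((1 - q) / 0.5) ^
        ((log(100 * tr$contrast[k]) / log(ct))^ind$eta)
      oracle <- oracle + log(if (tr$correct[k] == 1) theta else 1 - theta)
    }
    for (pn in c("n_add", "n_mul", "w_ext", "eta")) {
      pop <- state$population[state$population$parameter == pn, ]
      oracle <- oracle + dnorm(ind[[pn]], pop$mean, pop$sd, log = TRUE) -
        log(1 - pnorm(0, pop$mean, pop$sd))
    }
  }
  expect_equal(hier_log_posterior(state, trials), oracle,
               tolerance = 1e-10)
})

test_that("single-trial likelihood at threshold is log(q)", {
  ind <- tibble::tibble(participant_id = "p", group = "g",
                        n_add = 0.004, n_mul = 0.1, w_ext = 0.8, eta = 2)
  ct <- oracle_threshold(0.004, 0.1, 0.8, 1.25, 2, 1.089, 0.051)
  trial <- tibble::tibble(participant_id = "p", group = "g",
                          structure = 1L, noise_index = 1L, n_ext = 0.051,
                          contrast = ct, correct = 1L)
  pop <- tibble::tibble(group = "g",
                        parameter = c("n_add", "n_mul", "w_ext", "eta"),
                        mean = c(0.004, 0.1, 0.8, 2),
                        sd = c(0.001, 0.05, 0.1, 0.5))
  state <- list(individual = ind, population = pop)
  lp <- hier_log_posterior(state, trial)
  prior <- sum(dnorm(c(0.004, 0.1, 0.8, 2), pop$mean, pop$sd, log = TRUE) -
                 pnorm(0, pop$mean, pop$sd, lower.tail = FALSE,
                       log.p = TRUE))
  expect_equal(lp - prior, log(0.7071), tolerance = 1e-9)
})

test_that("degenerate population SDs and off-support states give -Inf", {
  study <- small_study(seed = 5, n_per_group = 2, trials = 2)
  trials <- study$trials
  truth <- study$truth
  state <- list(
    individual = truth[, c("participant_id", "group", "n_add", "n_mul",
                           "w_ext", "eta")],
    population = tidyr::expand_grid(
      group = c("case", "control"),
      parameter = c("n_add", "n_mul", "w_ext", "eta")) |>
      dplyr::mutate(mean = rep(c(0.004, 0.15, 0.8, 2), 2),
                    sd = rep(c(0.002, 0.1, 0.2, 0.5), 2)))
  base <- hier_log_posterior(state, trials)
  expect_true(is.finite(base))
  # shrink one sd toward zero with individuals away from the mean: the
  # density collapses (and is exactly -Inf at sd = 0, outside the support)
  st2 <- state
  st2$population$sd[st2$population$parameter == "n_add"] <- 1e-12
  expect_lt(hier_log_posterior(st2, trials), -1e6)
  st2$population$sd[st2$population$parameter == "n_add"] <- 0
  expect_equal(hier_log_posterior(st2, trials), -Inf)
  # negative individual parameter
  st3 <- state
  st3$individual$n_add[1] <- -0.001
  expect_equal(hier_log_posterior(st3, trials), -Inf)
  # population mean outside its uniform hyperprior
  st4 <- state
  st4$population$mean[st4$population$parameter == "w_ext"] <- 99
  expect_equal(hier_log_posterior(st4, trials), -Inf)
})

test_that("the sampler is deterministic and respects the support", {
  study <- small_study(seed = 21, n_per_group = 3, trials = 6)
  cfg <- mcmc_config(chains = 2, burn_in = 150, thin = 1,
                     draws_per_chain = 120)
  f1 <- suppressWarnings(fit_hierarchical(study$trials, cfg, seed = 4))
  f2 <- suppressWarnings(fit_hierarchical(study$trials, cfg, seed = 4))
  expect_identical(f1$population_draws, f2$population_draws)
  expect_identical(f1$individual_draws, f2$individual_draws)
  expect_equal(nrow(f1$population_draws), 2 * 120 * 2 * 4)
  # nonnegativity of every retained draw
  expect_true(all(f1$individual_draws$n_add >= 0))
  expect_true(all(f1$individual_draws$n_mul >= 0))
  expect_true(all(f1$individual_draws$w_ext >= 0))
  expect_true(all(f1$population_draws$sd > 0))
})

test_that("group differences summarize paired population draws correctly", {
  # synthetic draws, no sampler involved
  withr::with_seed(6, {
    nd <- 20000
    draws <- dplyr::bind_rows(
      tibble::tibble(chain = 1L, iteration = seq_len(nd), group = "case",
                     parameter = "n_add", mean = rnorm(nd, 0.2, 1),
                     sd = 1),
      tibble::tibble(chain = 1L, iteration = seq_len(nd), group = "control",
                     parameter = "n_add", mean = rnorm(nd, 0, 1), sd = 1))
  })
  gd <- group_difference(draws, "n_add", case = "case",
                         control = "control")
  expect_equal(gd$fraction_above_zero, pnorm(0.2 / sqrt(2)),
               tolerance = 0.02)
  # identical draws: delta exactly zero, fraction reported as 1/2
  same <- draws
  same$mean[same$group == "case"] <- same$mean[same$group == "control"]
  gd0 <- group_difference(same, "n_add", case = "case",
                          control = "control")
  expect_equal(gd0$delta_map, 0)
  expect_equal(gd0$fraction_above_zero, 0.5)
  expect_false(gd0$significant)
  # constant shift: degenerate interval at +1
  shift <- draws
  shift$mean[shift$group == "case"] <-
    shift$mean[shift$group == "control"] + 1
  gd1 <- group_difference(shift, "n_add", case = "case",
                          control = "control")
  expect_equal(gd1$ci95_lo, 1)
  expect_equal(gd1$ci95_hi, 1)
  expect_equal(gd1$fraction_above_zero, 1)
  expect_true(gd1$significant)
  expect_error(group_difference(draws, "nope"), "unknown parameter")
})

test_that("the histogram-mode estimator finds known modes", {
  expect_equal(map_from_draws(rep(3.7, 50)), 3.7)
  withr::with_seed(12, {
    expect_equal(map_from_draws(rnorm(50000, 5, 1)), 5, tolerance = 0.1)
  })
  # bimodal with unequal mass: taller mode wins
  withr::with_seed(13, {
    draws <- c(rnorm(30000, -2, 0.3), rnorm(10000, 2, 0.3))
    expect_equal(map_from_draws(draws), -2, tolerance = 0.2)
  })
})

test_that("hierarchical estimates shrink individual noise versus flat MLE", {
  # shrinkage: hierarchical individual estimates beat independent MLEs
  # in aggregate against the known truth
  study <- simulate_study(
    seed = 31,
    case_spec = case_group_spec(n = 6),
    control_spec = control_group_spec(n = 6),
    design = design_spec(trials_per_level_per_structure = 15))
  cfg <- mcmc_config(chains = 1, burn_in = 600, thin = 1,
                     draws_per_chain = 500)
  hier <- suppressWarnings(fit_hierarchical(study$trials, cfg, seed = 2))
  mle <- purrr::map_dfr(unique(study$trials$participant_id), function(id) {
    fit_ptm_mle(study$trials[study$trials$participant_id == id, ])
  })
  truth <- study$truth
  err <- function(est) {
    m <- dplyr::inner_join(est, truth, by = "participant_id",
                           suffix = c("", "_true"))
    mean((log(pmax(m$n_add, 1e-5)) - log(m$n_add_true))^2) +
      mean((log(pmax(m$w_ext, 1e-3)) - log(m$w_ext_true))^2)
  }
  expect_lt(err(hier$individual_map), err(mle))
})
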