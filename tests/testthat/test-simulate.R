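test_that("population sampling respects the spec and is deterministic", {
  spec <- control_group_spec(n = 6)
  a <- sample_population(spec, seed = 11)
  b <- sample_population(spec, seed = 11)
  expect_identical(a, b)
  expect_equal(nrow(a), 6)
  expect_true(all(a$n_add >= 0 & a$n_mul >= 0 & a$w_ext >= 0 & a$eta >= 0))

  # zero SDs collapse every participant onto the population mean
  degen <- group_spec("g", 4, 0.003, 0, 0.2, 0, 0.8, 0, eta_sd = 0)
  d <- sample_population(degen, seed = 1)
  expect_true(all(d$n_add == 0.003 & d$n_mul == 0.2 & d$w_ext == 0.8))
})

test_that("large samples reproduce the population means", {
  spec <- group_spec("g", 10000, 0.0027, 0.0004, 0.26, 0.05, 0.69, 0.08)
  s <- sample_population(spec, seed = 2)
  # truncation at zero is negligible at these means/sds
  expect_equal(mean(s$n_add), 0.0027, tolerance = 2 * 0.0004 / sqrt(10000) /
                 0.0027)
  expect_equal(mean(s$w_ext), 0.69, tolerance = 2 * 0.08 / sqrt(10000) /
                 0.69)
  expect_equal(mean(s$n_mul), 0.26, tolerance = 0.01)
})

test_that("a session has the designed trial layout", {
  p <- td_params()
  tr <- simulate_session(p, 2, design_spec(), seed = 7)
  expect_equal(nrow(tr), 480)
  counts <- dplyr::count(tr, noise_index)
  expect_true(all(counts$n == 60)) # 60 per level after pooling structures
  per_cell <- dplyr::count(tr, structure, noise_index)
  expect_true(all(per_cell$n == 30))
  expect_true(all(tr$contrast > 0))
  expect_identical(simulate_session(p, 2, design_spec(), seed = 7), tr)
})

test_that("responses track the PTM accuracy surface", {
  p <- td_params()
  design <- design_spec()
  # saturated contrasts: accuracy approaches the multiplicative-noise ceiling
  tr <- simulate_session(p, 2, design, seed = 3)
  high <- dplyr::group_by(tr, structure, noise_index) |>
    dplyr::slice_max(contrast, n = 5) |>
    dplyr::ungroup()
  ceiling_pc <- dprime_to_pc(1 / 0.26)
  expect_gt(mean(high$correct), ceiling_pc - 0.08)

  # contrasts pinned at threshold: accuracy near the difficulty target
  big <- design_spec(trials_per_level_per_structure = 200)
  at_threshold <- purrr::map_dfr(1:2, function(s) {
    dp <- big$d_primes[s]
    purrr::map_dfr(seq_along(big$noise_levels), function(j) {
      ct <- ptm_threshold(p, d_prime = dp, n_ext = big$noise_levels[j])
      tibble::tibble(structure = s, contrast = rep(ct, 200),
                     n_ext = big$noise_levels[j])
    })
  })
  withr::with_seed(13, {
    at_threshold$correct <- as.integer(
      runif(nrow(at_threshold)) <
        dprime_to_pc(ptm_dprime(p, at_threshold$contrast,
                                at_threshold$n_ext)))
  })
  acc <- dplyr::group_by(at_threshold, structure) |>
    dplyr::summarise(pc = mean(correct), n = dplyr::n())
  targets <- c(0.7071, 0.7937)
  for (s in 1:2) {
    se <- sqrt(targets[s] * (1 - targets[s]) / acc$n[s])
    expect_lt(abs(acc$pc[s] - targets[s]), 3 * se)
  }
})

test_that("empirical accuracy matches the analytic curve on a dense grid", {
  p <- ptm_params(n_add = 0.004, n_mul = 0.2, w_ext = 0.8)
  ne <- 0.051
  contrasts <- exp(seq(log(0.02), log(0.3), length.out = 5))
  withr::with_seed(21, {
    for (x in contrasts) {
      pc <- dprime_to_pc(ptm_dprime(p, x, ne))
      hits <- sum(runif(4000) < pc)
      se <- sqrt(pc * (1 - pc) / 4000)
      expect_lt(abs(hits / 4000 - pc), 3.5 * se)
    }
  })
})

test_that("binned accuracy is broadly nondecreasing in contrast", {
  p <- td_params()
  tr <- simulate_session(p, 2, design_spec(), seed = 19)
  binned <- tr |>
    dplyr::mutate(bin = dplyr::ntile(log(contrast), 6)) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(pc = mean(correct), n = dplyr::n())
  # allow binomial wiggle: each step down must be within sampling error
  steps <- diff(binned$pc)
  se <- sqrt(0.25 / min(binned$n))
  expect_true(all(steps > -3 * se))
})

test_that("staircase schedules concentrate contrasts near threshold", {
  p <- td_params()
  d <- design_spec(contrast_schedule = "staircase-2down1up")
  tr <- simulate_session(p, 2, d, seed = 5)
  expect_equal(nrow(tr), 480)
  # after convergence the 2-down-1-up staircase straddles ~70.7% accuracy
  acc <- mean(tr$correct)
  expect_gt(acc, 0.55)
  expect_lt(acc, 0.9)
})

test_that("a full study has the right schema and severity behavior", {
  study <- simulate_study(
    seed = 33,
    case_spec = case_group_spec(n = 6),
    control_spec = control_group_spec(n = 5),
    design = design_spec(trials_per_level_per_structure = 5))
  expect_s3_class(study$trials, "tbl_df")
  expect_equal(dplyr::n_distinct(study$trials$participant_id), 11)
  # severity only for the case group, integers in 4..9
  expect_equal(nrow(study$severity), 6)
  expect_true(all(study$severity$severity %in% 4:9))
  ctrl <- study$truth[study$truth$group == "control", ]
  expect_true(all(is.na(ctrl$severity)))
  # truth table retains all sampled parameters
  expect_true(all(c("n_add", "n_mul", "w_ext", "eta") %in%
                    names(study$truth)))
  # determinism
  study2 <- simulate_study(
    seed = 33,
    case_spec = case_group_spec(n = 6),
    control_spec = control_group_spec(n = 5),
    design = design_spec(trials_per_level_per_structure = 5))
  expect_identical(study$trials, study2$trials)
})

test_that("a noiseless severity link is a monotone function of n_add", {
  study <- simulate_study(
    seed = 14,
    case_spec = case_group_spec(n = 8),
    control_spec = control_group_spec(n = 5),
    link = severity_link(residual_sd = 0),
    design = design_spec(trials_per_level_per_structure = 2))
  case <- study$truth[study$truth$group == "case", ]
  ord <- order(case$n_add)
  expect_true(all(diff(case$severity[ord]) >= 0))
})

test_that("injected group coefficients scale the case population", {
  study <- simulate_study(
    seed = 5,
    case_spec = group_spec("case", 30, 0.003, 0, 0.2, 0, 0.8, 0,
                           eta_sd = 0),
    control_spec = control_group_spec(n = 5),
    design = design_spec(trials_per_level_per_structure = 2),
    case_coeffs = group_coefficients(a_a = 1.7, a_e = 1.13))
  case <- study$truth[study$truth$group == "case", ]
  expect_equal(unique(case$n_add), 0.003 * 1.7)
  expect_equal(unique(case$w_ext), 0.8 * 1.13)
})
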