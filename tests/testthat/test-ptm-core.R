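test_that("threshold equation reduces correctly in limiting cases", {
  # pure additive noise, linear transducer: c_tau = n_add * d'
  p <- ptm_params(n_add = 0.01, n_mul = 0, w_ext = 1, beta = 1, gamma = 1)
  expect_equal(ptm_threshold(p, d_prime = 1, n_ext = 0), 0.01)
  # pure external noise: c_tau = d' * n_ext
  p2 <- ptm_params(n_add = 0, n_mul = 0, w_ext = 1, beta = 1, gamma = 1)
  expect_equal(ptm_threshold(p2, d_prime = 2, n_ext = 0.1), 0.2)
})

test_that("threshold matches an independent step-by-step evaluation", {
  p <- td_params()
  for (ne in c(0, 0.0124, 0.051, 0.21)) {
    for (dp in c(1.089, 1.634)) {
      expect_equal(
        ptm_threshold(p, d_prime = dp, n_ext = ne),
        oracle_threshold(0.0027, 0.26, 0.69, 1.25, 2, dp, ne),
        tolerance = 1e-12)
    }
  }
  # with group coefficients folded in
  co <- group_coefficients(a_m = 1.1, a_a = 1.7, a_e = 1.13)
  expect_equal(
    ptm_threshold(p, co, d_prime = 1.089, n_ext = 0.051),
    oracle_threshold(0.0027, 0.26, 0.69, 1.25, 2, 1.089, 0.051,
                     a_m = 1.1, a_a = 1.7, a_e = 1.13),
    tolerance = 1e-12)
})

test_that("threshold is strictly increasing in external noise and d-prime", {
  p <- td_params()
  th <- ptm_threshold(p, d_prime = 1.089, n_ext = study_noise_levels())
  expect_true(all(diff(th) > 0))
  th_hard <- ptm_threshold(p, d_prime = 1.634, n_ext = study_noise_levels())
  expect_true(all(th_hard > th))
})

test_that("infeasible sensitivity raises an error", {
  p <- ptm_params(n_add = 0.003, n_mul = 0.5, w_ext = 1)
  expect_error(ptm_threshold(p, d_prime = 2.5, n_ext = 0),
               "infeasible")
  co <- group_coefficients(a_m = 3)
  expect_error(ptm_threshold(p, co, d_prime = 1, n_ext = 0), "infeasible")
})

test_that("d-prime inverts the threshold equation over random tuples", {
  withr::with_seed(101, {
    for (i in 1:200) {
      p <- ptm_params(n_add = runif(1, 1e-4, 0.05),
                      n_mul = runif(1, 0, 0.4),
                      w_ext = runif(1, 0.3, 2),
                      beta = runif(1, 0.5, 2),
                      gamma = runif(1, 0.8, 3))
      dp <- runif(1, 0.3, 2)
      ne <- runif(1, 0, 0.25)
      ct <- ptm_threshold(p, d_prime = dp, n_ext = ne)
      expect_lt(abs(ptm_dprime(p, ct, ne) - dp), 1e-8)
    }
  })
})

test_that("d-prime saturates at 1/n_mul for large contrast", {
  p <- ptm_params(n_add = 0.003, n_mul = 0.26, w_ext = 0.69)
  expect_equal(ptm_dprime(p, 50, 0.05), 1 / 0.26, tolerance = 1e-4)
  expect_equal(ptm_dprime(p, 0, 0.05), 0)
  # monotone nondecreasing in contrast
  d <- ptm_dprime(p, seq(0, 2, length.out = 100), 0.05)
  expect_true(all(diff(d) >= 0))
})

test_that("multiplicative noise carries the between-group ratio signature", {
  # The difficulty-level threshold ratio is constant across noise levels
  # (the external/additive numerator is shared by both difficulty levels);
  # with n_mul = 0 it is the same for every observer, while elevated
  # multiplicative noise (a_m > 1) shifts the ratio between groups — the
  # diagnostic signature separating a_m from a_a/a_e effects.
  ne <- study_noise_levels()
  p0 <- ptm_params(n_add = 0.003, n_mul = 0, w_ext = 0.8)
  ratio0 <- ptm_threshold(p0, d_prime = 1.634, n_ext = ne) /
    ptm_threshold(p0, d_prime = 1.089, n_ext = ne)
  expect_lt(diff(range(ratio0)), 1e-12)
  # with zero multiplicative noise the ratio is (d2/d1)^(1/gamma) for any
  # additive/external parameters: no group separation
  p0b <- ptm_params(n_add = 0.01, n_mul = 0, w_ext = 1.6)
  ratio0b <- ptm_threshold(p0b, d_prime = 1.634, n_ext = ne) /
    ptm_threshold(p0b, d_prime = 1.089, n_ext = ne)
  expect_equal(unique(round(ratio0b, 10)), unique(round(ratio0, 10)))
  expect_equal(ratio0[1], (1.634 / 1.089)^(1 / 2), tolerance = 1e-10)
  # elevated multiplicative noise: ratio still flat across noise levels,
  # but different between a group with a_m > 1 and the reference group
  p1 <- ptm_params(n_add = 0.003, n_mul = 0.3, w_ext = 0.8)
  co <- group_coefficients(a_m = 1.6)
  ratio_ref <- ptm_threshold(p1, d_prime = 1.634, n_ext = ne) /
    ptm_threshold(p1, d_prime = 1.089, n_ext = ne)
  ratio_case <- ptm_threshold(p1, co, d_prime = 1.634, n_ext = ne) /
    ptm_threshold(p1, co, d_prime = 1.089, n_ext = ne)
  expect_lt(diff(range(ratio_case)), 1e-12)
  expect_gt(min(abs(ratio_case - ratio_ref)), 0.01)
})

test_that("log-log TvN slope approaches 1 at high external noise", {
  withr::with_seed(7, {
    for (i in 1:20) {
      p <- ptm_params(n_add = runif(1, 1e-3, 0.02),
                      n_mul = runif(1, 0, 0.4),
                      w_ext = runif(1, 0.3, 1.5),
                      beta = runif(1, 0.7, 2), gamma = runif(1, 1, 3))
      ne <- c(10, 11)
      lt <- log(ptm_threshold(p, d_prime = 1.2, n_ext = ne))
      slope <- diff(lt) / diff(log(ne))
      expect_equal(slope, 1, tolerance = 1e-3)
    }
  })
})

test_that("group coefficients are equivalent to rescaled parameters", {
  p <- ptm_params(n_add = 0.004, n_mul = 0.2, w_ext = 0.8)
  co <- group_coefficients(a_a = 1.5, a_e = 1.2)
  p_scaled <- ptm_params(n_add = 1.5 * 0.004, n_mul = 0.2,
                         w_ext = 1.2 * 0.8)
  for (ne in c(0, 0.05, 0.2)) {
    expect_equal(ptm_threshold(p, co, d_prime = 1.3, n_ext = ne),
                 ptm_threshold(p_scaled, d_prime = 1.3, n_ext = ne),
                 tolerance = 1e-12)
  }
})

test_that("constructors validate their invariants", {
  expect_error(ptm_params(n_add = -0.01), "non-negative")
  expect_error(ptm_params(n_add = 0.01, beta = 0), "positive")
  expect_error(group_coefficients(a_a = 0), "positive")
  expect_error(ptm_threshold(td_params(), d_prime = 1.089, n_ext = -1),
               "n_ext")
})
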