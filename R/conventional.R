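#' Threshold-versus-noise table of group means
#'
#' Averages the per-participant log thresholds from
#' [fit_weibull_thresholds()] into the group-level TvN table used by the
#' conventional PTM fit: mean and SEM of natural-log percent thresholds,
#' indexed by group, difficulty level `q`, and external-noise level (2 groups
#' x 2 difficulties x 8 levels = 32 cells under the default design).
#'
#' @param thresholds Output of [fit_weibull_thresholds()].
#' @return A tibble of class `tvn_table` with columns `group`, `q`,
#'   `noise_index`, `n_ext`, `mean_log_threshold`, `sem_log_threshold`, `n`.
#' @export
tvn_table <- function(thresholds) {
  out <- thresholds |>
    dplyr::group_by(.data$group, .data$q, .data$noise_index, .data$n_ext) |>
    dplyr::summarise(
      mean_log_threshold = mean(log(.data$threshold)),
      sem_log_threshold = stats::sd(log(.data$threshold)) /
        sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop")
  class(out) <- c("tvn_table", class(out))
  out
}

#' The eight candidate group-difference models
#'
#' Every subset of the three group coefficients (multiplicative `a_m`,
#' additive `a_a`, external `a_e`) may be freed for the case group, giving
#' 2^3 = 8 candidate models, from the null (4 free parameters: shared
#' `n_mul`, `n_add`, `beta`, `gamma`) to the full model (7).
#'
#' @return A tibble with columns `model` (label), `a_m`, `a_a`, `a_e`
#'   (logical: coefficient free?) and `k` (free-parameter count).
#' @export
candidate_models <- function() {
  grid <- tidyr::expand_grid(a_m = c(FALSE, TRUE), a_a = c(FALSE, TRUE),
                             a_e = c(FALSE, TRUE))
  grid$k <- 4L + rowSums(grid)
  grid$model <- vapply(seq_len(nrow(grid)), function(i) {
    free <- c("a_m", "a_a", "a_e")[unlist(grid[i, c("a_m", "a_a", "a_e")])]
    if (length(free) == 0) "null" else paste(free, collapse = "+")
  }, character(1))
  dplyr::relocate(grid, "model")
}

#' Variance explained on log thresholds
#'
#' `1 - SS_res / SS_tot` with sums pooled over every cell of the TvN table
#' (all groups, difficulty levels, and noise levels).
#'
#' @param predicted,observed Equal-length numeric vectors of log thresholds
#'   (length >= 2).
#' @return Proportion of variance explained.
#' @export
r_squared <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observations have zero variance", call. = FALSE)
  1 - sum((predicted - observed)^2) / ss_tot
}

# Predicted log percent thresholds for all TvN cells under one parameter
# vector, vectorized over cells (this sits inside the optimizer's inner
# loop). `free` names the case-group coefficients being estimated.
predict_tvn_log <- function(tvn, est, free, ref_group,
                            dp = pc_to_dprime(tvn$q),
                            is_case = tvn$group != ref_group) {
  co <- function(name) {
    ifelse(is_case & name %in% free, est[[name]] %||% 1, 1)
  }
  m <- co("a_m") * est[["n_mul"]]
  denom <- 1 / dp^2 - m^2
  if (any(denom <= 0)) return(rep(NaN, nrow(tvn)))
  g2 <- 2 * est[["gamma"]]
  e <- co("a_e") * tvn$n_ext
  num <- (1 + m^2) * e^g2 + (co("a_a") * est[["n_add"]])^2
  log(100 / est[["beta"]]) + log(num / denom) / g2
}

#' Fit one candidate group-coefficient PTM to a TvN table
#'
#' Least-squares fit of the group-coefficient PTM in log-threshold space:
#' shared parameters (`n_mul`, `n_add`, `beta`, `gamma`) for both groups,
#' reference-group coefficients fixed at 1, and the case-group coefficients
#' named in `free` estimated. The 7-parameter surface is multimodal, so the
#' optimizer is restarted from `n_starts` random points and the best
#' solution kept.
#'
#' @param tvn A [tvn_table()] (must be complete: every group x difficulty x
#'   noise cell present).
#' @param free Character vector, subset of `c("a_m", "a_a", "a_e")`: which
#'   case-group coefficients are free. Empty vector = null model.
#' @param ref_group Label of the reference group (coefficients fixed at 1);
#'   defaults to `"control"` when present.
#' @param n_starts Random multi-starts.
#' @param seed Integer seed for the starts.
#' @param extra_starts Optional list of additional working-scale start
#'   vectors (used by [fit_ptm_models()] to warm-start each model from the
#'   solutions of its nested submodels, which keeps variance explained
#'   monotone in model nesting).
#' @return An object of class `ptm_group_fit`: `estimates` (named list),
#'   `free`, `k`, `r_squared`, `residuals`, `predicted`, `observed`,
#'   `ref_group`, `sse`.
#' @export
fit_ptm_group <- function(tvn, free = character(), ref_group = NULL,
                          n_starts = 20, seed = 1,
                          extra_starts = list()) {
  stopifnot(all(free %in% c("a_m", "a_a", "a_e")))
  groups <- unique(tvn$group)
  if (length(groups) != 2) stop("TvN table must contain exactly two groups",
                                call. = FALSE)
  if (is.null(ref_group)) {
    ref_group <- if ("control" %in% groups) "control" else sort(groups)[1]
  }
  counts <- dplyr::count(tvn, .data$group, .data$q)
  if (length(unique(counts$n)) != 1 || any(is.na(tvn$mean_log_threshold))) {
    stop("TvN table is incomplete", call. = FALSE)
  }
  obs <- tvn$mean_log_threshold
  dp <- pc_to_dprime(tvn$q)
  is_case <- tvn$group != ref_group
  d_max <- max(dp)
  # working scale: log for positives, raw for n_mul (feasibility-penalized)
  unpack <- function(th) {
    est <- list(n_add = exp(th[1]), n_mul = th[2], beta = exp(th[3]),
                gamma = exp(th[4]))
    for (j in seq_along(free)) est[[free[j]]] <- exp(th[4 + j])
    est
  }
  objective <- function(th) {
    est <- unpack(th)
    a_m <- if ("a_m" %in% free) est$a_m else 1
    if (est$n_mul < 0 || max(1, a_m) * est$n_mul >= 0.99 / d_max ||
        est$gamma > 10 || est$gamma < 0.2) {
      return(1e10)
    }
    pred <- predict_tvn_log(tvn, est, free, ref_group, dp, is_case)
    if (any(!is.finite(pred))) return(1e10)
    sum((pred - obs)^2)
  }
  best <- NULL
  withr::with_seed(seed, {
    starts <- c(extra_starts, lapply(seq_len(n_starts), function(s) {
      c(log(stats::runif(1, 5e-4, 0.05)),
        stats::runif(1, 0, 0.45 / d_max),
        log(stats::runif(1, 0.6, 2.5)),
        log(stats::runif(1, 1, 3.5)),
        stats::runif(length(free), log(0.6), log(1.8)))
    }))
    for (start in starts) {
      opt <- try(stats::optim(start, objective, method = "Nelder-Mead",
                              control = list(maxit = 3000,
                                             reltol = 1e-12)), silent = TRUE)
      if (inherits(opt, "try-error") || opt$value >= 1e10) next
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (!is.null(best)) { # polish the winner
      opt <- stats::optim(best$par, objective, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-13))
      if (opt$value < best$value) best <- opt
    }
  })
  if (is.null(best)) stop("optimization failed: no start converged",
                          call. = FALSE)
  est <- unpack(best$par)
  pred <- predict_tvn_log(tvn, est, free, ref_group)
  structure(
    list(estimates = est, free = free, k = 4L + length(free),
         r_squared = r_squared(pred, obs), residuals = obs - pred,
         predicted = pred, observed = obs, ref_group = ref_group,
         sse = best$value, par = best$par),
    class = "ptm_group_fit")
}

#' Nested-model F test on variance explained
#'
#' Compares a reduced candidate model against the model it is nested in via
#' `F = ((r2_full - r2_reduced) / df1) / ((1 - r2_full) / df2)`, with
#' `df1 = k_full - k_reduced` and `df2 = n_data - k_full`.
#'
#' @param full,reduced `ptm_group_fit` objects; `reduced$free` must be a
#'   subset of `full$free`.
#' @param n_data Number of fitted data points (32 for the default 2 x 2 x 8
#'   design; configurable because df conventions vary).
#' @return A tibble with `f`, `df1`, `df2`, `p`.
#' @export
nested_f_test <- function(full, reduced, n_data = 32) {
  stopifnot(inherits(full, "ptm_group_fit"),
            inherits(reduced, "ptm_group_fit"))
  if (!all(reduced$free %in% full$free) || reduced$k >= full$k) {
    stop("`reduced` is not nested in `full`", call. = FALSE)
  }
  df1 <- full$k - reduced$k
  df2 <- n_data - full$k
  if (df2 <= 0) stop("non-positive denominator degrees of freedom",
                     call. = FALSE)
  f <- if (full$r_squared == reduced$r_squared) 0 else
    ((full$r_squared - reduced$r_squared) / df1) /
      ((1 - full$r_squared) / df2)
  tibble::tibble(f = f, df1 = df1, df2 = df2,
                 p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Fit all eight candidate models to a TvN table
#'
#' Runs [fit_ptm_group()] for every candidate in [candidate_models()] and
#' tests each reduced model against the full model with [nested_f_test()].
#'
#' @inheritParams fit_ptm_group
#' @param n_data Data points for the F tests (see [nested_f_test()]).
#' @return An object of class `ptm_model_set`: the comparison tibble
#'   (`model`, `k`, `r_squared`, `f`, `df1`, `df2`, `p`, and a `fit`
#'   list-column) plus the TvN table.
#' @export
fit_ptm_models <- function(tvn, ref_group = NULL, n_starts = 20, seed = 1,
                           n_data = nrow(tvn)) {
  cand <- candidate_models()
  cand <- cand[order(cand$k), ]
  fits <- vector("list", nrow(cand))
  frees <- lapply(seq_len(nrow(cand)), function(i) {
    c("a_m", "a_a", "a_e")[unlist(cand[i, c("a_m", "a_a", "a_e")])]
  })
  for (i in seq_len(nrow(cand))) {
    # warm-start from every fitted submodel: its solution is a feasible
    # point of this model (freed coefficients it lacks start at 1)
    warm <- list()
    for (j in seq_len(i - 1)) {
      if (all(frees[[j]] %in% frees[[i]])) {
        sub <- fits[[j]]
        par <- sub$par[1:4]
        for (nm in frees[[i]]) {
          par <- c(par, if (nm %in% frees[[j]])
            log(sub$estimates[[nm]]) else 0)
        }
        warm <- c(warm, list(par))
      }
    }
    fits[[i]] <- fit_ptm_group(tvn, frees[[i]], ref_group = ref_group,
                               n_starts = n_starts,
                               seed = derive_seed(seed, cand$model[i]),
                               extra_starts = warm)
  }
  full <- fits[[which(cand$k == 7L)]]
  comp <- purrr::map2_dfr(fits, seq_len(nrow(cand)), function(fit, i) {
    ft <- if (cand$k[i] < 7L) nested_f_test(full, fit, n_data) else
      tibble::tibble(f = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                     p = NA_real_)
    dplyr::bind_cols(
      tibble::tibble(model = cand$model[i], k = cand$k[i],
                     r_squared = fit$r_squared), ft)
  })
  comp$fit <- fits
  structure(list(comparison = comp, tvn = tvn, n_data = n_data),
            class = "ptm_model_set")
}

#' Select the best-fitting candidate model
#'
#' The model with the fewest free parameters that is not significantly worse
#' than the full model at level `alpha`; ties at equal parameter count are
#' broken by higher variance explained. The full model itself is always
#' admissible.
#'
#' @param models A `ptm_model_set` from [fit_ptm_models()].
#' @param alpha Significance level of the nested F tests.
#' @return The selected `ptm_group_fit`, with the model label attached as
#'   attribute `"model"`.
#' @export
select_model <- function(models, alpha = 0.05) {
  stopifnot(inherits(models, "ptm_model_set"))
  comp <- models$comparison
  ok <- is.na(comp$p) | comp$p >= alpha
  cand <- comp[ok, ]
  cand <- cand[order(cand$k, -cand$r_squared), ]
  fit <- cand$fit[[1]]
  attr(fit, "model") <- cand$model[1]
  fit
}
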