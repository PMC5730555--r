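# Deterministic sub-seed derivation: every stochastic stage hashes the global
# seed with a stage label so stages are independent but reproducible.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

#' Posterior mode from MCMC draws
#'
#' Histogram-mode estimator for a scalar parameter: bin width by the
#' Freedman-Diaconis rule over the pooled draws, point estimate at the
#' midpoint of the tallest bin. Ties are broken toward the lower value. If
#' the draws are (numerically) constant, that constant is returned.
#'
#' @param draws Numeric vector of posterior draws (>= 1 values; intended for
#'   >= 1000).
#' @return Scalar point estimate.
#' @examples
#' map_from_draws(rnorm(5000, mean = 5))
#' @export
map_from_draws <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (length(draws) == 0L) stop("no finite draws", call. = FALSE)
  iqr <- stats::IQR(draws)
  if (iqr == 0 || diff(range(draws)) == 0) return(stats::median(draws))
  bw <- 2 * iqr * length(draws)^(-1 / 3)
  breaks <- seq(min(draws), max(draws) + bw, by = bw)
  counts <- tabulate(findInterval(draws, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  i <- which.max(counts) # which.max returns the first (lowest) maximum
  (breaks[i] + breaks[i + 1L]) / 2
}

# Split (potential scale reduction) statistic per parameter across chains,
# plus lag-1 autocorrelation of the pooled retained draws. `mat` is
# draws x chains.
chain_diagnostics <- function(mat_list) {
  m <- length(mat_list)
  n <- nrow(mat_list[[1]])
  means <- vapply(mat_list, colMeans, numeric(ncol(mat_list[[1]])))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  vars <- vapply(mat_list, function(x) apply(x, 2, stats::var),
                 numeric(ncol(mat_list[[1]])))
  if (is.null(dim(vars))) vars <- matrix(vars, nrow = 1)
  w <- rowMeans(vars)
  rhat <- if (m > 1) {
    b <- n * apply(means, 1, stats::var)
    sqrt(pmax((n - 1) / n + b / (n * pmax(w, 1e-300)), 0))
  } else rep(NA_real_, length(w))
  lag1 <- vapply(seq_along(w), function(j) {
    x <- unlist(lapply(mat_list, function(d) d[, j]))
    if (stats::var(x) == 0) return(0)
    stats::cor(x[-length(x)], x[-1])
  }, numeric(1))
  list(rhat = rhat, lag1_autocorrelation = lag1)
}

# Random-walk Metropolis over an unconstrained working scale. `log_post`
# takes the working-scale vector. Step sizes adapt toward ~30% acceptance
# during the first `cfg$adapt` iterations only, so retained draws come from
# a fixed kernel. Returns a draws matrix (draws_per_chain x d).
metropolis_chain <- function(log_post, init, step, cfg) {
  if (is.function(init)) {
    for (try in 1:100) {
      x <- init()
      lp <- log_post(x)
      if (is.finite(lp)) break
    }
  } else {
    x <- init
    lp <- log_post(x)
  }
  d <- length(x)
  if (!is.finite(lp)) stop("initial state has zero posterior density",
                           call. = FALSE)
  total <- cfg$burn_in + cfg$thin * cfg$draws_per_chain
  out <- matrix(NA_real_, cfg$draws_per_chain, d)
  acc <- 0L
  kept <- 0L
  window <- 50L
  for (it in seq_len(total)) {
    prop <- x + stats::rnorm(d, 0, step)
    lpp <- log_post(prop)
    if (is.finite(lpp) && log(stats::runif(1)) < lpp - lp) {
      x <- prop
      lp <- lpp
      acc <- acc + 1L
    }
    if (it <= cfg$adapt && it %% window == 0L) {
      rate <- acc / window
      step <- step * exp(rate - 0.3)
      acc <- 0L
    } else if (it == cfg$adapt) acc <- 0L
    if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- x
    }
  }
  out
}
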