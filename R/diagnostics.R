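#' Autocorrelation of an MCMC chain
#'
#' Standard biased autocovariance estimator normalised by lag zero (so the
#' lag-0 value is exactly 1). A constant chain yields zero autocorrelation
#' beyond lag 0, with a warning.
#'
#' @param chain Numeric vector, longer than `max_lag`.
#' @param max_lag Largest lag to report.
#' @return Tibble with columns `lag` (0..max_lag) and `acf`.
#' @export
chain_acf <- function(chain, max_lag = 20) {
  stopifnot(length(chain) > max_lag)
  if (length(chain) < 2L || stats::sd(chain) == 0) {
    warning("constant chain: autocorrelation undefined, reporting 0 beyond lag 0")
    return(tibble::tibble(lag = 0:max_lag,
                          acf = c(1, rep(0, max_lag))))
  }
  a <- stats::acf(chain, lag.max = max_lag, plot = FALSE, demean = TRUE)
  tibble::tibble(lag = 0:max_lag, acf = drop(a$acf))
}

#' Equal-tailed credible interval
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2` using the
#' default linear-interpolation quantile rule (type 7), which makes the
#' interval bit-reproducible for a given draw vector.
#'
#' @param draws Non-empty numeric vector of posterior draws.
#' @param level Coverage level in (0, 1), default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  stopifnot(length(draws) > 0, level > 0, level < 1)
  a <- (1 - level) / 2
  q <- stats::quantile(draws, probs = c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Effective sample size of a chain
#'
#' `n / (1 + 2 sum rho_l)` with the autocorrelation sum truncated at the
#' first non-positive estimate (initial positive sequence), capped at the
#' chain length.
#'
#' @param chain Numeric vector.
#' @param max_lag Truncation bound for the autocorrelation sum.
#' @return A single number in (0, n\].
#' @export
ess <- function(chain, max_lag = min(length(chain) - 1L, 200L)) {
  n <- length(chain)
  if (n < 2L || stats::sd(chain) == 0) return(n)
  rho <- chain_acf(chain, max_lag)$acf[-1]
  cut <- which(rho <= 0)
  if (length(cut) > 0L) rho <- rho[seq_len(cut[1] - 1L)]
  min(n / (1 + 2 * sum(rho)), n)
}

#' Posterior summaries of a draws object
#'
#' Posterior mean, equal-tailed credible interval, effective sample size
#' and lag-1 autocorrelation for each parameter of a Gibbs run (burn-in
#' already removed by the samplers). For g-prior runs, `weighted = TRUE`
#' reports importance-weighted means and weighted quantile intervals
#' instead; the default summarises the chain draws directly, since the
#' importance weights exist to steer the model-selection stage and their
#' effective sample size degrades quickly with n (see the methods
#' vignette).
#'
#' @param x A `quantfp_gibbs`/`quantfp_bqr` object, or a numeric matrix of
#'   draws with named columns.
#' @param weighted Use the importance weights when present.
#' @param level Credible level (default 0.95).
#' @return Tibble: `term`, `estimate`, `conf.low`, `conf.high`, `ess`,
#'   `acf1`.
#' @export
summarize_draws <- function(x, weighted = FALSE, level = 0.95) {
  w <- NULL
  if (inherits(x, "quantfp_gibbs")) {
    mat <- as.matrix(x$draws[, c(x$term, "sigma")])
    if (weighted) w <- normalized_weights(x)
  } else if (inherits(x, "quantfp_bqr")) {
    mat <- as.matrix(x$draws[, c(x$term, "sigma")])
  } else {
    mat <- as.matrix(x)
    if (is.null(colnames(mat))) {
      colnames(mat) <- paste0("par", seq_len(ncol(mat)))
    }
  }
  a <- (1 - level) / 2
  purrr::map_dfr(colnames(mat), function(nm) {
    ch <- mat[, nm]
    if (is.null(w)) {
      est <- mean(ch)
      ci <- credible_interval(ch, level)
    } else {
      est <- sum(w * ch)
      ci <- weighted_quantile(ch, w, c(a, 1 - a))
      names(ci) <- c("lower", "upper")
    }
    acf1 <- if (length(ch) > 2 && stats::sd(ch) > 0)
      chain_acf(ch, 1)$acf[2] else NA_real_
    tibble::tibble(term = nm, estimate = est,
                   conf.low = ci[["lower"]], conf.high = ci[["upper"]],
                   ess = ess(ch), acf1 = acf1)
  })
}

# weighted empirical quantiles (step interpolation of the weighted ecdf)
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p)[1]], numeric(1))
}

#' Mean absolute autocorrelation over a lag window
#'
#' Convenience summary used when comparing the mixing of two samplers: the
#' mean of |acf| over lags `1..max_lag`, averaged across the coefficient
#' chains of a fitted object.
#'
#' @param x `quantfp_gibbs` or `quantfp_bqr` object.
#' @param max_lag Lag window (default 20).
#' @return A single number.
#' @export
mean_abs_acf <- function(x, max_lag = 20) {
  terms <- x$term
  mean(vapply(terms, function(nm) {
    mean(abs(chain_acf(x$draws[[nm]], max_lag)$acf[-1]))
  }, numeric(1)))
}
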