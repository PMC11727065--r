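#' Log prior mass of a model indicator
#'
#' Beta-binomial prior on the inclusion indicators: each `gamma_d` is
#' Bernoulli(`pi`) with `pi ~ Beta(1/2, 1/2)` marginalised out, giving
#' `p(gamma) propto Beta(sum gamma + 1/2, D - sum gamma + 1/2)`.
#'
#' @param gamma Binary (0/1) indicator vector of length D.
#' @return The log of the beta function at the inclusion counts.
#' @export
#' @examples
#' gamma_log_prior(c(1, 0, 0))  # log Beta(1.5, 2.5)
gamma_log_prior <- function(gamma) {
  stopifnot(all(gamma %in% c(0, 1)))
  k <- sum(gamma); D <- length(gamma)
  lbeta(k + 0.5, D - k + 0.5)
}

# Per-latent-vector sufficient statistics reused across all gamma within
# one sweep: B'VB, B'Vu, u'Vu, sum log v, sum v.
selection_stats <- function(y, B, v, tau) {
  B <- as_design_matrix(B)
  if (any(v <= 0)) stop("all latents must be positive", call. = FALSE)
  u <- y - (1 - 2 * tau) * v
  w <- 1 / v
  list(BtVB = crossprod(B, B * w), BtVu = drop(crossprod(B, u * w)),
       uVu = sum(u^2 * w), sumlogv = sum(log(v)), sumv = sum(v),
       n = length(y), m = tau * (1 - tau))
}

#' Log marginal likelihood of the response under a model indicator
#'
#' Integrating the coefficients (quantile-specific g-prior) and the scale
#' (`p(sigma) propto 1/sigma`, with the exponential latent densities) out of
#' the scale-mixture likelihood yields a 2n-degree-of-freedom multivariate
#' Student-t with location `(1-2 tau) v`:
#' `log p(y | gamma, v) = -(n/2) log(4 pi) - (1/2) sum log v_i
#'   - (D_gamma / 2) log(1 + g) + log Gamma(3n/2)
#'   - (3n/2) log( Q_gamma / 4 + tau (1-tau) sum v_i )`,
#' where `Q_gamma = u' V H_v u`, `u = y - (1-2 tau) v`, and
#' `H_v = I - g/(g+1) B_gamma Sigma_v(gamma)^{-1} B_gamma' V`. The empty
#' model is the pure-noise case `Q = u'Vu`.
#'
#' @param y Response vector.
#' @param B Full design matrix (or `fp_design`).
#' @param gamma Binary indicator vector over the columns of `B`.
#' @param v Positive latent vector.
#' @param tau Quantile level in (0, 1).
#' @param g g-prior scaling factor.
#' @param stats Optional precomputed per-latent sufficient statistics
#'   (internal reuse across a sweep).
#' @return A single log marginal likelihood value.
#' @export
log_marginal_gamma <- function(y, B, gamma, v, tau, g, stats = NULL) {
  if (is.null(stats)) stats <- selection_stats(y, B, v, tau)
  D <- length(stats$BtVu)
  stopifnot(length(gamma) == D, all(gamma %in% c(0, 1)))
  act <- which(gamma == 1)
  q <- stats$uVu
  if (length(act) > 0L) {
    Sv <- stats$BtVB[act, act, drop = FALSE]
    R <- tryCatch(chol(Sv), error = function(e) matrix(0, 1, 1))
    if (any(diag(R)^2 < 1e-10 * max(diag(Sv)))) {
      stop("active design columns are collinear: ",
           paste(colnames(stats$BtVB)[act], collapse = ", "), call. = FALSE)
    }
    z <- backsolve(R, stats$BtVu[act], transpose = TRUE)
    q <- q - g / (g + 1) * sum(z^2)
  }
  n <- stats$n
  -(n / 2) * log(4 * pi) - 0.5 * stats$sumlogv -
    (length(act) / 2) * log1p(g) + lgamma(1.5 * n) -
    1.5 * n * log(q / 4 + stats$m * stats$sumv)
}

#' One systematic-scan Gibbs sweep over the model indicators
#'
#' Visits each component `d = 1..D` in order and redraws `gamma_d` from its
#' Bernoulli full conditional, proportional to
#' `p(y | gamma, v) p(gamma)` with the other components held fixed. The
#' stationary law of repeated sweeps is the stated model posterior, which
#' is checkable by exact enumeration for small D.
#'
#' @inheritParams log_marginal_gamma
#' @param gamma Current binary indicator vector.
#' @return Updated indicator vector.
#' @export
gamma_sweep <- function(gamma, y, B, v, tau, g, stats = NULL) {
  if (is.null(stats)) stats <- selection_stats(y, B, v, tau)
  for (d in seq_along(gamma)) {
    g1 <- gamma; g1[d] <- 1
    g0 <- gamma; g0[d] <- 0
    l1 <- log_marginal_gamma(y, B, g1, v, tau, g, stats = stats) +
      gamma_log_prior(g1)
    l0 <- log_marginal_gamma(y, B, g0, v, tau, g, stats = stats) +
      gamma_log_prior(g0)
    p1 <- 1 / (1 + exp(l0 - l1))
    gamma[d] <- as.numeric(stats::runif(1) < p1)
  }
  gamma
}

#' Stage-3 importance reweighting and stochastic model search
#'
#' Selects `S` latent vectors from a stage-2 run by weighted sampling
#' without replacement on the importance weights (Gumbel-top-k on the log
#' weights), then runs one [gamma_sweep()] per selected latent vector,
#' carrying the indicator across steps. After discarding `S_burn` steps the
#' marginal inclusion probability of predictor `d` is the average of the
#' retained `gamma_d`.
#'
#' @param gibbs A `quantfp_gibbs` object (stage-2 run, weights attached).
#' @param y Response vector used in the stage-2 run.
#' @param B Design matrix used in the stage-2 run.
#' @param S Reweighting steps (default 1250).
#' @param S_burn Steps discarded as burn-in (default 500).
#' @param threshold Inclusion threshold on the MIPs (default 0.9).
#' @param seed Optional integer seed.
#' @param gamma_init Initial indicator (default: all ones).
#' @return An object of class `quantfp_selection`: list with `mip` (tibble:
#'   `term`, `mip`, `selected`), `gamma_draws`, `threshold`, `S_tilde`,
#'   `tau`, `g`.
#' @export
run_selection <- function(gibbs, y, B, S = 1250, S_burn = 500,
                          threshold = 0.9, seed = NULL, gamma_init = NULL) {
  stopifnot(inherits(gibbs, "quantfp_gibbs"), S_burn < S)
  if (!is.null(seed)) set.seed(seed)
  Bm <- as_design_matrix(B)
  D <- ncol(Bm)
  lw <- gibbs$draws$log_weight
  ok <- which(is.finite(lw))
  if (S > length(ok)) {
    stop("S (", S, ") exceeds the ", length(ok),
         " available weighted draws", call. = FALSE)
  }
  # Gumbel-top-k: the S largest log w + Gumbel noise form an exact weighted
  # sample without replacement.
  keys <- lw[ok] - log(-log(stats::runif(length(ok))))
  pick <- ok[order(keys, decreasing = TRUE)[seq_len(S)]]
  gamma <- if (is.null(gamma_init)) rep(1, D) else gamma_init
  gdraws <- matrix(NA_real_, S, D)
  for (s in seq_len(S)) {
    v <- gibbs$v_draws[pick[s], ]
    stats <- selection_stats(y, Bm, v, gibbs$tau)
    gamma <- gamma_sweep(gamma, y, Bm, v, gibbs$tau, gibbs$g, stats = stats)
    gdraws[s, ] <- gamma
  }
  retained <- gdraws[(S_burn + 1):S, , drop = FALSE]
  mip <- colMeans(retained)
  out <- tibble::tibble(term = gibbs$term, mip = mip,
                        selected = mip >= threshold)
  structure(
    list(mip = out, gamma_draws = gdraws, threshold = threshold,
         S = S, S_burn = S_burn, S_tilde = nrow(retained),
         tau = gibbs$tau, g = gibbs$g),
    class = "quantfp_selection"
  )
}

#' Predictors whose marginal inclusion probability clears the threshold
#'
#' @param x A `quantfp_selection` object.
#' @param threshold Inclusion threshold (default: the one stored in `x`).
#' @return Integer indices of the selected design columns.
#' @export
#' @examples
#' # mip = (1.0, 0.31, 0.97) with threshold 0.9 selects columns 1 and 3
select_predictors <- function(x, threshold = NULL) {
  stopifnot(inherits(x, "quantfp_selection"))
  thr <- if (is.null(threshold)) x$threshold else threshold
  which(x$mip$mip >= thr)
}

#' @export
print.quantfp_selection <- function(x, ...) {
  cat(sprintf(
    "Marginal inclusion probabilities (tau = %.2f, g = %g, %d retained sweeps)\n",
    x$tau, x$g, x$S_tilde))
  print(x$mip)
  invisible(x)
}

#' @export
tidy.quantfp_selection <- function(x, ...) x$mip

#' @export
glance.quantfp_selection <- function(x, ...) {
  tibble::tibble(tau = x$tau, g = x$g, S = x$S, S_burn = x$S_burn,
                 S_tilde = x$S_tilde, threshold = x$threshold,
                 n_selected = sum(x$mip$selected))
}

#' Format marginal inclusion probabilities as a wide table
#'
#' One row per model/quantile, one column per predictor, MIPs to four
#' decimals - the conventional presentation for reporting which predictors
#' clear the inclusion threshold.
#'
#' @param ... Named `quantfp_selection` objects; names become row labels.
#' @return A tibble in wide layout.
#' @export
mip_table <- function(...) {
  fits <- list(...)
  stopifnot(length(fits) > 0)
  purrr::imap_dfr(fits, function(f, nm) {
    wide <- tidyr::pivot_wider(
      dplyr::mutate(f$mip, mip = round(.data$mip, 4)),
      id_cols = character(), names_from = "term", values_from = "mip")
    dplyr::bind_cols(tibble::tibble(model = nm, tau = f$tau), wide)
  })
}
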