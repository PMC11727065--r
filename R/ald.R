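#' Quantile-level constants
#'
#' For a quantile level `tau` in (0, 1), returns the constants used
#' throughout the asymmetric-Laplace mixture machinery:
#' `theta1 = (1 - 2 tau) / (tau (1 - tau))`, `theta2 = 2 / (tau (1 - tau))`,
#' together with `xi = 1 - 2 tau` (the location loading of the exponential
#' latent in the parameterisation used here, where the latent has rate
#' `tau (1 - tau) / sigma`) and `m = tau (1 - tau)`.
#'
#' @param tau Quantile level, a single number strictly between 0 and 1.
#' @return A list with elements `tau`, `theta1`, `theta2`, `xi` and `m`.
#' @export
#' @examples
#' quantile_constants(0.5)$theta1  # 0
quantile_constants <- function(tau) {
  check_tau(tau)
  m <- tau * (1 - tau)
  list(tau = tau, theta1 = (1 - 2 * tau) / m, theta2 = 2 / m,
       xi = 1 - 2 * tau, m = m)
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) ||
      tau <= 0 || tau >= 1) {
    stop("'tau' must be a single number strictly between 0 and 1", call. = FALSE)
  }
  invisible(tau)
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("'sigma' must be a single positive number", call. = FALSE)
  }
  invisible(sigma)
}

#' Check (pinball) loss
#'
#' `rho_tau(delta) = delta * (tau - 1\{delta < 0\})`: positive residuals are
#' weighted by `tau`, negative ones by `1 - tau`. Its minimiser over a
#' location parameter is the `tau`-quantile.
#'
#' @param delta Numeric vector of residuals.
#' @param tau Quantile level in (0, 1).
#' @return Non-negative numeric vector, zero exactly where `delta == 0`.
#' @export
#' @examples
#' check_loss(-2, 0.75)  # 0.5
check_loss <- function(delta, tau) {
  check_tau(tau)
  delta * (tau - (delta < 0))
}

#' Asymmetric Laplace density
#'
#' Density of the ALD with location `mu`, scale `sigma` and skewness
#' `tau`: `tau (1 - tau) / sigma * exp(-rho_tau(x - mu) / sigma)`. Its
#' `tau`-quantile is at `mu`, so maximising this likelihood is equivalent
#' to minimising the check loss.
#'
#' @param x Numeric vector of evaluation points.
#' @param mu Location (default 0).
#' @param sigma Positive scale.
#' @param tau Quantile level in (0, 1).
#' @param log Return the log density?
#' @return Numeric vector of (log) density values.
#' @export
#' @examples
#' dald(0, sigma = 1, tau = 0.5)  # 0.25
dald <- function(x, mu = 0, sigma = 1, tau = 0.5, log = FALSE) {
  check_tau(tau); check_sigma(sigma)
  ll <- log(tau) + log1p(-tau) - log(sigma) - check_loss(x - mu, tau) / sigma
  if (log) ll else exp(ll)
}

#' ALD density via its normal-exponential scale mixture
#'
#' Evaluates the ALD density by adaptive quadrature over the mixing latent:
#' `f(eps) = Int N(eps; (1-2 tau) v, 2 sigma v) Exp(v; tau(1-tau)/sigma) dv`.
#' By the Andrews-Mallows identity this equals [dald()]; the function exists
#' so the identity can be asserted numerically, since the Gibbs samplers in
#' this package rely on exactly this representation.
#'
#' @inheritParams dald
#' @param rel.tol Relative tolerance passed to [stats::integrate()].
#' @return Numeric vector of density values.
#' @export
#' @examples
#' dald_mixture(0, sigma = 1, tau = 0.5)  # 0.25
dald_mixture <- function(x, sigma = 1, tau = 0.5, rel.tol = 1e-10) {
  check_tau(tau); check_sigma(sigma)
  m <- tau * (1 - tau)
  vapply(x, function(e) {
    q <- stats::integrate(
      function(v) stats::dnorm(e, (1 - 2 * tau) * v, sqrt(2 * sigma * v)) *
        stats::dexp(v, rate = m / sigma),
      lower = 0, upper = Inf, rel.tol = rel.tol
    )
    if (q$message != "OK") {
      stop("mixture quadrature did not converge: ", q$message, call. = FALSE)
    }
    q$value
  }, numeric(1))
}

#' Random asymmetric Laplace deviates
#'
#' Draws from `AL(mu, sigma, tau)` using the location-scale mixture: a
#' latent `v ~ Exp(rate = tau(1-tau)/sigma)` followed by
#' `mu + (1-2 tau) v + sqrt(2 sigma v) z`, `z ~ N(0, 1)`. This exercises the
#' same representation the samplers in this package are built on.
#'
#' @param n Number of draws.
#' @inheritParams dald
#' @return Numeric vector of length `n`.
#' @export
rald <- function(n, mu = 0, sigma = 1, tau = 0.5) {
  check_tau(tau); check_sigma(sigma)
  m <- tau * (1 - tau)
  v <- stats::rexp(n, rate = m / sigma)
  mu + (1 - 2 * tau) * v + sqrt(2 * sigma * v) * stats::rnorm(n)
}

#' Quantile function of the asymmetric Laplace distribution
#'
#' @param p Probabilities.
#' @inheritParams dald
#' @return Numeric vector of quantiles.
#' @export
qald <- function(p, mu = 0, sigma = 1, tau = 0.5) {
  check_tau(tau); check_sigma(sigma)
  # F(x) = tau * exp((1-tau) x / sigma) for x <= 0; 1 - (1-tau) exp(-tau x/sigma) above
  ifelse(p <= tau,
         mu + sigma / (1 - tau) * log(p / tau),
         mu - sigma / tau * log((1 - p) / (1 - tau)))
}

#' Complete-data log likelihood of the mixture representation
#'
#' The joint log density of the response given coefficients, scale and the
#' exponential latents under the scale-mixture form:
#' `sum_i [ -log(4 pi sigma^3 v_i)/2 - (y_i - B_i'beta - (1-2 tau) v_i)^2 /
#' (4 sigma v_i) - tau(1-tau) v_i / sigma ]`. This is the quantity the EM
#' Q-function averages and the importance weights evaluate.
#'
#' @param y Numeric response vector, length n.
#' @param B n x D design matrix (or `fp_design`).
#' @param beta Coefficient vector, length D.
#' @param sigma Positive scale.
#' @param v Positive latent vector, length n.
#' @param tau Quantile level in (0, 1).
#' @return A single number, the complete-data log likelihood.
#' @export
ald_complete_loglik <- function(y, B, beta, sigma, v, tau) {
  check_tau(tau); check_sigma(sigma)
  B <- as_design_matrix(B)
  stopifnot(length(y) == nrow(B), length(beta) == ncol(B),
            length(v) == length(y))
  if (any(v <= 0)) stop("all latent values 'v' must be positive", call. = FALSE)
  m <- tau * (1 - tau)
  r <- y - drop(B %*% beta) - (1 - 2 * tau) * v
  sum(-0.5 * log(4 * pi * sigma^3 * v) - r^2 / (4 * sigma * v) - m * v / sigma)
}
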