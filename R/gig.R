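#' Generalised inverse Gaussian density
#'
#' Density proportional to `x^(lambda - 1) exp(-(c x + d / x) / 2)` on
#' `(0, Inf)`, normalised by the modified Bessel function of the second
#' kind: `2 (d/c)^(lambda/2) K_lambda(sqrt(c d))`. The `lambda = 0` case,
#' normalised by `2 K_0(sqrt(c d))`, is the full conditional of the
#' exponential mixing latents under the g-prior sampler.
#'
#' @param x Positive numeric vector of evaluation points.
#' @param lambda Real index.
#' @param c,d Positive rate parameters.
#' @param log Return the log density?
#' @return Numeric vector of (log) density values.
#' @export
#' @examples
#' integrate(dgig, 0, Inf, lambda = 0, c = 1, d = 4)  # 1
dgig <- function(x, lambda, c, d, log = FALSE) {
  stopifnot(c > 0, d > 0)
  om <- sqrt(c * d)
  lognc <- log(2) + (lambda / 2) * (log(d) - log(c)) + log_besselK(om, abs(lambda))
  ll <- (lambda - 1) * log(x) - 0.5 * (c * x + d / x) - lognc
  ll[x <= 0] <- -Inf
  if (log) ll else exp(ll)
}

# log K_nu(x), using the exponentially scaled Bessel function so that large
# arguments (common when residuals are small relative to sigma) do not
# underflow.
log_besselK <- function(x, nu) {
  log(besselK(x, nu, expon.scaled = TRUE)) - x
}

#' Generalised inverse Gaussian random deviates
#'
#' Vectorised exact sampler for `GIG(lambda, c, d)` with density
#' proportional to `x^(lambda-1) exp(-(c x + d/x)/2)`. Two index values are
#' supported, covering the full conditionals arising in asymmetric-Laplace
#' quantile regression:
#'
#' * `lambda = 0` - rejection sampling on the log scale `t = log(x sqrt(c/d))`,
#'   where the density `exp(-omega cosh t)`, `omega = sqrt(c d)`, is symmetric
#'   and log-concave; a uniform centre piece with exponential tails bounds it
#'   with uniformly bounded expected rejections.
#' * `lambda = 1/2` - the reciprocal of an inverse-Gaussian variate
#'   (Michael-Schucany-Haas), since `1/X ~ GIG(-1/2, d, c)` is inverse
#'   Gaussian with mean `sqrt(c/d)` and shape `c`.
#'
#' @param n Number of draws.
#' @param lambda Index, either 0 or 0.5.
#' @param c,d Positive parameters, scalars or vectors of length `n`.
#' @return Numeric vector of `n` positive draws.
#' @export
rgig <- function(n, lambda, c, d) {
  if (any(c <= 0) || any(d <= 0)) {
    stop("GIG parameters 'c' and 'd' must be positive", call. = FALSE)
  }
  c <- rep_len(c, n); d <- rep_len(d, n)
  if (lambda == 0) {
    rgig_zero(n, c, d)
  } else if (lambda == 0.5) {
    1 / rinvgauss(n, mean = sqrt(c / d), shape = c)
  } else {
    stop("only lambda = 0 and lambda = 1/2 are implemented", call. = FALSE)
  }
}

# GIG(0, c, d): x = sqrt(d/c) e^t with t having density prop. to
# exp(-omega cosh t). Envelope: constant on [-t0, t0] where
# omega (cosh t0 - 1) = 1, exponential with slope omega sinh(t0) beyond.
rgig_zero <- function(n, c, d) {
  om <- sqrt(c * d)
  t0 <- acosh(1 + 1 / om)
  s <- om * sinh(t0)              # |tail slope| at +-t0
  w_mid <- 2 * t0                 # envelope mass of the centre piece
  w_tail <- exp(-1) / s           # each tail (height e^{-1} at t0)
  p_mid <- w_mid / (w_mid + 2 * w_tail)
  p_tail <- w_tail / (w_mid + 2 * w_tail)
  t <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    k <- length(todo)
    u <- stats::runif(k)
    omt <- om[todo]; t0t <- t0[todo]; st <- s[todo]
    pm <- p_mid[todo]; pt <- p_tail[todo]
    prop <- numeric(k); logenv <- numeric(k)
    mid <- u < pm
    tail_hi <- !mid & (u < pm + pt)
    # centre: uniform on [-t0, t0], envelope log-height 0
    prop[mid] <- stats::runif(sum(mid), -t0t[mid], t0t[mid])
    # tails: shifted exponentials, envelope log-height -1 - s (t - t0)
    e1 <- stats::rexp(sum(tail_hi)); e2 <- stats::rexp(sum(!mid & !tail_hi))
    prop[tail_hi] <- t0t[tail_hi] + e1 / st[tail_hi]
    prop[!mid & !tail_hi] <- -(t0t[!mid & !tail_hi] + e2 / st[!mid & !tail_hi])
    logenv[mid] <- 0
    logenv[!mid] <- -1 - st[!mid] * (abs(prop[!mid]) - t0t[!mid])
    logf <- -omt * (cosh(prop) - 1)
    acc <- log(stats::runif(k)) < logf - logenv
    t[todo[acc]] <- prop[acc]
    todo <- todo[!acc]
  }
  sqrt(d / c) * exp(t)
}

#' Inverse-Gaussian random deviates
#'
#' Michael-Schucany-Haas transformation method for the inverse-Gaussian
#' distribution with mean `mean` and shape `shape` (density proportional to
#' `x^(-3/2) exp(-shape (x - mean)^2 / (2 mean^2 x))`).
#'
#' @param n Number of draws.
#' @param mean,shape Positive parameters, scalars or length-`n` vectors.
#' @return Numeric vector of `n` positive draws.
#' @export
rinvgauss <- function(n, mean, shape) {
  stopifnot(all(mean > 0), all(shape > 0))
  mu <- rep_len(mean, n); lam <- rep_len(shape, n)
  z <- stats::rnorm(n)
  y <- z^2
  x <- mu + mu^2 * y / (2 * lam) - mu / (2 * lam) * sqrt(4 * mu * lam * y + mu^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' Moments of the GIG distribution from Bessel closed forms
#'
#' `E[X^k] = (d/c)^(k/2) K_(lambda+k)(sqrt(cd)) / K_lambda(sqrt(cd))`.
#' Used as an independent oracle against the sampler.
#'
#' @param k Moment order (possibly negative).
#' @inheritParams dgig
#' @return The k-th moment.
#' @export
gig_moment <- function(k, lambda, c, d) {
  om <- sqrt(c * d)
  exp((k / 2) * (log(d) - log(c)) +
        log_besselK(om, abs(lambda + k)) - log_besselK(om, abs(lambda)))
}
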