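#' Frequentist fractional-polynomial quantile regression
#'
#' Minimises the check loss `sum rho_tau(y_i - B_i'beta)` by a
#' majorise-minimise (IRLS) algorithm: each step solves the weighted least
#' squares problem that majorises the check loss at the current residuals
#' (absolute residuals floored at `floor`). Confidence intervals come from
#' a nonparametric bootstrap over rows.
#'
#' @param y Response vector.
#' @param B Design matrix or `fp_design` (full column rank).
#' @param tau Quantile level in (0, 1).
#' @param boot Number of bootstrap resamples for the 95 percent intervals
#'   (default 999; set 0 to skip).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed for the bootstrap.
#' @param tol,max_iter,floor MM iteration controls.
#' @return An object of class `quantfp_qr`: tibble `coef` (`term`,
#'   `estimate`, `conf.low`, `conf.high`), minimised `objective`,
#'   `tau`, convergence info.
#' @export
#' @examples
#' fit_qr_fp(c(1, 2, 3, 10, 11), matrix(1, 5), tau = 0.5, boot = 0)
fit_qr_fp <- function(y, B, tau, boot = 999, level = 0.95, seed = NULL,
                      tol = 1e-10, max_iter = 500, floor = 1e-11) {
  check_tau(tau)
  Bm <- as_design_matrix(B)
  stopifnot(length(y) == nrow(Bm), nrow(Bm) >= ncol(Bm))
  if (!is.null(seed)) set.seed(seed)
  est <- qr_mm(y, Bm, tau, tol, max_iter, floor)
  terms <- colnames(Bm)
  if (is.null(terms)) terms <- paste0("b", seq_len(ncol(Bm)))
  ci <- matrix(NA_real_, ncol(Bm), 2)
  if (boot > 0) {
    n <- length(y)
    bmat <- matrix(NA_real_, boot, ncol(Bm))
    for (b in seq_len(boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      bmat[b, ] <- qr_mm(y[idx], Bm[idx, , drop = FALSE], tau,
                         tol = 1e-8, max_iter = 200, floor = floor)
    }
    a <- (1 - level) / 2
    ci <- t(apply(bmat, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  }
  structure(
    list(coef = tibble::tibble(term = terms, estimate = est,
                               conf.low = ci[, 1], conf.high = ci[, 2]),
         objective = sum(check_loss(y - drop(Bm %*% est), tau)),
         tau = tau, level = level, boot = boot, n = length(y)),
    class = "quantfp_qr"
  )
}

# MM iterations for the check loss; the floor is tightened as iterations
# approach interpolation so the fixed point is the quantile-regression
# solution to high accuracy on well-conditioned problems.
qr_mm <- function(y, B, tau, tol, max_iter, floor) {
  beta <- drop(qr.coef(qr(B), y))
  beta[!is.finite(beta)] <- 0
  obj <- sum(check_loss(y - drop(B %*% beta), tau))
  for (it in seq_len(max_iter)) {
    beta_new <- em_step_beta(y, B, beta, tau, floor = floor)
    obj_new <- sum(check_loss(y - drop(B %*% beta_new), tau))
    if (!is.finite(obj_new)) break
    done <- abs(obj - obj_new) < tol * (abs(obj) + tol)
    if (obj_new <= obj) beta <- beta_new
    obj <- min(obj, obj_new)
    if (done) break
  }
  beta
}

#' @export
print.quantfp_qr <- function(x, ...) {
  cat(sprintf("Check-loss quantile regression (tau = %.2f, objective = %.6g)\n",
              x$tau, x$objective))
  print(x$coef)
  invisible(x)
}

#' @export
tidy.quantfp_qr <- function(x, ...) x$coef

#' @export
glance.quantfp_qr <- function(x, ...) {
  tibble::tibble(tau = x$tau, objective = x$objective, nobs = x$n,
                 boot = x$boot, level = x$level)
}

#' Unregularised Bayesian quantile regression (diffuse prior)
#'
#' Gibbs sampler for asymmetric-Laplace quantile regression under a flat
#' prior on the coefficients and `p(sigma) propto 1/sigma`, using the same
#' scale-mixture conditional family as the g-prior sampler: latents from
#' `GIG(1/2, 1/(2 sigma), (y_i - B_i'beta)^2 / (2 sigma))`, scale from
#' `IG(3n/2, sum (y_i - B_i'beta - (1-2 tau) v_i)^2 / (4 v_i)
#'  + tau(1-tau) sum v_i)`, coefficients from
#' `N(Sigma_v^{-1} B'V (y - (1-2 tau) v), 2 sigma Sigma_v^{-1})`.
#'
#' @inheritParams fit_qr_fp
#' @param R Total iterations (default 10000).
#' @param burn_in Discarded iterations (default 1000).
#' @param seed Optional integer seed.
#' @param level Credible level for the reported intervals.
#' @return An object of class `quantfp_bqr`: `draws` tibble (`iteration`,
#'   coefficients, `sigma`), `coef` summary tibble, `tau`.
#' @export
fit_bqr_fp <- function(y, B, tau, R = 10000, burn_in = 1000, seed = NULL,
                       level = 0.95) {
  check_tau(tau)
  stopifnot(burn_in < R)
  Bm <- as_design_matrix(B)
  n <- length(y); D <- ncol(Bm)
  if (!is.null(seed)) set.seed(seed)
  beta <- drop(qr.coef(qr(Bm), y)); beta[!is.finite(beta)] <- 0
  sigma <- max(mean(abs(y - drop(Bm %*% beta))), 1e-8)
  m <- tau * (1 - tau)
  keep <- R - burn_in
  beta_out <- matrix(NA_real_, keep, D)
  sigma_out <- numeric(keep)
  for (r in seq_len(R)) {
    res <- y - drop(Bm %*% beta)
    d <- pmax(res^2, 1e-10) / (2 * sigma)
    v <- rgig(n, lambda = 0.5, c = 1 / (2 * sigma), d = d)
    u <- y - (1 - 2 * tau) * v
    rv <- u - drop(Bm %*% beta)
    sigma <- 1 / stats::rgamma(1, shape = 1.5 * n,
                               rate = sum(rv^2 / (4 * v)) + m * sum(v))
    w <- 1 / v
    Sv <- crossprod(Bm, Bm * w)
    Rch <- chol(Sv)
    mean_b <- drop(chol2inv(Rch) %*% crossprod(Bm, u * w))
    beta <- mean_b + sqrt(2 * sigma) * drop(backsolve(Rch, stats::rnorm(D)))
    if (r > burn_in) {
      beta_out[r - burn_in, ] <- beta
      sigma_out[r - burn_in] <- sigma
    }
  }
  terms <- colnames(Bm)
  if (is.null(terms)) terms <- paste0("b", seq_len(D))
  colnames(beta_out) <- terms
  draws <- tibble::as_tibble(beta_out)
  draws$sigma <- sigma_out
  draws <- tibble::add_column(draws, iteration = burn_in + seq_len(keep),
                              .before = 1)
  a <- (1 - level) / 2
  coef <- tibble::tibble(
    term = terms,
    estimate = colMeans(beta_out),
    conf.low = apply(beta_out, 2, stats::quantile, probs = a, names = FALSE),
    conf.high = apply(beta_out, 2, stats::quantile, probs = 1 - a, names = FALSE)
  )
  structure(
    list(draws = draws, coef = coef, tau = tau, R = R, burn_in = burn_in,
         level = level, n = n, term = terms,
         sigma_mean = mean(sigma_out), sigma_sd = stats::sd(sigma_out)),
    class = "quantfp_bqr"
  )
}

#' @export
print.quantfp_bqr <- function(x, ...) {
  cat(sprintf(
    "Diffuse-prior Bayesian quantile regression (tau = %.2f, %d retained draws)\n",
    x$tau, nrow(x$draws)))
  print(x$coef)
  cat(sprintf("sigma: %.4g (posterior sd %.3g)\n", x$sigma_mean, x$sigma_sd))
  invisible(x)
}

#' @export
tidy.quantfp_bqr <- function(x, ...) x$coef

#' @export
glance.quantfp_bqr <- function(x, ...) {
  tibble::tibble(tau = x$tau, R = x$R, burn_in = x$burn_in, nobs = x$n,
                 sigma = x$sigma_mean, level = x$level)
}

#' Tables-style coefficient report
#'
#' Formats one or more fitted models as "estimate (lower, upper)" strings,
#' one row per predictor and one column per quantile level - the layout
#' used for reporting quantile-regression coefficient comparisons.
#'
#' @param ... Named fitted objects with a [generics::tidy()] method
#'   returning `term`, `estimate`, `conf.low`, `conf.high`.
#' @param digits Decimal places (default 3).
#' @return A tibble in wide layout.
#' @export
coef_table <- function(..., digits = 3) {
  fits <- list(...)
  stopifnot(length(fits) > 0)
  fmt <- function(e, l, u) sprintf(paste0("%.", digits, "f (%.", digits,
                                          "f, %.", digits, "f)"), e, l, u)
  purrr::imap_dfr(fits, function(f, nm) {
    td <- tidy(f)
    tibble::tibble(model = nm, term = td$term,
                   value = fmt(td$estimate, td$conf.low, td$conf.high))
  }) |>
    tidyr::pivot_wider(names_from = "model", values_from = "value")
}
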