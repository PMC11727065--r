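test_that("beta update matches an independent dense-matrix evaluation", {
  inst <- small_instance(n = 3, beta = c(1.5, -0.4), tau = 0.3, seed = 13)
  beta_prev <- c(1, 0)
  got <- em_step_beta(inst$y, inst$B, beta_prev, inst$tau)
  # direct evaluation of (B'WB)^{-1} B'W (y - (1-2tau) Delta3)
  d3 <- pmax(abs(inst$y - inst$B %*% beta_prev), 1e-8)
  W <- diag(1 / drop(d3))
  oracle <- solve(t(inst$B) %*% W %*% inst$B,
                  t(inst$B) %*% W %*% (inst$y - (1 - 2 * inst$tau) * d3))
  expect_equal(got, drop(oracle), ignore_attr = TRUE)
})

test_that("constant residuals reduce the beta update to offset least squares", {
  # choose y so that residuals at beta_prev are exactly c > 0
  withr::with_seed(3, B <- cbind(1, rnorm(6)))
  beta_prev <- c(2, 1)
  cc <- 0.7
  y <- drop(B %*% beta_prev) + cc
  tau <- 0.8
  got <- em_step_beta(y, B, beta_prev, tau)
  ls <- qr.coef(qr(B), y - (1 - 2 * tau) * cc)
  expect_equal(got, drop(ls), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("sigma update matches the printed formula term by term", {
  inst <- small_instance(n = 3, tau = 0.7, seed = 17)
  beta_prev <- c(1.8, -1.2); sigma_prev <- 0.6
  beta_new <- em_step_beta(inst$y, inst$B, beta_prev, inst$tau)
  got <- em_step_sigma(inst$y, inst$B, beta_new, beta_prev, sigma_prev,
                       inst$tau)
  r_prev <- drop(inst$y - inst$B %*% beta_prev)
  r_new <- drop(inst$y - inst$B %*% beta_new)
  d3 <- abs(r_prev); d2 <- abs(r_prev) + 2 * sigma_prev
  n <- 3
  oracle <- (sum(d2) + sum(r_new^2 / d3) -
               2 * (1 - 2 * inst$tau) * sum(r_new)) / (2 * (3 * n + 2))
  expect_equal(got, oracle)
})

test_that("perfect fit at the median leaves only the Delta2 sum", {
  withr::with_seed(8, B <- cbind(1, rnorm(5)))
  beta <- c(1, 2)
  y <- drop(B %*% beta)            # zero residuals at beta
  sigma_prev <- 0.4
  got <- em_step_sigma(y, B, beta, beta, sigma_prev, tau = 0.5)
  n <- 5
  expect_equal(got, sum(abs(y - drop(B %*% beta)) + 2 * sigma_prev) /
                 (2 * (3 * n + 2)))
})

test_that("EM is scale equivariant in the response", {
  inst <- small_instance(n = 60, tau = 0.75, seed = 23)
  f1 <- qreg_em(inst$y, inst$B, inst$tau)
  f2 <- qreg_em(2 * inst$y, inst$B, inst$tau)
  expect_equal(f2$beta, 2 * f1$beta, tolerance = 1e-5)
  expect_equal(f2$sigma, 2 * f1$sigma, tolerance = 1e-5)
})

test_that("EM recovers noiseless data and the intercept-only median", {
  withr::with_seed(31, B <- cbind(a = rnorm(30, 3), b = runif(30, 1, 2)))
  beta_star <- c(2, -1)
  fit <- qreg_em(drop(B %*% beta_star), B, tau = 0.5)
  expect_equal(fit$beta, beta_star, tolerance = 1e-6, ignore_attr = TRUE)
  # intercept-only at the median is the sample median (LAD oracle)
  withr::with_seed(32, y <- rt(41, df = 3) * 2 + 1)
  fit2 <- qreg_em(y, matrix(1, 41, 1), tau = 0.5)
  expect_equal(unname(fit2$beta), median(y), tolerance = 1e-4)
})

test_that("a fixed point returns immediately as converged", {
  inst <- small_instance(n = 50, seed = 77)
  f1 <- qreg_em(inst$y, inst$B, 0.5)
  f2 <- qreg_em(inst$y, inst$B, 0.5, init_beta = f1$beta,
                init_sigma = f1$sigma)
  expect_true(f2$converged)
  expect_lte(f2$iterations, 2L)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
})

test_that("beta steps never increase the check loss (MM property)", {
  inst <- small_instance(n = 80, tau = 0.25, seed = 55)
  beta <- c(0, 0)
  obj <- sum(check_loss(inst$y - drop(inst$B %*% beta), inst$tau))
  for (k in 1:25) {
    beta <- em_step_beta(inst$y, inst$B, beta, inst$tau)
    obj_new <- sum(check_loss(inst$y - drop(inst$B %*% beta), inst$tau))
    expect_lte(obj_new, obj + 1e-10)
    obj <- obj_new
  }
})

test_that("EM output is invariant to row permutation", {
  inst <- small_instance(n = 70, tau = 0.75, seed = 91)
  f1 <- qreg_em(inst$y, inst$B, inst$tau)
  perm <- withr::with_seed(1, sample(70))
  f2 <- qreg_em(inst$y[perm], inst$B[perm, ], inst$tau)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-7)
  expect_equal(f1$sigma, f2$sigma, tolerance = 1e-7)
})

test_that("median EM agrees with the frequentist LAD fit", {
  inst <- small_instance(n = 120, beta = c(1.2, 0.8), sigma = 0.6, seed = 12)
  em <- qreg_em(inst$y, inst$B, 0.5)
  qr <- fit_qr_fp(inst$y, inst$B, 0.5, boot = 0)
  expect_equal(unname(em$beta), qr$coef$estimate, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("tidy and glance expose the fit", {
  inst <- small_instance(seed = 2)
  fit <- qreg_em(inst$y, inst$B, 0.5)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_gt(gl$sigma, 0)
})
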