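test_that("check loss matches its piecewise definition", {
  expect_equal(check_loss(-2, 0.75), 0.5)
  expect_equal(check_loss(0, 0.3), 0)
  expect_equal(check_loss(3, 0.5), 1.5)
  expect_true(all(check_loss(c(-5, -0.1, 0.1, 5), 0.2) >= 0))
  expect_error(check_loss(1, 1.2), "tau")
})

test_that("quantile constants obey their symmetries", {
  qc <- quantile_constants(0.5)
  expect_equal(qc$theta1, 0)
  expect_gt(qc$theta2, 0)
  for (tau in c(0.1, 0.25, 0.4)) {
    expect_equal(quantile_constants(tau)$theta1,
                 -quantile_constants(1 - tau)$theta1)
  }
})

test_that("ALD density evaluates and integrates to one", {
  expect_equal(dald(0, sigma = 1, tau = 0.5), 0.25)
  expect_equal(dald(2, sigma = 1, tau = 0.5), 0.25 * exp(-1))
  for (tau in c(0.25, 0.95)) {
    total <- integrate(dald, -Inf, Inf, sigma = 0.8, tau = tau,
                       rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  expect_error(dald(0, sigma = -1), "sigma")
})

test_that("the scale-mixture density equals the closed-form ALD", {
  expect_equal(dald_mixture(0, 1, 0.5), 0.25, tolerance = 1e-6)
  expect_equal(dald_mixture(2, 1, 0.5), dald(2, sigma = 1, tau = 0.5),
               tolerance = 1e-6)
  expect_equal(dald_mixture(1, 0.5, 0.75), dald(1, sigma = 0.5, tau = 0.75),
               tolerance = 1e-6)
})

test_that("random generation places mass tau below the location", {
  withr::with_seed(11, {
    x <- rald(1e5, sigma = 1.3, tau = 0.75)
  })
  se <- sqrt(0.75 * 0.25 / 1e5)
  expect_within_3se(mean(x <= 0), 0.75, se)
})

test_that("ALD quantile function inverts the distribution", {
  expect_equal(qald(0.5, sigma = 2, tau = 0.5), 0)
  for (p in c(0.1, 0.5, 0.9)) {
    q <- qald(p, sigma = 0.7, tau = 0.3)
    mass <- integrate(dald, -Inf, q, sigma = 0.7, tau = 0.3)$value
    expect_equal(mass, p, tolerance = 1e-5)
  }
})

test_that("maximising the ALD likelihood is minimising the check loss", {
  withr::with_seed(5, eps <- rald(50, sigma = 0.9, tau = 0.3))
  nll <- -sum(dald(eps, sigma = 0.9, tau = 0.3, log = TRUE))
  expect_equal(nll, 50 * log(0.9 / (0.3 * 0.7)) +
                 sum(check_loss(eps, 0.3)) / 0.9)
})

test_that("complete-data log likelihood matches a direct re-evaluation", {
  inst <- small_instance(n = 4, tau = 0.3, seed = 9)
  withr::with_seed(2, v <- rexp(4, rate = 1))
  sigma <- 0.8
  got <- ald_complete_loglik(inst$y, inst$B, inst$beta, sigma, v, inst$tau)
  # independent term-by-term evaluation of the printed formula
  oracle <- 0
  for (i in 1:4) {
    ri <- inst$y[i] - sum(inst$B[i, ] * inst$beta) -
      (1 - 2 * inst$tau) * v[i]
    oracle <- oracle - 0.5 * log(4 * pi * sigma^3 * v[i]) -
      ri^2 / (4 * sigma * v[i]) -
      inst$tau * (1 - inst$tau) * v[i] / sigma
  }
  expect_equal(got, oracle)
  # quadratic term vanishes when y sits exactly at the latent-shifted fit
  y1 <- sum(inst$B[1, ] * inst$beta) + (1 - 2 * inst$tau) * v[1]
  got1 <- ald_complete_loglik(y1, inst$B[1, , drop = FALSE], inst$beta,
                              sigma, v[1], inst$tau)
  expect_equal(got1, -0.5 * log(4 * pi * sigma^3 * v[1]) -
                 inst$tau * (1 - inst$tau) * v[1] / sigma)
  # strictly decreasing in the misfit
  worse <- ald_complete_loglik(y1 + 1, inst$B[1, , drop = FALSE], inst$beta,
                               sigma, v[1], inst$tau)
  expect_lt(worse, got1)
  expect_error(ald_complete_loglik(inst$y, inst$B, inst$beta, sigma,
                                   c(-1, v[-1]), inst$tau), "positive")
})
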