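test_that("indicator prior evaluates the marginalised beta-binomial mass", {
  expect_equal(gamma_log_prior(c(1, 0, 0)),
               log(gamma(1.5) * gamma(2.5) / gamma(4)))
  expect_equal(exp(gamma_log_prior(c(1, 0, 0))), 0.19635, tolerance = 1e-4)
  # complement symmetry
  g <- c(1, 1, 0, 1, 0)
  expect_equal(gamma_log_prior(g), gamma_log_prior(1 - g))
  # D = 1: both models get half the mass after normalisation
  p <- exp(c(gamma_log_prior(0), gamma_log_prior(1)))
  expect_equal(p / sum(p), c(0.5, 0.5))
  expect_error(gamma_log_prior(c(1, 2)), "0, 1")
})

test_that("marginal likelihood loses its gamma dependence as g vanishes", {
  inst <- small_instance(n = 10, seed = 31)
  withr::with_seed(1, v <- rexp(10, 1))
  vals <- vapply(list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), function(gam) {
    log_marginal_gamma(inst$y, inst$B, gam, v, inst$tau, g = 1e-8)
  }, numeric(1))
  expect_lt(diff(range(vals)), 1e-6)
})

test_that("marginal likelihood is invariant to active-column reordering and flags collinearity", {
  withr::with_seed(41, {
    n <- 15
    B <- cbind(a = rnorm(n, 2), b = runif(n), c = rnorm(n, 1))
    y <- rnorm(n, B[, 1])
    v <- rexp(n, 1)
  })
  l1 <- log_marginal_gamma(y, B, c(1, 1, 0), v, 0.4, 20)
  l2 <- log_marginal_gamma(y, B[, c(2, 1, 3)], c(1, 1, 0), v, 0.4, 20)
  expect_equal(l1, l2, tolerance = 1e-10)
  Bdup <- cbind(B[, 1], B[, 1])
  expect_error(log_marginal_gamma(y, Bdup, c(1, 1), v, 0.4, 20), "collinear")
})

test_that("the sweep finds a strong predictor and ignores pure noise", {
  withr::with_seed(51, {
    n <- 20
    B <- cbind(signal = rnorm(n, 0, 1), noise = rnorm(n))
    y <- 5 * B[, 1] + rnorm(n)      # 5-sd effect on the first column
    v <- rexp(n, 1)
  })
  gam <- c(1, 1)
  hits <- matrix(NA_real_, 500, 2)
  withr::with_seed(52, for (s in 1:500) {
    gam <- gamma_sweep(gam, y, B, v, 0.5, 100)
    hits[s, ] <- gam
  })
  freq <- colMeans(hits)
  expect_gt(freq[1], 0.95)
})

test_that("flat likelihood leaves the prior's even inclusion odds", {
  withr::with_seed(61, {
    n <- 15
    B <- matrix(rnorm(n), ncol = 1)
    y <- rnorm(n)
    v <- rexp(n, 1)
  })
  gam <- 1
  hits <- withr::with_seed(62, vapply(1:4000, function(s) {
    gam <<- gamma_sweep(gam, y, B, v, 0.5, g = 1e-10)
    gam
  }, numeric(1)))
  se <- 0.5 / sqrt(ess(hits))
  expect_within_3se(mean(hits), 0.5, se)
})

test_that("selection runs are deterministic and respect the threshold rule", {
  withr::with_seed(71, {
    n <- 80
    B <- cbind(x1 = rnorm(n, 3), x2 = runif(n, 1, 2), x3 = rnorm(n))
    y <- drop(B %*% c(2, 1, 0)) + rald(n, sigma = 0.5, tau = 0.5)
  })
  gib <- gibbs_gprior(y, B, 0.5, g = 1000, R = 800, burn_in = 300, seed = 9)
  s1 <- run_selection(gib, y, B, S = 300, S_burn = 100, seed = 10)
  s2 <- run_selection(gib, y, B, S = 300, S_burn = 100, seed = 10)
  expect_identical(s1$mip, s2$mip)
  expect_true(all(s1$mip$mip >= 0 & s1$mip$mip <= 1))
  expect_error(run_selection(gib, y, B, S = 10000), "exceeds")
  # threshold rule on a report mirroring published inclusion numbers
  rep <- structure(list(mip = tibble::tibble(
    term = c("a", "b", "c"), mip = c(1.0, 0.3062, 0.9733),
    selected = c(TRUE, FALSE, TRUE)), threshold = 0.9),
    class = "quantfp_selection")
  expect_equal(select_predictors(rep), c(1L, 3L))
  expect_equal(select_predictors(rep, threshold = 0), 1:3)
  rep$mip$mip <- c(0, 0, 0)
  expect_length(select_predictors(rep), 0)
})

test_that("all-included draws give unit inclusion probabilities", {
  withr::with_seed(81, {
    n <- 60
    B <- cbind(x1 = rnorm(n, 3), x2 = runif(n, 1, 2))
    y <- drop(B %*% c(5, 4)) + rald(n, sigma = 0.3, tau = 0.5)
  })
  gib <- gibbs_gprior(y, B, 0.5, g = 1000, R = 600, burn_in = 200, seed = 3)
  sel <- run_selection(gib, y, B, S = 200, S_burn = 50, seed = 4)
  expect_equal(sel$mip$mip, c(1, 1))   # overwhelming signal on both columns
  expect_equal(sel$S_tilde, 150)
})

test_that("mip_table lays out inclusion probabilities wide", {
  rep <- structure(list(mip = tibble::tibble(
    term = c("a", "b"), mip = c(0.91234, 0.1), selected = c(TRUE, FALSE)),
    threshold = 0.9, tau = 0.5, g = 1000), class = "quantfp_selection")
  tab <- mip_table(SBP = rep)
  expect_equal(tab$model, "SBP")
  expect_equal(tab$a, 0.9123)
})
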