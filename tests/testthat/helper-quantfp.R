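# Shared fixtures: small seeded regression instances used across modules.

bp_spec <- function() {
  fp_spec(list(BMI = c(0.5, 1), Age = c(0.5, 1)),
          categorical = c("Ethnicity", "Gender", "MaritalStatus"))
}

# tiny seeded (y, B) instance with ALD errors and known coefficients
small_instance <- function(n = 40, beta = c(2, -1), sigma = 0.5, tau = 0.5,
                           seed = 42) {
  withr::with_seed(seed, {
    B <- cbind(x1 = rnorm(n, 2, 0.7), x2 = runif(n, 1, 3))
    y <- drop(B %*% beta) + rald(n, sigma = sigma, tau = tau)
    list(y = y, B = B, beta = beta, sigma = sigma, tau = tau)
  })
}

expect_within_3se <- function(est, truth, se) {
  expect_lt(abs(est - truth), 3 * se)
}
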