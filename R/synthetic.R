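#' Configuration for the NHANES-like synthetic blood-pressure generator
#'
#' Defines a seeded data-generating process mirroring the structure of the
#' 2007-2008 adult blood-pressure analysis sample: n subjects with a
#' right-skewed positive BMI (log-normal, median 27 kg/m^2), adult ages
#' (uniform 20-80 years), a 5-level ethnicity, 2-level gender and 6-level
#' marital status with probabilities matching the study margins, and
#' responses generated from the fractional-polynomial quantile model
#' `y = B beta* + eps` with `eps ~ AL(0, sigma*, tau)` by default (so the
#' fitted model is correctly specified and the true coefficient vector is
#' the tau-quantile surface). The default coefficient magnitudes are those
#' of the fitted median SBP/DBP models, and `sigma* = 5` (SBP) / `4` (DBP)
#' gives residual spreads of roughly 14 / 11 mmHg.
#'
#' @param n Number of subjects (default 4609, the study sample size).
#' @param tau Quantile level at which the error law is centred (default 0.5).
#' @param powers Named list of FP power vectors for the continuous
#'   predictors (default `BMI` and `Age`, powers `(0.5, 1)`).
#' @param beta_sbp,beta_dbp True coefficient vectors in design-column order
#'   (FP terms in sorted-power order, then Ethnicity, Gender, MaritalStatus).
#' @param sigma_sbp,sigma_dbp True ALD scales.
#' @param error Error family: `"ald"` (default), `"normal"` (sd matched to
#'   the ALD), or `"two_piece_t"` (skewed heavy tails, 4 df) for
#'   misspecification runs. Non-ALD families are shifted so their
#'   tau-quantile is zero.
#' @param bmi_meanlog,bmi_sdlog Log-normal BMI parameters.
#' @param age_range Age bounds (uniform).
#' @param p_ethnicity,p_gender,p_marital Category probabilities (must sum
#'   to one); defaults are the study margins.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 4609, tau = 0.5,
                       powers = list(BMI = c(0.5, 1), Age = c(0.5, 1)),
                       beta_sbp = c(35.55, -2.81, -1.13, 0.46, 0.57, -4.58, 0.83),
                       beta_dbp = c(-11.30, 1.10, 30.60, -2.22, 0.51, -3.40, 0.19),
                       sigma_sbp = 5, sigma_dbp = 4,
                       error = c("ald", "normal", "two_piece_t"),
                       bmi_meanlog = log(27), bmi_sdlog = 0.2,
                       age_range = c(20, 80),
                       p_ethnicity = c(0.182, 0.117, 0.459, 0.203, 0.039),
                       p_gender = c(0.501, 0.499),
                       p_marital = c(0.546, 0.061, 0.111, 0.037, 0.173, 0.072),
                       seed = NULL) {
  error <- match.arg(error)
  check_tau(tau)
  stopifnot(n > 0, sigma_sbp > 0, sigma_dbp > 0,
            abs(sum(p_ethnicity) - 1) < 1e-6,
            abs(sum(p_gender) - 1) < 1e-6,
            abs(sum(p_marital) - 1) < 1e-6)
  D <- sum(lengths(powers)) + 3L
  stopifnot(length(beta_sbp) == D, length(beta_dbp) == D)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic blood-pressure dataset
#'
#' Draws predictors and both responses under a [sim_config()]. The true
#' coefficients, powers and scales are attached as the `"truth"` attribute
#' (and retrievable with [sim_truth()]), so recovery of the generating
#' model can be asserted exactly.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `SBP`, `DBP`, `BMI`, `Age`, `Ethnicity`,
#'   `Gender`, `MaritalStatus` (categoricals integer-coded) and a `truth`
#'   attribute.
#' @export
#' @examples
#' d <- simulate_bp(sim_config(n = 100, seed = 1))
#' sim_truth(d)$beta_sbp
simulate_bp <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  data <- tibble::tibble(
    BMI = stats::rlnorm(n, config$bmi_meanlog, config$bmi_sdlog),
    Age = stats::runif(n, config$age_range[1], config$age_range[2]),
    Ethnicity = sample(seq_along(config$p_ethnicity), n, TRUE,
                       prob = config$p_ethnicity),
    Gender = sample(seq_along(config$p_gender), n, TRUE,
                    prob = config$p_gender),
    MaritalStatus = sample(seq_along(config$p_marital), n, TRUE,
                           prob = config$p_marital)
  )
  spec <- fp_spec(config$powers,
                  categorical = c("Ethnicity", "Gender", "MaritalStatus"))
  B <- build_fp_design(data, spec)$B
  data$SBP <- drop(B %*% config$beta_sbp) +
    sim_errors(n, config$sigma_sbp, config$tau, config$error)
  data$DBP <- drop(B %*% config$beta_dbp) +
    sim_errors(n, config$sigma_dbp, config$tau, config$error)
  data <- data[, c("SBP", "DBP", "BMI", "Age", "Ethnicity", "Gender",
                   "MaritalStatus")]
  attr(data, "truth") <- list(
    beta_sbp = config$beta_sbp, beta_dbp = config$beta_dbp,
    sigma_sbp = config$sigma_sbp, sigma_dbp = config$sigma_dbp,
    tau = config$tau, powers = config$powers, error = config$error,
    term = colnames(B), seed = config$seed, n = n
  )
  data
}

# error draws centred so the tau-quantile of the law is zero
sim_errors <- function(n, sigma, tau, family) {
  switch(family,
    ald = rald(n, sigma = sigma, tau = tau),
    normal = {
      sd <- sqrt(ald_variance(sigma, tau))
      e <- stats::rnorm(n, sd = sd)
      e - stats::qnorm(tau, sd = sd)
    },
    two_piece_t = {
      # two-piece Student-t(4): scale sigma, left mass tau at the origin
      u <- stats::runif(n)
      e <- ifelse(u < tau,
                  -abs(stats::rt(n, df = 4)) * sigma * (1 - tau) * 2,
                  abs(stats::rt(n, df = 4)) * sigma * tau * 2)
      e
    })
}

# variance of AL(0, sigma, tau) in this parameterisation:
# eps = (1-2tau) v + sqrt(2 sigma v) z, v ~ Exp(m/sigma), m = tau(1-tau)
ald_variance <- function(sigma, tau) {
  m <- tau * (1 - tau)
  mu_v <- sigma / m
  (1 - 2 * tau)^2 * mu_v^2 + 2 * sigma * mu_v
}

#' Retrieve the generating truth of a synthetic dataset
#'
#' @param data A tibble from [simulate_bp()] (or read back alongside its
#'   truth sidecar with [read_simulation()]).
#' @return The truth list (`beta_sbp`, `beta_dbp`, scales, powers, ...).
#' @export
sim_truth <- function(data) {
  tr <- attr(data, "truth")
  if (is.null(tr)) stop("no 'truth' attribute on this dataset", call. = FALSE)
  tr
}

#' Write a synthetic dataset with its truth sidecar
#'
#' Saves the dataset as CSV and the generating truth as JSON next to it.
#'
#' @param data Tibble from [simulate_bp()].
#' @param path CSV output path; the sidecar is `<path>` with extension
#'   `.truth.json`.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(data, path) {
  readr::write_csv(data, path)
  truth <- sim_truth(data)
  jsonlite::write_json(truth, sub("\\.csv$", ".truth.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a synthetic dataset and its truth sidecar
#'
#' @param path CSV path written by [write_simulation()].
#' @return The tibble with the `truth` attribute restored.
#' @export
read_simulation <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- sub("\\.csv$", ".truth.json", path)
  if (file.exists(sidecar)) {
    tr <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    tr$powers <- lapply(tr$powers, as.numeric)
    attr(data, "truth") <- tr
  }
  data
}

# config of the packaged n = 400 fixture (frozen seed)
fixture_config <- function() sim_config(n = 400, seed = 20240400)

#' Packaged synthetic blood-pressure fixture (n = 400)
#'
#' A small committed dataset generated by [simulate_bp()] under
#' `sim_config(n = 400, seed = 20240400)`, with its truth sidecar. Useful
#' for examples and fast end-to-end runs without simulation cost.
#'
#' @return Tibble with the study schema and a `truth` attribute.
#' @export
synthetic_bp_fixture <- function() {
  path <- system.file("extdata", "synthetic_bp_n400.csv",
                      package = "quantfp", mustWork = TRUE)
  read_simulation(path)
}
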