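test_that("categorisation applies half-open clinical bands", {
  expect_equal(as.character(categorize(c(119, 120, 139, 140), "sbp")),
               c("Normal", "Pre-hypertension", "Pre-hypertension",
                 "Hypertension"))
  expect_equal(as.character(categorize(c(79, 80, 90), "dbp")),
               c("Normal", "Pre-hypertension", "Hypertension"))
  expect_equal(as.character(categorize(c(18.4, 18.5, 40), "bmi")),
               c("Underweight", "Healthy", "Morbidly obese"))
  expect_equal(as.character(categorize(c(29, 30, 55), "age")),
               c("20-29 years", "30-39 years", ">=50 years"))
  expect_error(categorize(-5, "sbp"), "implausible")
  expect_error(categorize(500, "sbp"), "implausible")
  expect_error(categorize(100, "nope"), "unknown rule")
})

test_that("cross tabulation counts pairs like a naive double loop", {
  r <- factor(c("a", "a", "b", "b"))
  c2 <- factor(c("x", "x", "y", "y"))
  expect_equal(unname(crosstab(r, c2)$table), rbind(c(2, 0), c(0, 2)))
  # empty input
  e <- crosstab(factor(character(), levels = "a"),
                factor(character(), levels = "x"))
  expect_equal(e$n, 0)
  # seeded random vectors vs a pair-counting oracle
  withr::with_seed(7, {
    rr <- sample(letters[1:3], 200, TRUE)
    cc <- sample(LETTERS[1:4], 200, TRUE)
  })
  tab <- crosstab(rr, cc)$table
  for (i in letters[1:3]) for (j in LETTERS[1:4]) {
    expect_equal(tab[i, j], sum(rr == i & cc == j))
  }
  expect_error(crosstab(1:3, 1:4), "equal length")
})

test_that("Cramer's V has its closed-form extremes and phi equivalence", {
  expect_equal(cramers_v(diag(c(5, 5)))$cramers_v, 1)
  indep <- outer(c(10, 10), c(10, 10)) / 20
  expect_equal(cramers_v(indep)$cramers_v, 0)
  # 2x2: V equals |phi| computed from the determinant formula
  tab <- rbind(c(20, 12), c(7, 30))
  phi <- abs(det(tab)) / sqrt(prod(rowSums(tab)) * prod(colSums(tab)))
  expect_equal(cramers_v(tab)$cramers_v, phi)
  # invariance to scaling all cells by a positive integer
  expect_equal(cramers_v(5 * tab)$cramers_v, cramers_v(tab)$cramers_v)
})

test_that("degenerate tables are handled explicitly", {
  tab <- rbind(c(3, 0, 2), c(1, 0, 4), c(0, 0, 0))
  expect_message(res <- cramers_v(tab), "dropping")
  expect_equal(dim(res$table), c(2L, 2L))
  expect_error(cramers_v(rbind(c(1, 2))), "at least 2")
  expect_error(cramers_v(matrix(-1, 2, 2)), "non-negative")
})

test_that("strength labels follow the half-open guideline bands", {
  expect_equal(rea_parker_label(c(0, 0.0999, 0.1, 0.1999, 0.2, 0.3999, 0.4, 0.8)),
               c("very weak", "very weak", "weak", "weak", "moderate",
                 "moderate", "strong", "strong"))
})

test_that("the packaged counts reproduce the published association statistics", {
  counts <- nhanes_bp_counts()
  expect_equal(nrow(counts), 46)
  stats <- assoc_from_counts(counts)
  got <- stats[stats$response == "SBP" & stats$factor == "Gender", ]
  expect_equal(round(got$cramers_v, 4), 0.1310)
  expect_equal(got$label, "weak")
  expect_equal(got$n, 4609)
  got2 <- stats[stats$response == "SBP" & stats$factor == "Age", ]
  expect_equal(round(got2$cramers_v, 4), 0.2535)
  expect_equal(got2$label, "moderate")
})

test_that("row percentages round to two decimals", {
  counts <- nhanes_bp_counts()
  pct <- counts_row_pct(counts)
  over50 <- pct[pct$response == "SBP" & pct$level == ">=50 years", ]
  expect_equal(over50$pct_hypertension, 24.84)
})

test_that("microdata and counts modes agree through one statistics path", {
  withr::with_seed(12, {
    d <- tibble::tibble(SBP = runif(300, 90, 180),
                        Gender = sample(1:2, 300, TRUE))
  })
  rep <- assoc_report(d, "SBP", "sbp", list(Gender = "Gender"))
  tab <- crosstab(factor(d$Gender), categorize(d$SBP, "sbp"))
  direct <- cramers_v(tab)
  expect_equal(rep$stats$cramers_v, direct$cramers_v)
  expect_equal(sum(rep$rows$count), 300)
})
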