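#' Categorisation rules for blood-pressure study variables
#'
#' Clinical banding rules: systolic BP in mmHg (normal < 120,
#' pre-hypertension 120-139, hypertension >= 140), diastolic BP in mmHg
#' (< 80, 80-89, >= 90), BMI in kg/m^2 (underweight < 18.5, healthy
#' 18.5-24.9, overweight 25-29.9, obese 30-34.9, very obese 35-39.9,
#' morbidly obese 40 and over) and age bands in years (20-29, 30-39,
#' 40-49, 50 and over). Lower bounds are inclusive on the upper categories.
#'
#' @return Named list of rule sets, each with `breaks`, `labels` and a
#'   plausible `range`.
#' @export
bp_rules <- function() {
  list(
    sbp = list(breaks = c(120, 140),
               labels = c("Normal", "Pre-hypertension", "Hypertension"),
               range = c(50, 300)),
    dbp = list(breaks = c(80, 90),
               labels = c("Normal", "Pre-hypertension", "Hypertension"),
               range = c(20, 200)),
    bmi = list(breaks = c(18.5, 25, 30, 35, 40),
               labels = c("Underweight", "Healthy", "Overweight", "Obese",
                          "Very obese", "Morbidly obese"),
               range = c(8, 100)),
    age = list(breaks = c(30, 40, 50),
               labels = c("20-29 years", "30-39 years", "40-49 years",
                          ">=50 years"),
               range = c(18, 130))
  )
}

#' Categorise a study variable
#'
#' Applies one of the [bp_rules()] rule sets with half-open banding
#' (`[lower, upper)`, so an SBP of exactly 120 is pre-hypertension and a
#' BMI of exactly 40 is morbidly obese).
#'
#' @param x Numeric vector.
#' @param rule One of `"sbp"`, `"dbp"`, `"bmi"`, `"age"`, or a list with
#'   `breaks`, `labels` and `range` in the same shape.
#' @return Factor with the rule's labels.
#' @export
#' @examples
#' categorize(c(119, 120, 140), "sbp")
categorize <- function(x, rule) {
  if (is.character(rule)) {
    rules <- bp_rules()
    if (!rule %in% names(rules)) {
      stop("unknown rule '", rule, "'", call. = FALSE)
    }
    rule <- rules[[rule]]
  }
  bad <- which(!is.finite(x) | x < rule$range[1] | x > rule$range[2])
  if (length(bad) > 0L) {
    stop(sprintf("implausible value(s) outside [%g, %g]; row(s): %s",
                 rule$range[1], rule$range[2],
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  cut(x, breaks = c(-Inf, rule$breaks, Inf), labels = rule$labels,
      right = FALSE)
}

#' Cross-tabulate two categorical vectors
#'
#' Counts-only cross tabulation retaining declared-but-empty levels; the
#' statistics slots of the result are filled by [cramers_v()].
#'
#' @param rows,cols Vectors (factors or coercible) of equal length.
#' @return An object of class `quantfp_assoc` with the count matrix in
#'   `$table` and `$n` the total count.
#' @export
crosstab <- function(rows, cols) {
  if (length(rows) != length(cols)) {
    stop("'rows' and 'cols' must have equal length", call. = FALSE)
  }
  tab <- table(rows, cols)
  structure(list(table = unclass(tab), n = sum(tab),
                 chi2 = NA_real_, df = NA_integer_, p_value = NA_real_,
                 cramers_v = NA_real_, label = NA_character_),
            class = "quantfp_assoc")
}

#' Cramer's V association statistic with qualitative label
#'
#' Pearson chi-square (no continuity correction) on an r x c count table,
#' `V = sqrt(chi2 / (n min(r-1, c-1)))`, the chi-square p-value on
#' `(r-1)(c-1)` degrees of freedom, and the conventional strength label:
#' V in \[0, 0.10) very weak, \[0.10, 0.20) weak, \[0.20, 0.40) moderate,
#' and 0.40 or above strong. Rows or columns with zero margin are dropped
#' (with a message) before testing.
#'
#' @param x A count matrix, a `quantfp_assoc` object from [crosstab()], or
#'   a data frame of counts.
#' @return A `quantfp_assoc` object with `chi2`, `df`, `p_value`,
#'   `cramers_v` and `label` filled.
#' @export
#' @examples
#' cramers_v(rbind(c(999, 957, 352), c(1275, 684, 342)))  # V = 0.1310
cramers_v <- function(x) {
  if (inherits(x, "quantfp_assoc")) {
    tab <- x$table
  } else {
    tab <- as.matrix(x)
  }
  storage.mode(tab) <- "double"
  if (any(tab < 0) || anyNA(tab)) stop("counts must be non-negative", call. = FALSE)
  n <- sum(tab)
  if (n <= 0) stop("empty table", call. = FALSE)
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    message("dropping ", sum(zr), " zero row(s) and ", sum(zc),
            " zero column(s) before testing")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("need at least 2 non-empty rows and columns", call. = FALSE)
  }
  ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  v <- sqrt(unname(ch$statistic) / (n * (min(dim(tab)) - 1)))
  structure(list(table = tab, n = n,
                 chi2 = unname(ch$statistic), df = unname(ch$parameter),
                 p_value = ch$p.value, cramers_v = v,
                 label = rea_parker_label(v)),
            class = "quantfp_assoc")
}

#' Qualitative association-strength label for Cramer's V
#'
#' @param v Cramer's V value in \[0, 1\].
#' @return One of "very weak", "weak", "moderate", "strong".
#' @export
rea_parker_label <- function(v) {
  stopifnot(is.numeric(v), all(v >= 0))
  cut(v, breaks = c(-Inf, 0.10, 0.20, 0.40, Inf),
      labels = c("very weak", "weak", "moderate", "strong"),
      right = FALSE) |> as.character()
}

#' @export
print.quantfp_assoc <- function(x, ...) {
  print(x$table)
  if (!is.na(x$cramers_v)) {
    cat(sprintf("n = %d, chi2 = %.4f (df = %d), p = %.4g, V = %.4f (%s)\n",
                x$n, x$chi2, x$df, x$p_value, x$cramers_v, x$label))
  } else {
    cat(sprintf("n = %d (statistics not yet computed)\n", x$n))
  }
  invisible(x)
}

#' @export
tidy.quantfp_assoc <- function(x, ...) {
  tibble::tibble(n = x$n, chi2 = x$chi2, df = x$df, p_value = x$p_value,
                 cramers_v = x$cramers_v, label = x$label)
}

#' Descriptive association report for a blood-pressure table
#'
#' For each factor, cross-tabulates the categorised response against the
#' factor and reports counts, within-row percentages, and the chi-square /
#' Cramer's V summary - the standard "proportions by characteristics"
#' descriptive table.
#'
#' @param data Data frame with the response and factor columns.
#' @param response Response column name (continuous; categorised by `rule`).
#' @param rule Categorisation rule for the response (see [categorize()]).
#' @param factors Named list mapping display names to either a column name
#'   (used as-is) or `list(column =, rule =)` for continuous factors.
#' @return A list with `rows` (tibble of counts and row percentages) and
#'   `stats` (tibble of per-factor chi-square / V summaries).
#' @export
assoc_report <- function(data, response, rule, factors) {
  resp <- categorize(data[[response]], rule)
  rows <- list(); stats <- list()
  for (nm in names(factors)) {
    f <- factors[[nm]]
    fac <- if (is.list(f)) categorize(data[[f$column]], f$rule) else
      as.factor(data[[f]])
    tab <- crosstab(fac, resp)
    counts <- tab$table
    pct <- 100 * counts / pmax(rowSums(counts), 1)
    rows[[nm]] <- tibble::tibble(
      factor = nm,
      level = rep(rownames(counts), times = ncol(counts)),
      response = rep(colnames(counts), each = nrow(counts)),
      count = as.vector(counts),
      row_pct = round(as.vector(pct), 2)
    )
    st <- tryCatch(cramers_v(tab), error = function(e) NULL)
    stats[[nm]] <- if (is.null(st)) {
      tibble::tibble(factor = nm, n = tab$n, chi2 = NA_real_, df = NA_integer_,
                     p_value = NA_real_, cramers_v = NA_real_,
                     label = NA_character_)
    } else {
      dplyr::bind_cols(tibble::tibble(factor = nm), tidy(st))
    }
  }
  list(rows = dplyr::bind_rows(rows), stats = dplyr::bind_rows(stats))
}

#' Printed contingency counts from the blood-pressure study
#'
#' Loads the packaged counts file: one row per (response, factor, level)
#' with the three response-category counts. These are the published
#' cross-tabulations of categorised SBP/DBP against BMI class, age band,
#' ethnicity, gender and marital status for the 2007-2008 NHANES analysis
#' sample (n = 4609), usable directly in counts-entry mode without any
#' microdata.
#'
#' @return A tibble with columns `response`, `factor`, `level`, `normal`,
#'   `pre_hypertension`, `hypertension`.
#' @export
nhanes_bp_counts <- function() {
  path <- system.file("extdata", "nhanes0708_bp_counts.csv",
                      package = "quantfp", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    response = readr::col_character(),
                    factor = readr::col_character(),
                    level = readr::col_character(),
                    normal = readr::col_integer(),
                    pre_hypertension = readr::col_integer(),
                    hypertension = readr::col_integer()))
}

#' Association statistics from a counts table
#'
#' Counts-entry analogue of [assoc_report()]: computes the chi-square,
#' p-value, Cramer's V and strength label for every (response, factor)
#' block of a counts tibble shaped like [nhanes_bp_counts()], through the
#' identical statistics path as the microdata route.
#'
#' @param counts Tibble with columns `response`, `factor`, `level` and one
#'   column per response category.
#' @return Tibble with one row per (response, factor) and the statistics,
#'   plus `row_pct` nested per level via [counts_row_pct()] if needed.
#' @export
assoc_from_counts <- function(counts) {
  catcols <- setdiff(names(counts), c("response", "factor", "level"))
  counts |>
    dplyr::group_by(.data$response, .data$factor) |>
    dplyr::group_modify(function(d, key) {
      tab <- as.matrix(d[, catcols])
      rownames(tab) <- d$level
      tidy(cramers_v(tab))
    }) |>
    dplyr::ungroup()
}

#' Row percentages from a counts table
#'
#' @inheritParams assoc_from_counts
#' @return The input with each count column accompanied by a `pct_` column
#'   of within-row percentages (two decimals).
#' @export
counts_row_pct <- function(counts) {
  catcols <- setdiff(names(counts), c("response", "factor", "level"))
  tot <- rowSums(counts[, catcols])
  out <- counts
  for (cc in catcols) {
    out[[paste0("pct_", cc)]] <- round(100 * counts[[cc]] / tot, 2)
  }
  out
}
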