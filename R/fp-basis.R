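#' Canonical fractional-polynomial power set
#'
#' The restricted set of exponents \{-2, -1, -1/2, 0, 1/2, 1, 2, 3\}
#' conventionally used for fractional polynomials of degree up to three.
#' It contains the classical polynomial powers 1, 2, 3 together with
#' reciprocal and square-root transforms; 0 denotes the natural logarithm.
#'
#' @return Numeric vector of the eight canonical powers, sorted.
#' @export
#' @examples
#' fp_power_set()
fp_power_set <- function() {
  c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
}

#' Box-Tidwell power transformation
#'
#' `x^a` for `a != 0` and `log(x)` for `a == 0`. Defined only for strictly
#' positive `x`.
#'
#' @param x Strictly positive numeric vector.
#' @param a Single real exponent.
#' @param .name Optional predictor name used in error messages.
#' @return Numeric vector, same length as `x`.
#' @export
#' @examples
#' box_tidwell(4, 0.5)   # 2
#' box_tidwell(1, 0)     # 0
#' box_tidwell(2, -1)    # 0.5
box_tidwell <- function(x, a, .name = deparse(substitute(x))) {
  stopifnot(is.numeric(x), length(a) == 1L, is.finite(a))
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad) > 0L) {
    stop(sprintf(
      "power transform of '%s' requires strictly positive values; offending row(s): %s",
      .name, paste(utils::head(bad, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  if (a == 0) log(x) else x^a
}

#' Fractional-polynomial term matrix for one predictor
#'
#' Builds the degree-`m` FP basis for a positive predictor from a sorted
#' power vector `p_1 <= ... <= p_m`. Column `j` is the Box-Tidwell transform
#' `x^(p_j)` when `p_j != p_{j-1}`; a repeated power multiplies the previous
#' column by `log(x)`, so e.g. powers `(2, 2)` give `x^2` and `x^2 log(x)`.
#'
#' @param x Strictly positive numeric vector of length n.
#' @param powers Sorted numeric vector of powers (possibly with repeats).
#'   A zero-length vector yields a zero-column matrix (predictor omitted).
#' @param .name Predictor name used for column labels and errors.
#' @return An n x m numeric matrix with descriptive column names.
#' @export
#' @examples
#' fp_terms(exp(1), c(-0.5, 2, 2))
#' fp_terms(1:5, c(1, 2, 3))   # classical cubic basis
fp_terms <- function(x, powers, .name = "x") {
  stopifnot(is.numeric(powers))
  if (is.unsorted(powers)) {
    stop("'powers' must be sorted in non-decreasing order", call. = FALSE)
  }
  m <- length(powers)
  out <- matrix(numeric(0), nrow = length(x), ncol = 0L)
  if (m == 0L) return(out)
  labels <- character(m)
  cols <- vector("list", m)
  logx <- NULL
  for (j in seq_len(m)) {
    repeated <- j > 1L && powers[j] == powers[j - 1L]
    if (repeated) {
      if (is.null(logx)) logx <- box_tidwell(x, 0, .name = .name)
      cols[[j]] <- cols[[j - 1L]] * logx
      labels[j] <- paste0(labels[j - 1L], "*log(", .name, ")")
    } else {
      cols[[j]] <- box_tidwell(x, powers[j], .name = .name)
      labels[j] <- fp_label(.name, powers[j])
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- labels
  out
}

fp_label <- function(name, p) {
  if (p == 0) return(paste0("log(", name, ")"))
  if (p == 1) return(name)
  paste0(name, "^", format(p, trim = TRUE))
}

#' Specify a multiple fractional-polynomial design
#'
#' Describes how a design matrix is assembled from raw predictors: one
#' (possibly empty) power vector per continuous predictor, categorical
#' predictors passed through as their integer codes, and an optional
#' intercept. A continuous predictor with an empty power vector is omitted.
#'
#' Categorical predictors enter as single integer-coded columns (one
#' coefficient per factor) by default; set `dummy = TRUE` to expand each
#' into treatment-contrast indicator columns instead.
#'
#' @param continuous Named list of sorted power vectors, one per continuous
#'   predictor, e.g. `list(BMI = c(0.5, 1), Age = c(0.5, 1))`.
#' @param categorical Character vector of categorical predictor columns.
#' @param intercept Logical; include a column of ones (default `FALSE`,
#'   matching the blood-pressure model form which carries no intercept).
#' @param dummy Logical; expand categorical predictors into indicator
#'   columns (default `FALSE`: integer codes as provided).
#' @return An object of class `fp_spec`.
#' @export
#' @examples
#' fp_spec(list(BMI = c(0.5, 1), Age = c(0.5, 1)),
#'         categorical = c("Ethnicity", "Gender", "MaritalStatus"))
fp_spec <- function(continuous = list(), categorical = character(),
                    intercept = FALSE, dummy = FALSE) {
  stopifnot(is.list(continuous), is.character(categorical),
            is.logical(intercept), is.logical(dummy))
  if (length(continuous) > 0L && is.null(names(continuous))) {
    stop("'continuous' must be a named list of power vectors", call. = FALSE)
  }
  for (nm in names(continuous)) {
    p <- continuous[[nm]]
    if (!is.numeric(p)) stop("power vector for '", nm, "' must be numeric", call. = FALSE)
    if (is.unsorted(p)) stop("power vector for '", nm, "' must be sorted", call. = FALSE)
  }
  structure(
    list(continuous = continuous, categorical = categorical,
         intercept = isTRUE(intercept), dummy = isTRUE(dummy)),
    class = "fp_spec"
  )
}

#' @export
print.fp_spec <- function(x, ...) {
  cat("Fractional-polynomial design specification\n")
  for (nm in names(x$continuous)) {
    p <- x$continuous[[nm]]
    cat(sprintf("  %s: powers (%s)%s\n", nm,
                paste(p, collapse = ", "),
                if (length(p) == 0L) " [omitted]" else ""))
  }
  if (length(x$categorical)) {
    cat("  categorical:", paste(x$categorical, collapse = ", "),
        if (x$dummy) "(dummy-coded)\n" else "(integer-coded)\n")
  }
  cat("  intercept:", x$intercept, "\n")
  invisible(x)
}

#' Build the multiple-FP design matrix
#'
#' Assembles the n x D design matrix B: FP terms for each continuous
#' predictor in specification order, then categorical columns, then an
#' optional intercept column of ones. Column order is deterministic given
#' the specification. Predictors with an empty power vector are silently
#' omitted.
#'
#' @param data Data frame containing all referenced columns. Continuous
#'   predictors must be strictly positive; categorical predictors must be
#'   numeric-coded (or factors, which are converted to their integer codes).
#' @param spec An [fp_spec()] object.
#' @return An object of class `fp_design`: a list with elements `B` (the
#'   labelled numeric matrix), `labels` (a tibble mapping each column to its
#'   predictor and power) and `spec`.
#' @export
#' @examples
#' d <- data.frame(BMI = c(22, 31, 27), Age = c(25, 60, 44),
#'                 Gender = c(1, 2, 1))
#' build_fp_design(d, fp_spec(list(BMI = c(0.5, 1)), categorical = "Gender"))
build_fp_design <- function(data, spec) {
  stopifnot(inherits(spec, "fp_spec"), is.data.frame(data))
  needed <- c(names(spec$continuous), spec$categorical)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(data)
  blocks <- list()
  lab <- list()
  for (nm in names(spec$continuous)) {
    p <- spec$continuous[[nm]]
    if (length(p) == 0L) next
    blk <- fp_terms(data[[nm]], p, .name = nm)
    blocks[[length(blocks) + 1L]] <- blk
    lab[[length(lab) + 1L]] <- tibble::tibble(
      column = colnames(blk), predictor = nm, power = p
    )
  }
  for (nm in spec$categorical) {
    v <- data[[nm]]
    if (is.factor(v)) v <- as.numeric(v)
    if (!is.numeric(v)) {
      stop("categorical column '", nm, "' must be numeric-coded or a factor",
           call. = FALSE)
    }
    if (spec$dummy) {
      lev <- sort(unique(v))
      if (length(lev) > 1L) {
        blk <- vapply(lev[-1L], function(l) as.numeric(v == l), numeric(n))
        colnames(blk) <- paste0(nm, lev[-1L])
      } else {
        blk <- matrix(numeric(0), nrow = n, ncol = 0L)
      }
    } else {
      blk <- matrix(v, ncol = 1L, dimnames = list(NULL, nm))
    }
    if (ncol(blk) > 0L) {
      blocks[[length(blocks) + 1L]] <- blk
      lab[[length(lab) + 1L]] <- tibble::tibble(
        column = colnames(blk), predictor = nm, power = NA_real_
      )
    }
  }
  if (spec$intercept) {
    blocks[[length(blocks) + 1L]] <- matrix(1, nrow = n, ncol = 1L,
                                            dimnames = list(NULL, "(Intercept)"))
    lab[[length(lab) + 1L]] <- tibble::tibble(
      column = "(Intercept)", predictor = "(Intercept)", power = NA_real_
    )
  }
  B <- if (length(blocks)) do.call(cbind, blocks) else
    matrix(numeric(0), nrow = n, ncol = 0L)
  if (anyNA(B) || any(!is.finite(B))) {
    stop("design matrix contains non-finite entries", call. = FALSE)
  }
  structure(
    list(B = B,
         labels = if (length(lab)) dplyr::bind_rows(lab) else
           tibble::tibble(column = character(), predictor = character(),
                          power = numeric()),
         spec = spec),
    class = "fp_design"
  )
}

#' @export
print.fp_design <- function(x, ...) {
  cat(sprintf("fp_design: %d rows x %d columns\n", nrow(x$B), ncol(x$B)))
  print(x$labels)
  invisible(x)
}

#' Extract the design matrix from inputs accepted by the fitters
#' @noRd
as_design_matrix <- function(B) {
  if (inherits(B, "fp_design")) return(B$B)
  if (is.data.frame(B)) return(as.matrix(B))
  stopifnot(is.matrix(B), is.numeric(B))
  B
}

#' Write a design matrix to CSV with labelled header
#'
#' @param design An `fp_design` object or numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  B <- as_design_matrix(design)
  readr::write_csv(tibble::as_tibble(B, .name_repair = "minimal"), path)
  invisible(path)
}
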