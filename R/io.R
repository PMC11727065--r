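#' Read an analysis configuration (YAML or JSON)
#'
#' The configuration binds a CSV input to column roles and run settings:
#'
#' * `input`: path to the subject-level CSV (header required), or
#'   `counts_input` for counts-entry descriptive runs;
#' * `response`: response column; `continuous`: named map of FP power
#'   vectors; `categorical`: vector of categorical columns;
#' * `tau`: quantile level(s), default `c(0.5, 0.75, 0.95)`;
#' * `method`: one of `qr_fp`, `bqr_fp`, `bqrvs_fp` (default);
#' * `g`, `R`, `burn_in`, `S`, `S_burn`, `threshold`, `seed`, `boot`;
#' * `filters`: optional character vector of row-filter expressions applied
#'   to the data before fitting (declarative exclusion rules, e.g.
#'   `"MaritalStatus > 0"`);
#' * `output`: output directory; `overwrite`: allow reuse of an existing
#'   run directory (default FALSE: a numeric suffix is appended).
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return A validated list of class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json", call. = FALSE)
  }
  as_analysis_config(cfg)
}

#' Coerce a list to a validated analysis configuration
#'
#' @param cfg Named list of configuration entries (see
#'   [read_analysis_config()] for the schema).
#' @return A list of class `analysis_config` with defaults filled in.
#' @export
as_analysis_config <- function(cfg) {
  defaults <- list(tau = c(0.5, 0.75, 0.95), method = "bqrvs_fp", g = 1000,
                   R = 5000, burn_in = 2500, S = 1250, S_burn = 500,
                   threshold = 0.9, boot = 999, overwrite = FALSE,
                   filters = character(), output = "quantfp_run",
                   categorical = character(), continuous = list())
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (!cfg$method %in% c("qr_fp", "bqr_fp", "bqrvs_fp")) {
    stop("unknown method '", cfg$method, "'", call. = FALSE)
  }
  for (tt in cfg$tau) check_tau(tt)
  if (cfg$method != "qr_fp" && is.null(cfg$seed)) {
    stop("a 'seed' is mandatory for Bayesian methods", call. = FALSE)
  }
  cfg$continuous <- lapply(cfg$continuous, as.numeric)
  structure(cfg, class = "analysis_config")
}

# resolve the run directory without silently overwriting
resolve_run_dir <- function(path, overwrite = FALSE) {
  if (dir.exists(path) && !overwrite) {
    k <- 1L
    while (dir.exists(sprintf("%s_%d", path, k))) k <- k + 1L
    path <- sprintf("%s_%d", path, k)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  path
}

read_input_csv <- function(cfg) {
  if (is.null(cfg$input)) stop("config lacks an 'input' CSV path", call. = FALSE)
  if (!file.exists(cfg$input)) {
    stop("input file not found: ", cfg$input, call. = FALSE)
  }
  data <- readr::read_csv(cfg$input, show_col_types = FALSE)
  need <- c(cfg$response, names(cfg$continuous), cfg$categorical)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stop("input is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (f in cfg$filters) {
    keep <- rlang::eval_tidy(rlang::parse_expr(f), data = data)
    if (!is.logical(keep)) stop("filter '", f, "' is not logical", call. = FALSE)
    data <- data[keep & !is.na(keep), ]
  }
  data
}

#' Run a configured model fit
#'
#' Reads the input CSV, applies the declared row filters, builds the FP
#' design, runs the configured method at each quantile level, and writes
#' draws, summaries, the resolved configuration and a log into the run
#' directory. Reruns never silently overwrite: a numeric suffix is added
#' unless `overwrite: true`.
#'
#' @param cfg An `analysis_config` (or path to one).
#' @return Invisibly, a named list of fitted objects (one per tau) with
#'   the run directory in attribute `"dir"`.
#' @export
run_analysis <- function(cfg) {
  if (is.character(cfg)) cfg <- read_analysis_config(cfg)
  stopifnot(inherits(cfg, "analysis_config"))
  data <- read_input_csv(cfg)
  spec <- fp_spec(cfg$continuous, categorical = cfg$categorical)
  design <- build_fp_design(data, spec)
  y <- data[[cfg$response]]
  dir <- resolve_run_dir(cfg$output, cfg$overwrite)
  log_path <- file.path(dir, "run.log")
  logline <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ..., "\n",
        file = log_path, append = TRUE, sep = "")
  }
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  fits <- list()
  for (tt in cfg$tau) {
    tag <- sprintf("tau%02.0f", 100 * tt)
    logline("fitting method=", cfg$method, " tau=", tt)
    fit <- switch(cfg$method,
      qr_fp = fit_qr_fp(y, design, tt, boot = cfg$boot, seed = cfg$seed),
      bqr_fp = fit_bqr_fp(y, design, tt, R = cfg$R, burn_in = cfg$burn_in,
                          seed = cfg$seed),
      bqrvs_fp = bqrvs_fit(y = y, B = design, tau = tt, g = cfg$g,
                           R = cfg$R, burn_in = cfg$burn_in, S = cfg$S,
                           S_burn = cfg$S_burn, threshold = cfg$threshold,
                           seed = cfg$seed)
    )
    readr::write_csv(tidy(fit), file.path(dir, paste0("summary_", tag, ".csv")))
    jsonlite::write_json(glance(fit), file.path(dir, paste0("glance_", tag, ".json")),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(fit$gibbs)) {
      readr::write_csv(fit$gibbs$draws, file.path(dir, paste0("draws_", tag, ".csv")))
      jsonlite::write_json(
        fit$selection$mip, file.path(dir, paste0("inclusion_", tag, ".json")),
        auto_unbox = TRUE, digits = NA)
    } else if (!is.null(fit$draws)) {
      readr::write_csv(fit$draws, file.path(dir, paste0("draws_", tag, ".csv")))
    }
    fits[[tag]] <- fit
  }
  if (cfg$method == "bqrvs_fp") {
    mt <- do.call(mip_table, stats::setNames(
      lapply(fits, function(f) f$selection), names(fits)))
    readr::write_csv(mt, file.path(dir, "mip_table.csv"))
  }
  logline("done")
  attr(fits, "dir") <- dir
  invisible(fits)
}

#' Run a configured descriptive analysis
#'
#' Microdata mode (config `input` + `response`/`rule`/`factors`) or
#' counts-entry mode (config `counts_input` pointing at a counts CSV shaped
#' like [nhanes_bp_counts()]); both feed the identical statistics path.
#'
#' @param cfg An `analysis_config`-style list or path (fields: either
#'   `counts_input`, or `input` plus `describe` with `response`, `rule`
#'   and `factors`).
#' @return A list with `stats` (and `rows` in microdata mode); written to
#'   the output directory as CSV.
#' @export
run_descriptive <- function(cfg) {
  if (is.character(cfg)) cfg <- read_analysis_config(cfg)
  dir <- resolve_run_dir(cfg$output, isTRUE(cfg$overwrite))
  if (!is.null(cfg$counts_input)) {
    counts <- readr::read_csv(cfg$counts_input, show_col_types = FALSE)
    out <- list(stats = assoc_from_counts(counts),
                rows = counts_row_pct(counts))
  } else {
    data <- read_input_csv(cfg)
    d <- cfg$describe
    out <- assoc_report(data, d$response, d$rule, d$factors)
  }
  readr::write_csv(out$stats, file.path(dir, "association_stats.csv"))
  readr::write_csv(out$rows, file.path(dir, "category_rows.csv"))
  attr(out, "dir") <- dir
  invisible(out)
}

#' Run a configured simulation
#'
#' @param cfg List or config path with a `simulate` block of [sim_config()]
#'   fields plus `output`.
#' @return The simulated tibble, invisibly; CSV + truth JSON written.
#' @export
run_simulation <- function(cfg) {
  if (is.character(cfg)) cfg <- read_analysis_config(cfg)
  sc <- do.call(sim_config, cfg$simulate %||% list())
  data <- simulate_bp(sc)
  dir <- resolve_run_dir(cfg$output, isTRUE(cfg$overwrite))
  write_simulation(data, file.path(dir, "synthetic_bp.csv"))
  attr(data, "dir") <- dir
  invisible(data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
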