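#' Trace, density and autocorrelation panels for a sampler run
#'
#' The conventional three-column convergence display: trace plot, posterior
#' density and autocorrelation per parameter chain.
#'
#' @param x A `quantfp_gibbs` or `quantfp_bqr` object.
#' @param pars Parameters to display (default: all coefficients and sigma).
#' @param max_lag Autocorrelation lag window.
#' @return A ggplot object (facetted).
#' @export
plot_chain_diagnostics <- function(x, pars = NULL, max_lag = 30) {
  if (is.null(pars)) pars <- c(x$term, "sigma")
  long <- x$draws |>
    dplyr::select(dplyr::all_of(c("iteration", pars))) |>
    tidyr::pivot_longer(-"iteration", names_to = "term", values_to = "value")
  acfs <- purrr::map_dfr(pars, function(nm) {
    dplyr::mutate(chain_acf(x$draws[[nm]], max_lag), term = nm)
  })
  trace <- long |>
    dplyr::mutate(panel = "trace", xvar = .data$iteration, yvar = .data$value)
  dens <- long |>
    dplyr::mutate(panel = "density", xvar = .data$value, yvar = NA_real_)
  acfp <- acfs |>
    dplyr::mutate(panel = "autocorrelation", xvar = .data$lag,
                  yvar = .data$acf)
  ggplot2::ggplot() +
    ggplot2::geom_line(data = trace,
                       ggplot2::aes(x = .data$xvar, y = .data$yvar),
                       linewidth = 0.2) +
    ggplot2::geom_density(data = dens, ggplot2::aes(x = .data$xvar)) +
    ggplot2::geom_col(data = acfp,
                      ggplot2::aes(x = .data$xvar, y = .data$yvar),
                      width = 0.2) +
    ggplot2::facet_grid(term ~ panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.quantfp_gibbs <- function(object, ...) {
  plot_chain_diagnostics(object, ...)
}

#' @export
autoplot.quantfp_bqr <- function(object, ...) {
  plot_chain_diagnostics(object, ...)
}

#' @export
autoplot.quantfp_selection <- function(object, ...) {
  ggplot2::ggplot(object$mip,
                  ggplot2::aes(x = stats::reorder(.data$term, .data$mip),
                               y = .data$mip, fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "marginal inclusion probability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.quantfp_qr <- function(object, ...) {
  ggplot2::ggplot(object$coef,
                  ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2) +
    ggplot2::labs(x = "estimate", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
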