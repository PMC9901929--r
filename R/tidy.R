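#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a refinement's parameter estimates
#'
#' @param x A `taam_refinement`.
#' @param ... Unused.
#' @return Tibble with `atom`, `name` (parameter), `value` and `esd`.
#' @export
tidy.taam_refinement <- function(x, ...) {
  tibble::as_tibble(x$params[, c("atom", "name", "value", "esd")])
}

#' One-row refinement summary
#'
#' @param x A `taam_refinement`.
#' @param ... Unused.
#' @return One-row tibble: R factors (percent), GooF, peak/hole when
#'   available, scale, cycle count and convergence flag.
#' @export
glance.taam_refinement <- function(x, ...) {
  tibble::tibble(
    r1_gt = x$stats$r1_gt, r1_all = x$stats$r1_all,
    wr2_gt = x$stats$wr2_gt, wr2_all = x$stats$wr2_all,
    goof = x$goof, n_gt = x$stats$n_gt, n_all = x$stats$n_all,
    scale = x$scale, n_outer = x$n_outer, converged = x$converged
  )
}

#' Tidy a fractal-dimension curve
#'
#' @param x A `fractal_curve`.
#' @param ... Unused.
#' @return The underlying tibble (`rho0`, `df`).
#' @export
tidy.fractal_curve <- function(x, ...) tibble::as_tibble(x)

#' @rdname plot_fractal
#' @param object A `fractal_curve`.
#' @param ... Unused.
#' @export
autoplot.fractal_curve <- function(object, ...) plot_fractal(object)

#' Fractal-dimension plot
#'
#' The standard residual-density diagnostic: \eqn{d^f} against the
#' iso-level \eqn{\rho_0}. A narrow parabola peaking near zero indicates
#' featureless Gaussian noise; shoulders or displaced maxima indicate
#' model bias.
#'
#' @param curve A `fractal_curve` from [fractal_dimension()].
#' @return A ggplot object.
#' @export
plot_fractal <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$rho0, y = .data$df)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = expression(rho[0] ~ (e ~ ring(A)^-3)),
                  y = expression(d^f)) +
    ggplot2::theme_minimal()
}

#' Residual-map section plot
#'
#' Heat map of one grid section of a residual density map.
#'
#' @param map A [difference_map()] result.
#' @param section Index of the section along `axis` (default: the section
#'   containing the map maximum).
#' @param axis Sectioning axis (1, 2 or 3).
#' @return A ggplot object.
#' @export
plot_map_section <- function(map, section = NULL, axis = 3L) {
  if (is.null(section)) {
    section <- arrayInd(which.max(map$values), map$dim)[axis]
  }
  idx <- switch(axis,
                `1` = map$values[section, , ],
                `2` = map$values[, section, ],
                `3` = map$values[, , section])
  df <- expand.grid(i = seq_len(nrow(idx)), j = seq_len(ncol(idx)))
  df$rho <- as.vector(idx)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$rho)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = expression(Delta * rho), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Refinement cycle diagnostics plot
#'
#' @param object A `taam_refinement`.
#' @param ... Unused.
#' @return A ggplot of per-cycle R1 (percent).
#' @export
autoplot.taam_refinement <- function(object, ...) {
  log <- object$cycle_log
  log$cycle <- seq_len(nrow(log))
  ggplot2::ggplot(log, ggplot2::aes(x = .data$cycle, y = 100 * .data$r1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$outer))) +
    ggplot2::labs(x = "least-squares cycle", y = "R1 (%)",
                  shape = "outer cycle") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
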