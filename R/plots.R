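#' Plot methods
#'
#' `autoplot()` methods for the package's result types, built on ggplot2:
#' \describe{
#'   \item{`torsion_series`}{per-frame torsion traces, one facet per
#'     torsion, the y axis fixed to (-180, 180].}
#'   \item{`basin_summary`}{circular histogram support intervals with basin
#'     centers and occupancies.}
#'   \item{`boltzmann_table`}{equilibrium percentages per conformer.}
#'   \item{`fit_result`}{offset-corrected MM energy against QM energy with
#'     the identity line; a well-fitted torsion set falls on the line.}
#' }
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @name boronfit-autoplot
NULL

#' @rdname boronfit-autoplot
#' @method autoplot torsion_series
#' @export
autoplot.torsion_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$angle)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$torsion)) +
    ggplot2::scale_y_continuous(limits = c(-180, 180), breaks = seq(-180, 180, 60)) +
    ggplot2::labs(x = "frame", y = "torsion angle (deg)") +
    ggplot2::theme_bw()
}

#' @rdname boronfit-autoplot
#' @method autoplot basin_summary
#' @export
autoplot.basin_summary <- function(object, ...) {
  has_t <- "torsion" %in% names(object)
  p <- ggplot2::ggplot(object) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$support_lo, xend = .data$support_hi,
                                       y = .data$occupancy, yend = .data$occupancy),
                          linewidth = 2, alpha = 0.4) +
    ggplot2::geom_point(ggplot2::aes(x = .data$center, y = .data$occupancy),
                        size = 2, colour = "firebrick") +
    ggplot2::scale_x_continuous(limits = c(-180, 180), breaks = seq(-180, 180, 60)) +
    ggplot2::labs(x = "torsion angle (deg)", y = "basin occupancy") +
    ggplot2::theme_bw()
  if (has_t) p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$torsion))
  p
}

#' @rdname boronfit-autoplot
#' @method autoplot boltzmann_table
#' @export
autoplot.boltzmann_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "conformer",
                  y = sprintf("equilibrium population at %s K (%%)",
                              attr(object, "temperature"))) +
    ggplot2::theme_bw()
}

#' @rdname boronfit-autoplot
#' @method autoplot fit_result
#' @export
autoplot.fit_result <- function(object, ...) {
  df <- object$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$e_qm, y = .data$e_mm + object$K)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "QM energy (kcal/mol)", y = "MM energy + K (kcal/mol)",
                  subtitle = sprintf("K = %.3f kcal/mol, R² = %.4f", object$K, object$r2)) +
    ggplot2::theme_bw()
}
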