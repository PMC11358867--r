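# Standard shape-space plots: the PMI triangle and exit-vector scatter
# plots, optionally Boltzmann population-weighted.

utils::globalVariables(c("x", "y", "s", "NPR1", "NPR2", "weight", "locants",
                         "theta_plot", "r", "phi1", "phi2"))

#' PMI triangle plot
#'
#' Normalised PMI ratios on the standard triangular plot with rod (0, 1),
#' disc (0.5, 0.5) and sphere (1, 1) vertices, and guide lines of constant
#' NPR1 + NPR2 at 0.1 increments.  When the table carries a `weight`
#' column (see [weighted_descriptor_table()]) point sizes are scaled by
#' population.
#'
#' @param table A data frame from [pmi_table()] (optionally weighted).
#' @param label Label points with their locants.
#' @return A ggplot object.
#' @export
plot_pmi <- function(table, label = FALSE) {
  tri <- data.frame(x = c(0, 0.5, 1, 0), y = c(1, 0.5, 1, 1))
  iso <- do.call(rbind, lapply(seq(1.1, 1.9, by = 0.1), function(s) {
    # segment of NPR1 + NPR2 = s clipped to the triangle: from the
    # disc-sphere edge (y = x) to the rod-sphere edge (y = 1)
    data.frame(s = s, x = c(s / 2, s - 1), y = c(s / 2, 1))
  }))
  p <- ggplot2::ggplot(table, ggplot2::aes(x = NPR1, y = NPR2)) +
    ggplot2::geom_path(data = tri, ggplot2::aes(x = x, y = y),
                       inherit.aes = FALSE, colour = "grey30") +
    ggplot2::geom_line(data = iso,
                       ggplot2::aes(x = x, y = y,
                                    group = s),
                       inherit.aes = FALSE, colour = "grey85",
                       linewidth = 0.3) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0.5, 1)) +
    ggplot2::labs(x = "NPR1 (I1/I3)", y = "NPR2 (I2/I3)") +
    ggplot2::theme_minimal()
  if ("weight" %in% names(table)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(size = weight),
                                 alpha = 0.7) +
      ggplot2::scale_size_area(max_size = 8)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  if (label)
    p <- p + ggplot2::geom_text(ggplot2::aes(label = locants),
                                vjust = -0.8, size = 2.7)
  p
}

#' Exit-vector scatter plot (r against theta)
#'
#' @param table A data frame from [ev_table()] (optionally weighted).
#' @param theta_range x-axis limits in degrees (default c(-90, 90); use
#'   c(0, 180) with `absolute = TRUE` for the unsigned convention).
#' @param absolute Plot |theta| instead of the signed dihedral.
#' @return A ggplot object.
#' @export
plot_ev <- function(table, theta_range = c(-90, 90), absolute = FALSE) {
  table$theta_plot <- if (absolute) abs(table$theta) else table$theta
  p <- ggplot2::ggplot(table, ggplot2::aes(x = theta_plot,
                                           y = r)) +
    ggplot2::coord_cartesian(xlim = theta_range) +
    ggplot2::labs(x = if (absolute) "|theta| (deg)" else "theta (deg)",
                  y = "r (A)") +
    ggplot2::theme_minimal()
  if ("weight" %in% names(table)) {
    p + ggplot2::geom_point(ggplot2::aes(size = weight), alpha = 0.7) +
      ggplot2::scale_size_area(max_size = 8)
  } else {
    p + ggplot2::geom_point(alpha = 0.7)
  }
}

#' Plane-angle plot (phi1 against phi2)
#'
#' @param table A data frame from [ev_table()] (optionally weighted).
#' @return A ggplot object.
#' @export
plot_ev_phi <- function(table) {
  p <- ggplot2::ggplot(table, ggplot2::aes(x = phi1, y = phi2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "phi1 (deg)", y = "phi2 (deg)") +
    ggplot2::theme_minimal()
  if ("weight" %in% names(table)) {
    p + ggplot2::geom_point(ggplot2::aes(size = weight), alpha = 0.7) +
      ggplot2::scale_size_area(max_size = 8)
  } else {
    p + ggplot2::geom_point(alpha = 0.7)
  }
}
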