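#' Plot a switch distance series
#'
#' Distance vs time with the classification threshold drawn as a dashed
#' line (omitted for unclassified reporter distances).
#'
#' @param object a `switch_series` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.switch_series <- function(object, ...) {
  def <- attr(object, "definition")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$time_ps, y = .data$distance_A)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::facet_wrap(~switch, scales = "free_y") +
    ggplot2::labs(x = "time (ps)", y = "distance (Å)") +
    ggplot2::theme_minimal()
  if (!is.null(def) && !is.na(def$threshold_A)) {
    p <- p + ggplot2::geom_hline(yintercept = def$threshold_A,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot a helix rotation series
#' @param object a `rotation_series` tibble.
#' @param ... unused.
#' @export
autoplot.rotation_series <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time_ps, y = .data$angle_deg)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "steelblue4") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time (ps)", y = "rotation (°)",
                  title = paste("helix span", object$span[1])) +
    ggplot2::theme_minimal()
}

#' Plot a 2D free-energy surface
#'
#' Filled raster of the surface with contour lines, the standard
#' presentation of a metadynamics free-energy map.
#'
#' @param object an `fes_grid`.
#' @param contour_by contour spacing (kcal/mol).
#' @param threshold_A optional activation threshold to draw on both axes.
#' @param ... unused.
#' @export
autoplot.fes_grid <- function(object, contour_by = 0.5, threshold_A = NULL,
                              ...) {
  td <- tidy(object)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$cv1, y = .data$cv2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$free_energy)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$free_energy),
                          binwidth = contour_by, colour = "white",
                          linewidth = 0.2) +
    ggplot2::scale_fill_viridis_c(name = "F (kcal/mol)") +
    ggplot2::labs(x = "d1 (Å)", y = "d2 (Å)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (!is.null(threshold_A)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold_A,
                                 linetype = "dashed", colour = "grey80") +
      ggplot2::geom_hline(yintercept = threshold_A, linetype = "dashed",
                          colour = "grey80")
  }
  p
}

#' Plot a ligand contact-frequency table
#' @param object a `contact_table`.
#' @param ... unused.
#' @export
autoplot.contact_table <- function(object, ...) {
  lab <- ifelse(is.na(object$bw),
                paste0(object$resname, object$resseq),
                paste0(object$resname, object$resseq, " (", object$bw, ")"))
  df <- mutate(object, residue = factor(lab, levels = rev(lab)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$residue)) +
    ggplot2::geom_col(fill = "goldenrod3") +
    ggplot2::labs(x = paste0("contact frequency (cutoff ",
                             attr(object, "cutoff_A"), " Å)"),
                  y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a mid-plane slice of a water-occupancy grid
#'
#' @param object an `occupancy_grid`.
#' @param normalization passed to [grid_values()].
#' @param z_index slice index (default: middle of the grid).
#' @param ... unused.
#' @export
autoplot.occupancy_grid <- function(object,
                                    normalization = "bulk_relative",
                                    z_index = NULL, ...) {
  vals <- grid_values(object, normalization)
  if (is.null(z_index)) z_index <- ceiling(object$dims[3] / 2)
  sl <- vals[, , z_index]
  df <- tibble(
    x = object$origin[1] +
      (rep(seq_len(object$dims[1]), times = object$dims[2]) - 0.5) *
      object$spacing_A,
    y = object$origin[2] +
      (rep(seq_len(object$dims[2]), each = object$dims[1]) - 0.5) *
      object$spacing_A,
    occupancy = as.vector(sl))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$occupancy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = normalization) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)") +
    ggplot2::theme_minimal()
}
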