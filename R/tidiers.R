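#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
glance.laplace_field <- function(x, ...) {
  tibble::tibble(n_unknowns = x$n_unknowns, residual = x$residual,
                 n_undefined = x$n_undefined,
                 u_min = min(x$u, na.rm = TRUE),
                 u_max = max(x$u, na.rm = TRUE))
}

#' @export
tidy.substrate_result <- function(x, ...) x$summary

#' @export
glance.substrate_result <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$endo_map),
    n_vertices = nrow(x$mesh$vertices),
    n_points = nrow(x$points),
    n_assigned = sum(!is.na(x$points$node_id)),
    landmark_rms_mm = x$registration$landmark$rms_mm,
    icp_rms_mm = x$registration$icp$rms_mm,
    laplace_residual = x$field$residual)
}

# shared 2D projection: azimuth (around z) vs z, a cheap unrolling of a
# ventricular surface for plotting
.project_az <- function(xyz) {
  tibble::tibble(azimuth_deg = atan2(xyz[, 2], xyz[, 1]) * 180 / pi,
                 z_mm = xyz[, 3])
}

#' Plot an endocardial map metric
#'
#' Unrolls the endocardial nodes into azimuth (about the z axis) against
#' z and colours them by the chosen metric.
#'
#' @param object An [endocardial_map()] tibble.
#' @param metric Column name to colour by (default `"thickness_mm"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.endocardial_map <- function(object, metric = "thickness_mm", ...) {
  pr <- .project_az(as.matrix(object[, c("x", "y", "z")]))
  pr$value <- object[[metric]]
  ggplot2::ggplot(pr, ggplot2::aes(.data$azimuth_deg, .data$z_mm,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c(name = metric) +
    ggplot2::labs(x = "azimuth (deg)", y = "z (mm)",
                  title = "Endocardial map") +
    ggplot2::theme_minimal()
}

#' Plot mapped electroanatomic points over the endocardial surface
#'
#' @param object A `mapped_points` tibble from [map_points_to_nodes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mapped_points <- function(object, ...) {
  pr <- .project_az(as.matrix(object[, c("x", "y", "z")]))
  pr$category <- object$category
  pr$assigned <- !is.na(object$node_id)
  ggplot2::ggplot(pr, ggplot2::aes(.data$azimuth_deg, .data$z_mm,
                                   colour = .data$category,
                                   shape = .data$assigned)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "azimuth (deg)", y = "z (mm)",
                  title = "Mapped points") +
    ggplot2::theme_minimal()
}

#' Plot an activation map and its detected block lines
#'
#' @param object Result of [detect_block_lines()].
#' @param points The activation point table that was analysed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_block_lines <- function(object, points, ...) {
  g <- ggplot2::ggplot(points, ggplot2::aes(.data$x, .data$y,
                                            colour = .data$time_ms)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(name = "LAT (ms)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("Conduction block: %.1f mm in %d region(s)",
                                  object$total_length_mm, object$n_regions)) +
    ggplot2::theme_minimal()
  for (ch in object$block_lines) {
    if (nrow(ch) >= 2L)
      g <- g + ggplot2::geom_path(
        data = data.frame(x = ch[, 1], y = ch[, 2]),
        ggplot2::aes(.data$x, .data$y), colour = "red", linewidth = 1,
        inherit.aes = FALSE)
  }
  g
}

#' @importFrom rlang .data
NULL
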