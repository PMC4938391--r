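#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a parcellation on a planar mesh
#'
#' Vertices colored by parcel label, placed at their (x, y) coordinates.
#' Intended for the synthetic grid patches; for folded surfaces export to
#' GIFTI and use a surface viewer.
#'
#' @param object a [parcellation()].
#' @param mesh the [surface_mesh()] the labels live on.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot parcellation
#' @export
autoplot.parcellation <- function(object, mesh, ...) {
  stopifnot(inherits(mesh, "surface_mesh"))
  df <- data.frame(x = mesh$vertices[, 1L], y = mesh$vertices[, 2L],
                   label = factor(object$labels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "parcel") +
    ggplot2::theme_minimal()
}

#' Plot one time frame of a field on a planar mesh
#'
#' @param field a [ts_field()].
#' @param mesh the [surface_mesh()].
#' @param tau time index to display.
#' @return a ggplot object with a diverging blue-white-red scale (the
#'   convention for signed BOLD intensity).
#' @export
plot_field_frame <- function(field, mesh, tau = 1L) {
  stopifnot(inherits(field, "ts_field"), inherits(mesh, "surface_mesh"))
  check_field_mesh(field, mesh)
  df <- data.frame(x = mesh$vertices[, 1L], y = mesh$vertices[, 2L],
                   value = field$data[, tau])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "BOLD") +
    ggplot2::theme_minimal()
}

#' Plot a cumulative boundary count map
#'
#' Triangles drawn at their centroid, shaded by how often they were
#' boundary triangles across parcellations.
#'
#' @param object a [cumulative_boundary_map()] result.
#' @param mesh the [surface_mesh()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot boundary_count_map
#' @export
autoplot.boundary_count_map <- function(object, mesh, ...) {
  stopifnot(inherits(mesh, "surface_mesh"))
  tri <- mesh$triangles
  cx <- rowMeans(matrix(mesh$vertices[tri, 1L], ncol = 3L))
  cy <- rowMeans(matrix(mesh$vertices[tri, 2L], ncol = 3L))
  df <- data.frame(x = cx, y = cy, count = as.integer(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$count)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "boundary\ncount") +
    ggplot2::theme_minimal()
}
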