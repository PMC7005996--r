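#' Plot a coexpression landscape
#'
#' Raster of the M x M grid over count pairs. Quasipotential landscapes
#' use a reversed scale so that valleys (likely states) appear bright.
#'
#' @param object A [coexpression_landscape()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coexpression_landscape <- function(object, ...) {
  df <- tidy(object)
  lab <- if (object$representation == "quasipotential") "phi = -ln(pi)" else "pi"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nx, y = .data$ny, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = if (object$representation == "quasipotential") -1 else 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mRNA count, gene X", y = "mRNA count, gene Y", fill = lab)
}

#' Plot library landscapes in shape-space
#'
#' Scatter of all library landscapes on the first two shape components,
#' colored by motif class or by a metric column.
#'
#' @param space A fitted `shape_space`.
#' @param library A `landscape_library`.
#' @param colour `"motif_class"` or the name of a metric column computed
#'   with [library_metrics()].
#' @return A ggplot.
#' @export
plot_shape_space <- function(space, library, colour = "motif_class") {
  occ <- motif_occupancy(space, library)
  if (!colour %in% names(occ) && colour != "motif_class") {
    occ <- dplyr::left_join(occ, library_metrics(library),
                            by = intersect(names(occ), names(library$models)))
  }
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$c1, y = .data$c2,
                                    colour = .data[[colour]])) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = sprintf("component 1 (%.1f%%)", 100 * space$var_fraction[1]),
                  y = sprintf("component 2 (%.1f%%)", 100 * space$var_fraction[2]))
}

#' Plot the loading maps of shape-space components
#'
#' Each component's loadings reshaped to the M x M count grid, showing
#' which landscape features the component encodes.
#'
#' @param object A `shape_space`.
#' @param n_components How many components to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_space <- function(object, n_components = object$n_components, ...) {
  M <- object$M
  df <- purrr::map_dfr(seq_len(n_components), function(j) {
    tibble::tibble(component = paste0("c", j),
                   nx = rep(0:(M - 1), times = M),
                   ny = rep(0:(M - 1), each = M),
                   loading = object$rotation[, j])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nx, y = .data$ny, fill = .data$loading)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~component) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mRNA count, gene X", y = "mRNA count, gene Y")
}

#' Plot one or more landscape-shape trajectories
#'
#' Stage-ordered paths through the first two shape components.
#'
#' @param object A `shape_trajectory`, or a named list of them.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_trajectory <- function(object, ...) {
  plot_trajectories(list(trajectory = object))
}

#' @rdname autoplot.shape_trajectory
#' @param trajectories Named list of `shape_trajectory` objects.
#' @export
plot_trajectories <- function(trajectories) {
  df <- purrr::imap_dfr(trajectories, function(tr, nm) {
    dplyr::mutate(tibble::as_tibble(tr), pair = nm,
                  stage = factor(.data$stage, levels = unique(.data$stage)))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$c1, y = .data$c2, colour = .data$pair,
                                   group = .data$pair)) +
    ggplot2::geom_path(arrow = grid::arrow(length = grid::unit(2, "mm"))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "component 1", y = "component 2", colour = "gene pair")
}
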