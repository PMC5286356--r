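# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.water_census <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.water_census <- function(x, ...) {
  counts <- table(x$category)
  tibble::tibble(n_waters = nrow(x),
                 n_bridging = unname(counts["bridging"]),
                 n_nonbridging_A = unname(counts["nonbridging_A"]),
                 n_nonbridging_B = unname(counts["nonbridging_B"]),
                 n_noninteracting = unname(counts["noninteracting"]),
                 mean_b = if (nrow(x) > 0) mean(x$bfactor) else NA_real_,
                 cutoff = attr(x, "cutoff"))
}

#' @export
tidy.kabsch_fit <- function(x, ...) {
  tibble::tibble(axis = c("x", "y", "z"),
                 r1 = x$rotation[, 1], r2 = x$rotation[, 2],
                 r3 = x$rotation[, 3], translation = x$translation)
}

#' @export
glance.kabsch_fit <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n = x$n, det = det(x$rotation))
}

#' @export
tidy.fulcrum_profile <- function(x, ...) x$per_atom

#' @export
glance.fulcrum_profile <- function(x, ...) {
  tibble::tibble(spearman = x$spearman, slope = x$slope, n = x$n,
                 unreliable = x$unreliable)
}

#' @export
tidy.sasa_result <- function(x, ...) x$per_atom

#' @export
glance.sasa_result <- function(x, ...) {
  tibble::tibble(total = x$total, probe = x$probe, n_points = x$n_points,
                 n_atoms = nrow(x$per_atom))
}

#' @export
tidy.et_path <- function(x, ...) {
  if (x$no_path) return(tibble::tibble(from = character(0),
                                       to = character(0),
                                       kind = character(0), R = numeric(0),
                                       eps = numeric(0)))
  dplyr::select(x$edges, "from", "to", "kind", "R", "eps")
}

#' @export
glance.et_path <- function(x, ...) {
  tibble::tibble(T_DA = x$T_DA, running_distance = x$running_distance,
                 n_steps = if (x$no_path) 0L else nrow(x$edges),
                 n_jumps = if (x$no_path) NA_integer_ else nrow(x$jumps),
                 no_path = x$no_path)
}

#' Scatter of interface waters in the two-distance plane
#'
#' Each water at its (nearest-A, nearest-B) distances, coloured by category,
#' with the interaction cutoff marked on both axes.
#'
#' @param object A `water_census`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.water_census <- function(object, ...) {
  cutoff <- attr(object, "cutoff") %||% 3.5
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$d_min_A, y = .data$d_min_B,
                               colour = .data$category)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = cutoff, linetype = "dashed") +
    ggplot2::labs(x = "nearest-atom distance to protein A (Å)",
                  y = "nearest-atom distance to protein B (Å)",
                  colour = "category") +
    ggplot2::theme_minimal()
}

#' B-factor versus distance from the interface anchors
#'
#' @param object A `fulcrum_profile`.
#' @param ... Unused.
#' @return A ggplot object with the per-atom scatter and binned means.
#' @export
autoplot.fulcrum_profile <- function(object, ...) {
  ggplot2::ggplot(object$per_atom,
                  ggplot2::aes(x = .data$distance, y = .data$bfactor)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_point(data = object$bins,
                        ggplot2::aes(x = .data$mid, y = .data$mean_b),
                        colour = "red", size = 3) +
    ggplot2::geom_line(data = object$bins,
                       ggplot2::aes(x = .data$mid, y = .data$mean_b),
                       colour = "red") +
    ggplot2::labs(x = "distance to nearest anchor (Å)",
                  y = expression(B~(ring(A)^2))) +
    ggplot2::theme_minimal()
}

#' Per-step decay factors along a tunneling path
#'
#' @param object An `et_path`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.et_path <- function(object, ...) {
  if (object$no_path) stop("cannot plot: no path")
  df <- dplyr::mutate(object$edges, step = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$eps,
                                   fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "path step", y = "decay factor (log scale)",
                  fill = "step kind") +
    ggplot2::theme_minimal()
}

#' Projected view of the interface hydrogen-bond network
#'
#' Nodes at their x/z coordinates (the interface normal is usually close to
#' one axis), edges as segments.
#'
#' @param object An `hbond_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hbond_network <- function(object, ...) {
  nodes <- object$nodes
  edges <- object$edges
  if (nrow(edges) > 0) {
    edges <- edges |>
      dplyr::left_join(dplyr::select(nodes, "node_id", x0 = "x", z0 = "z"),
                       by = c(from = "node_id")) |>
      dplyr::left_join(dplyr::select(nodes, "node_id", x1 = "x", z1 = "z"),
                       by = c(to = "node_id"))
  }
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$z))
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges, ggplot2::aes(x = .data$x0, y = .data$z0,
                                 xend = .data$x1, yend = .data$z1),
      colour = "grey60")
  }
  p + ggplot2::geom_point(ggplot2::aes(colour = .data$node_kind), size = 2) +
    ggplot2::labs(x = "x (Å)", y = "z (Å)", colour = "node") +
    ggplot2::theme_minimal()
}
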