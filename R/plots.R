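# ggplot2 visualisations of result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an order-parameter distribution
#'
#' @param object An [order_param_stats()] result.
#' @param ... Unused.
#' @return A ggplot: the accessible-volume-weighted density of the local
#'   order parameter, annotated with the Binder cumulant and skewness.
#' @export
autoplot.order_param_stats <- function(object, ...) {
  ggplot2::ggplot(object$histogram, ggplot2::aes(x = .data$mid,
                                                 y = .data$density)) +
    ggplot2::geom_col(width = 2 / object$n_bins, fill = "steelblue",
                      color = NA) +
    ggplot2::labs(
      x = expression(Delta * phi),
      y = expression(P(Delta * phi)),
      subtitle = sprintf("Binder = %.3f, skewness = %.3f",
                         object$binder, object$skewness)) +
    ggplot2::theme_minimal()
}

#' Plot segmented heterochromatin foci
#'
#' @param object A [segment_foci()] result.
#' @param ... Unused.
#' @return A ggplot of focus size (radius of gyration) against radial
#'   position, colored by shape anisotropy.
#' @export
autoplot.foci_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$radial_position,
                                       y = .data$Rg,
                                       color = .data$kappa_sq,
                                       size = .data$size)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_viridis_c(limits = c(0, 1),
                                   name = expression(kappa^2)) +
    ggplot2::labs(x = "radial position (l)",
                  y = expression(R[g] ~ "(l)")) +
    ggplot2::theme_minimal()
}

#' Plot radial density profiles
#'
#' @param profile A [radial_density()] tibble.
#' @return A ggplot of species densities against radius.
#' @export
plot_radial_density <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$r_mid, y = .data$density,
                                        color = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "r (l)", y = expression("density (beads/" * l^3 * ")")) +
    ggplot2::theme_minimal()
}

#' Plot reduced free-energy curves
#'
#' @param eps_values Repulsion parameters to draw.
#' @param Phi_grid Composition grid.
#' @return A ggplot of `f*(Phi_B)` for each `eps`, the mean-field
#'   convex-to-concave diagnostic.
#' @export
plot_f_star <- function(eps_values = c(0, 5, 10, 15, 20),
                        Phi_grid = seq(0.02, 0.98, by = 0.01)) {
  curves <- purrr::map_dfr(eps_values, function(e) {
    dplyr::mutate(f_star_curve(e, Phi_grid), eps = e)
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$Phi_B, y = .data$f_star,
                                       color = factor(.data$eps))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(Phi[B]), y = expression(f^"*"),
                  color = expression(epsilon)) +
    ggplot2::theme_minimal()
}
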