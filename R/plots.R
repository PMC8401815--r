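# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes
#' @export
ggplot2::autoplot

#' Histograms of the per-track estimates
#'
#' Faceted histograms of diffusivity, radius, axial velocity and density
#' difference — the at-a-glance view of what a recording recovered.
#'
#' @param object A [estimate_particles()] result.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pm_estimates
#' @export
autoplot.pm_estimates <- function(object, bins = 30, ...) {
  long <- tidy(object) |>
    dplyr::select("track_id", "D_um2_s", "r_um", "vz_um_s",
                  "delta_rho_kg_m3") |>
    tidyr::pivot_longer(-"track_id", names_to = "quantity") |>
    dplyr::filter(is.finite(.data$value))
  ggplot(long, aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "grey20", linewidth = 0.2) +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = NULL, y = "tracks",
                  title = "Per-track passive-motion estimates")
}

#' Strouhal regime map for one gravity environment
#'
#' Heat map of log10(Sr_p) over radius and particle density, with the
#' mixed-regime band (0.1 < Sr < 10) contoured; material densities can be
#' overlaid as horizontal guides.
#'
#' @param env A [mission_environment()].
#' @param radii_um Radius grid (um).
#' @param densities Particle density grid (kg/m^3).
#' @param materials Optional material names from [material_library()] to
#'   overlay.
#' @return A ggplot object.
#' @export
plot_strouhal_map <- function(env, radii_um = seq(0.2, 2, by = 0.05),
                              densities = seq(1000, 3000, by = 25),
                              materials = NULL) {
  grid <- strouhal_grid(radii_um * 1e-6, densities, env)
  df <- tidyr::expand_grid(radius_um = radii_um, density = densities)
  df$log10_sr <- as.vector(grid)
  p <- ggplot(df, aes(x = .data$radius_um, y = .data$density,
                      fill = .data$log10_sr)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(aes(z = .data$log10_sr), breaks = c(-1, 1),
                          colour = "white", linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = expression(log[10] ~ Sr[p])) +
    ggplot2::labs(x = "radius (µm)", y = expression(rho[p] ~ (kg/m^3)),
                  title = sprintf("Strouhal regimes: %s (g = %.3g m/s²)",
                                  env$name, env$gravity))
  if (!is.null(materials)) {
    lib <- dplyr::filter(material_library(),
                         .data$material %in% materials)
    p <- p + ggplot2::geom_hline(data = lib,
                                 aes(yintercept = .data$density_kg_m3),
                                 linetype = "dashed", colour = "grey90")
  }
  p
}

#' Classification calls coloured on the density axis
#'
#' @param object A [classify_population()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pm_classification
#' @export
autoplot.pm_classification <- function(object, ...) {
  ggplot(object, aes(x = .data$rho_hat_kg_m3, fill = .data$call)) +
    ggplot2::geom_histogram(bins = 40, colour = "grey20", linewidth = 0.2) +
    ggplot2::labs(x = expression(hat(rho)[p] ~ (kg/m^3)), y = "particles",
                  title = "Density-gap classification")
}
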