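#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-track estimates
#'
#' @param x A [estimate_particles()] result.
#' @param ... Unused.
#' @return The per-track estimates as a plain tibble.
#' @method tidy pm_estimates
#' @export
tidy.pm_estimates <- function(x, ...) {
  class(x) <- setdiff(class(x), "pm_estimates")
  attr(x, "env") <- NULL; attr(x, "fluid") <- NULL
  attr(x, "radius_source") <- NULL
  as_tibble(x)
}

#' One-row population overview of a set of estimates
#'
#' @param x A [estimate_particles()] result.
#' @param ... Unused.
#' @return One-row tibble: track counts and the population mean/median of
#'   diffusivity, radius, axial velocity and density difference.
#' @method glance pm_estimates
#' @export
glance.pm_estimates <- function(x, ...) {
  ok <- x$flags == "ok"
  tibble(
    n_tracks = nrow(x),
    n_ok = sum(ok),
    mean_D_um2_s = mean(x$D_um2_s, na.rm = TRUE),
    median_D_um2_s = stats::median(x$D_um2_s, na.rm = TRUE),
    mean_r_um = mean(x$r_um, na.rm = TRUE),
    mean_vz_um_s = mean(x$vz_um_s, na.rm = TRUE),
    mean_delta_rho_kg_m3 = mean(x$delta_rho_kg_m3, na.rm = TRUE),
    median_strouhal = stats::median(x$strouhal[is.finite(x$strouhal)])
  )
}
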