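#' Reference densities of materials relevant to life detection
#'
#' Densities of micro-organisms, biological structures and common minerals
#' suspended in water, with their offset from water at 20 degC
#' (998 kg/m^3). Biological material sits at or below ~1.2 g/cm^3 while
#' nearly all minerals exceed 1.5 g/cm^3 — the density gap the classifier
#' exploits. The diatom entry summarises a 1100-1200 kg/m^3 range by its
#' midpoint.
#'
#' @return A tibble with columns `material`, `density_kg_m3`,
#'   `delta_rho_kg_m3` (density minus water) and `kind`
#'   (`biological`/`mineral`/`synthetic`/`fluid`).
#' @examples
#' material_library()
#' @export
material_library <- function() {
  readr::read_csv(
    system.file("extdata", "materials.csv", package = "passivemotion",
                mustWork = TRUE),
    col_types = readr::cols(
      material = readr::col_character(),
      density_kg_m3 = readr::col_double(),
      delta_rho_kg_m3 = readr::col_double(),
      kind = readr::col_character()
    )
  )
}

#' Look up one material's density
#'
#' @param material Material name (case-insensitive exact match).
#' @return Density (kg/m^3).
#' @export
material_density <- function(material) {
  lib <- material_library()
  hit <- match(tolower(material), tolower(lib$material))
  if (anyNA(hit))
    abort(sprintf("Unknown material(s): %s. See material_library().",
                  paste(material[is.na(hit)], collapse = ", ")))
  lib$density_kg_m3[hit]
}

#' Gravity environments shipped with the package
#'
#' Surface gravitational accelerations for bodies of interest to ocean-world
#' life detection.
#'
#' @return A tibble with columns `body` and `gravity_m_s2`.
#' @export
mission_environments <- function() {
  readr::read_csv(
    system.file("extdata", "environments.csv", package = "passivemotion",
                mustWork = TRUE),
    col_types = readr::cols(body = readr::col_character(),
                            gravity_m_s2 = readr::col_double())
  )
}
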