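# Density-gap classification. Terrestrial aquatic cells sit below
# ~1.3 g/cm^3; almost no mineral is lighter than ~1.5 g/cm^3; nothing
# mineral floats. An estimated particle density therefore maps to
# cell-like / mineral-like / ambiguous, with floaters given their own
# high-confidence biological class.

#' Classify particles by estimated density
#'
#' Adds the implied particle density `rho_hat = delta_rho + rho_f` and a
#' call per track: below the fluid density -> `buoyant-biological` (no
#' mineral floats), below the cell threshold -> `cell-like`, above the
#' mineral threshold -> `mineral-like`, in the gap -> `ambiguous` (an
#' explicit output, matching the ~10% density uncertainty argument, never
#' a forced assignment). Calls are monotone in `rho_hat`.
#'
#' @param estimates A [estimate_particles()] result (needs
#'   `delta_rho_kg_m3`; `strouhal`/`regime` carried through if present).
#' @param fluid A [fluid_medium()] providing the fluid density.
#' @param thresholds Named numeric `c(cell = 1300, mineral = 1500)` kg/m^3.
#' @return Tibble with `track_id`, `rho_hat_kg_m3`, `call`, `regime`,
#'   `note`.
#' @examples
#' est <- tibble::tibble(track_id = 1:3,
#'                       delta_rho_kg_m3 = c(102, 1932, -879),
#'                       strouhal = c(5, 0.2, 0.05))
#' classify_density(est, fluid_medium(293.15, 1.002e-3, 998))
#' @export
classify_density <- function(estimates, fluid,
                             thresholds = c(cell = 1300, mineral = 1500)) {
  stopifnot(all(c("cell", "mineral") %in% names(thresholds)),
            thresholds["cell"] < thresholds["mineral"])
  rho <- estimates$delta_rho_kg_m3 + fluid$density
  call <- dplyr::case_when(
    is.na(rho) ~ "unclassifiable",
    rho < fluid$density ~ "buoyant-biological",
    rho < thresholds[["cell"]] ~ "cell-like",
    rho > thresholds[["mineral"]] ~ "mineral-like",
    TRUE ~ "ambiguous"
  )
  note <- dplyr::case_when(
    call == "unclassifiable" ~ "no density estimate",
    call == "buoyant-biological" ~ "floats: minerals never do",
    call == "ambiguous" ~ "inside the cell/mineral density gap",
    TRUE ~ ""
  )
  regime <- if ("regime" %in% names(estimates)) estimates$regime
            else if ("strouhal" %in% names(estimates))
              motion_regime(estimates$strouhal)
            else NA_character_
  tibble(track_id = estimates$track_id, rho_hat_kg_m3 = rho,
         call = call, regime = regime, note = note)
}

#' Classify a population, optionally scoring against ground truth
#'
#' Per-particle [classify_density()] calls; when a truth table is supplied
#' (as written by the simulator) each true density is classified by the
#' same rule and a confusion table of call vs truth is attached.
#'
#' @inheritParams classify_density
#' @param truth Optional truth tibble (`particle_id`, `density_kg_m3`).
#' @return Classification tibble; with truth, a `"confusion"` attribute
#'   (contingency table, truth in rows) retrievable via
#'   [confusion_matrix()].
#' @export
classify_population <- function(estimates, fluid,
                                thresholds = c(cell = 1300, mineral = 1500),
                                truth = NULL) {
  stopifnot(nrow(estimates) >= 1)
  calls <- classify_density(estimates, fluid, thresholds)
  if (!is.null(truth)) {
    true_calls <- classify_density(
      tibble(track_id = truth$particle_id,
             delta_rho_kg_m3 = truth$density_kg_m3 - fluid$density),
      fluid, thresholds)
    idx <- match(calls$track_id, true_calls$track_id)
    attr(calls, "confusion") <- table(truth = true_calls$call[idx],
                                      call = calls$call)
  }
  class(calls) <- c("pm_classification", class(calls))
  calls
}

#' @rdname classify_population
#' @param x A [classify_population()] result.
#' @export
confusion_matrix <- function(x) attr(x, "confusion")

#' Observation-time planning across gravity environments
#'
#' For each particle class and environment: the recording time needed for
#' the axial drift to exceed the instrument's axial resolution
#' (t = d / |v_stokes|, exactly linear in 1/g), the motion regime, and the
#' smallest density difference resolvable within a fixed recording
#' duration.
#'
#' @param classes Tibble of particle classes with columns `label`,
#'   `delta_rho_kg_m3`, `radius_um`. Defaults to the material library at
#'   0.75 um radius.
#' @param envs Tibble as [mission_environments()] (columns `body`,
#'   `gravity_m_s2`), or a character vector of body names.
#' @param fluid A [fluid_medium()].
#' @param axial_resolution_um Axial resolution of the instrument (um).
#' @param duration_s Available recording duration for the minimum
#'   resolvable density difference.
#' @return Tibble: `environment`, `g_m_s2`, `label`, `delta_rho_kg_m3`,
#'   `radius_um`, `t_required_s`, `strouhal`, `regime`,
#'   `min_resolvable_drho_kg_m3`.
#' @examples
#' mission_plan(envs = "Enceladus")
#' @export
mission_plan <- function(classes = NULL, envs = mission_environments(),
                         fluid = water_medium(),
                         axial_resolution_um = 2, duration_s = 30) {
  stopifnot(axial_resolution_um > 0, duration_s > 0)
  if (is.null(classes)) {
    lib <- dplyr::filter(material_library(), .data$kind != "fluid")
    classes <- tibble(label = lib$material,
                      delta_rho_kg_m3 = lib$delta_rho_kg_m3,
                      radius_um = 0.75)
  }
  if (is.character(envs))
    envs <- dplyr::filter(mission_environments(),
                          tolower(.data$body) %in% tolower(envs))
  stopifnot(nrow(envs) >= 1)
  d_m <- axial_resolution_um * 1e-6
  tidyr::crossing(dplyr::rename(envs, environment = "body"), classes) |>
    dplyr::mutate(
      env_obj = purrr::map(.data$gravity_m_s2,
                           ~ mission_environment("custom", .x, fluid)),
      t_required_s = purrr::pmap_dbl(
        list(.data$delta_rho_kg_m3, .data$radius_um, .data$env_obj),
        ~ required_observation_time(..1, ..2 * 1e-6, d_m, ..3)),
      strouhal = purrr::pmap_dbl(
        list(.data$radius_um, .data$delta_rho_kg_m3, .data$env_obj),
        ~ strouhal_number(particle_spec(..1 * 1e-6,
                                        pmax(fluid$density + ..2, 1e-9)), ..3)),
      regime = motion_regime(.data$strouhal),
      min_resolvable_drho_kg_m3 = purrr::map2_dbl(
        .data$radius_um, .data$env_obj,
        ~ 9 * fluid$viscosity * d_m /
          (2 * .y$gravity * (.x * 1e-6)^2 * duration_s))
    ) |>
    dplyr::select(environment = "environment", g_m_s2 = "gravity_m_s2",
                  "label", "delta_rho_kg_m3", "radius_um", "t_required_s",
                  "strouhal", "regime", "min_resolvable_drho_kg_m3")
}
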