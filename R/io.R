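# File formats. All tables are comma-separated UTF-8 with '.' decimals and
# a mandatory header, so files round-trip across locales. Track tables use
# the dialect: track_id, frame (0-based), t_s, x_um, y_um, z_um with z
# increasing downward (sinking positive).

.tracks_cols <- c("track_id", "frame", "t_s", "x_um", "y_um", "z_um")

#' Read / write track tables
#'
#' `read_tracks()` validates the header and enforces the package's sign
#' convention: if your z axis increases upward, pass `z_sign = "up"` and z
#' is negated on ingest so that sinking stays positive internally.
#'
#' @param path CSV file path.
#' @param z_sign `"down"` (file already has z increasing downward) or
#'   `"up"`.
#' @return A track tibble.
#' @export
read_tracks <- function(path, z_sign = c("down", "up")) {
  z_sign <- match.arg(z_sign)
  x <- readr::read_csv(path, col_types = readr::cols(
    track_id = readr::col_integer(), frame = readr::col_integer(),
    t_s = readr::col_double(), x_um = readr::col_double(),
    y_um = readr::col_double(), z_um = readr::col_double()))
  missing <- setdiff(.tracks_cols, names(x))
  if (length(missing) > 0)
    abort(sprintf("Malformed tracks CSV '%s': missing column(s) %s.",
                  path, paste(missing, collapse = ", ")))
  if (z_sign == "up") x$z_um <- -x$z_um
  x[, .tracks_cols]
}

#' @rdname read_tracks
#' @param tracks Track tibble.
#' @export
write_tracks <- function(tracks, path) {
  readr::write_csv(tracks[, .tracks_cols], path)
  invisible(path)
}

#' Read / write ground-truth tables
#'
#' Columns: `particle_id`, `radius_um`, `density_kg_m3`, `v_stokes_um_s`
#' (plus initial positions when present).
#' @param path CSV file path.
#' @export
read_truth <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols())
  need <- c("particle_id", "radius_um", "density_kg_m3", "v_stokes_um_s")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0)
    abort(sprintf("Malformed truth CSV '%s': missing column(s) %s.",
                  path, paste(missing, collapse = ", ")))
  x
}

#' @rdname read_truth
#' @param truth Truth tibble.
#' @export
write_truth <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}

#' Read / write per-track estimate tables
#'
#' Columns: `track_id`, `D_um2_s`, `r_um`, `vz_um_s`, `delta_rho_kg_m3`,
#' `strouhal`, `n_steps`, `flags`.
#' @param estimates A [estimate_particles()] result.
#' @param path CSV file path.
#' @export
write_estimates <- function(estimates, path) {
  cols <- c("track_id", "D_um2_s", "r_um", "vz_um_s", "delta_rho_kg_m3",
            "strouhal", "n_steps", "flags")
  readr::write_csv(as_tibble(estimates)[, intersect(cols, names(estimates))],
                   path)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_estimates <- function(path) {
  readr::read_csv(path, col_types = readr::cols())
}

#' Write classification and planning tables
#' @param x Result of [classify_population()] or [mission_plan()].
#' @param path CSV file path.
#' @export
write_classifications <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Write a Strouhal grid as a CSV matrix
#'
#' Plain CSV with the radius grid as the first column and the density grid
#' as the header row.
#' @param grid Matrix from [strouhal_grid()].
#' @param path CSV file path.
#' @export
write_strouhal_grid <- function(grid, path) {
  df <- data.frame(radius_m = rownames(grid), grid, check.names = FALSE)
  names(df)[-1] <- colnames(grid)
  readr::write_csv(df, path)
  invisible(path)
}

#' Write / read a volume series as multi-page TIFFs
#'
#' One 16-bit multi-page TIFF per time point, named `t00000.tif`,
#' `t00001.tif`, ... with one page per z slice. Intensities are clipped to
#' `[0, max_intensity]` and scaled to the 16-bit range.
#'
#' @param volumes 4D array `[y, x, z, t]`.
#' @param dir Output directory (created if needed).
#' @param max_intensity Intensity mapped to the top of the 16-bit range.
#' @return `dir`, invisibly (`write`); a 4D array (`read`).
#' @export
write_volume_series <- function(volumes, dir, max_intensity = 2) {
  stopifnot(length(dim(volumes)) == 4)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nt <- dim(volumes)[4]
  for (it in seq_len(nt)) {
    pages <- lapply(seq_len(dim(volumes)[3]), function(iz)
      pmin(pmax(volumes[, , iz, it] / max_intensity, 0), 1))
    tiff::writeTIFF(pages, file.path(dir, sprintf("t%05d.tif", it - 1L)),
                    bits.per.sample = 16)
  }
  invisible(dir)
}

#' @rdname write_volume_series
#' @export
read_volume_series <- function(dir, max_intensity = 2) {
  files <- sort(list.files(dir, pattern = "^t\\d{5}\\.tif$",
                           full.names = TRUE))
  if (length(files) == 0) abort(sprintf("No t*.tif volumes found in '%s'.", dir))
  first <- tiff::readTIFF(files[1], all = TRUE)
  dims <- dim(first[[1]])
  vol <- array(0, dim = c(dims[1], dims[2], length(first), length(files)))
  for (it in seq_along(files)) {
    pages <- tiff::readTIFF(files[it], all = TRUE)
    if (length(pages) != dim(vol)[3] || !all(dim(pages[[1]]) == dims))
      abort(sprintf("Inconsistent TIFF shapes in '%s' (file %s).",
                    dir, basename(files[it])))
    for (iz in seq_along(pages)) vol[, , iz, it] <- pages[[iz]] * max_intensity
  }
  vol
}

#' Write a population summary as JSON
#' @param summaries Tibble from [summarize_population()] (rows may be bound).
#' @param path JSON file path.
#' @export
write_summary_json <- function(summaries, path) {
  x <- lapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, ]
    list(quantity = s$quantity, n = s$n, mean = s$mean, median = s$median,
         ci_half_width = s$ci_half_width,
         histogram = as.list(s$histogram[[1]]))
  })
  names(x) <- summaries$quantity
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- configuration ---------------------------------------------------------

#' Default pipeline configuration
#'
#' A flat named list of every tunable the pipeline uses; see
#' [read_config()] for the on-disk YAML form.
#' @return Named list.
#' @export
default_config <- function() {
  list(
    material = "Polystyrene", n_particles = 50L,
    size_model = "fixed", radius_um = 0.5,
    size_sigma = 0.2, monomer_diameter_um = 0.8, max_multiplicity = 4L,
    environment = "Earth", temperature_K = 293.15,
    frame_rate = 15, duration_s = 30,
    field_x_um = 356, field_y_um = 365, chamber_depth_um = 1000,
    sigma_xy_um = 0.2, sigma_z_um = 1.0,
    drift_x_um_s = 0, drift_y_um_s = 0,
    init = "transit",
    max_disp_um = 5, gap_max = 2L, threshold = "otsu",
    dims = 2L, max_lag = 3L, outlier_D_cutoff_um2_s = 1.20,
    radius_source = "diffusivity", fixed_radius_um = NA,
    cell_threshold_kg_m3 = 1300, mineral_threshold_kg_m3 = 1500,
    seed = 1L
  )
}

#' Read / write pipeline configuration
#'
#' YAML-style flat key/value file. Unknown keys are rejected (they are
#' almost always typos); missing keys take their defaults. The
#' configuration round-trips losslessly.
#'
#' @param path Config file path.
#' @return Named list (read) or `path` invisibly (write).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  def <- default_config()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown) > 0)
    abort(sprintf("Unknown config key(s) in '%s': %s.",
                  path, paste(unknown, collapse = ", ")))
  utils::modifyList(def, raw)
}

#' @rdname read_config
#' @param config Named list as from [default_config()].
#' @export
write_config <- function(config, path) {
  unknown <- setdiff(names(config), names(default_config()))
  if (length(unknown) > 0)
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  yaml::write_yaml(config, path)
  invisible(path)
}
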