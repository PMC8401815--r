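# Per-track inference: lateral MSD -> diffusivity -> hydrodynamic radius
# (Einstein-Stokes); axial OLS slope -> Stokes density difference; the two
# combine into a per-particle Strouhal number. Population summaries report
# medians alongside means because size and diffusivity distributions are
# typically skewed.

.track_dt <- function(track) {
  dt <- diff(track$t_s)
  if (length(dt) == 0) return(NA_real_)
  stats::median(dt)
}

#' Diffusivity from the mean squared displacement
#'
#' MSD(k dt) is computed for lags 1..`max_lag` and fitted by an unweighted
#' straight line through the origin; the slope divided by 2 x `dims` is the
#' diffusivity. Short lags keep the bias-variance trade-off sane; the
#' default `max_lag = 3` is standard practice. Lateral coordinates must be
#' drift-subtracted first (see [estimate_drift()]).
#'
#' @param track Track tibble for one particle (`t_s`, `x_um`, and `y_um`
#'   when `dims = 2`).
#' @param dims 1 (x only) or 2 (x and y).
#' @param max_lag Largest lag (frames) entering the fit.
#' @return Diffusivity estimate (um^2/s); `NA` with a warning when the
#'   track is shorter than `max_lag + 1` points.
#' @export
msd_diffusivity <- function(track, dims = 2, max_lag = 3) {
  stopifnot(dims %in% c(1, 2))
  n <- nrow(track)
  if (n < max_lag + 1) {
    warn(sprintf("Track too short for MSD fit (%d points < %d); skipped.",
                 n, max_lag + 1))
    return(NA_real_)
  }
  dt <- .track_dt(track)
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(k) {
    dx <- track$x_um[(1 + k):n] - track$x_um[1:(n - k)]
    s <- dx^2
    if (dims == 2) {
      dy <- track$y_um[(1 + k):n] - track$y_um[1:(n - k)]
      s <- s + dy^2
    }
    mean(s)
  }, numeric(1))
  tau <- lags * dt
  sum(msd * tau) / sum(tau^2) / (2 * dims)
}

#' Axial velocity of one track
#'
#' Ordinary least-squares slope of z versus time; z increases downward, so
#' sinking is positive. OLS uses the whole trajectory and has lower
#' variance than an endpoint difference on long tracks.
#'
#' @param track Track tibble (`t_s`, `z_um`).
#' @return Velocity (um/s).
#' @export
z_velocity <- function(track) {
  if (nrow(track) < 2) {
    warn("Track has < 2 points; z velocity undefined.")
    return(NA_real_)
  }
  stats::cov(track$t_s, track$z_um) / stats::var(track$t_s)
}

#' Population mean axial drift
#'
#' Mean of the per-track OLS z velocities weighted by track length, i.e.
#' the ensemble sedimentation rate that near-neutral populations show only
#' collectively.
#'
#' @param tracks Track tibble (many `track_id`s).
#' @return Weighted mean z velocity (um/s).
#' @export
population_z_drift <- function(tracks) {
  per <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(v = z_velocity(dplyr::pick(dplyr::everything())),
                     n = dplyr::n())
  stats::weighted.mean(per$v, per$n, na.rm = TRUE)
}

#' Walker-style particle sizing from step lengths
#'
#' For a 2D Brownian walk the squared step lengths are exponential with
#' mean 4 D dt, so the per-track maximum-likelihood diffusivity is
#' mean(dr^2) / (4 dt); the Einstein-Stokes relation then converts each
#' track to a hydrodynamic diameter d = kB T / (3 pi eta D). This per-track
#' MLE + histogram realisation is a simplification of the full
#' step-distribution deconvolution.
#'
#' @param tracks Track tibble.
#' @param fluid A [fluid_medium()].
#' @param min_steps Minimum number of steps per usable track.
#' @return Tibble `track_id`, `n_steps`, `D_um2_s`, `diameter_um`, with a
#'   `"histogram"` attribute from [diameter_histogram()].
#' @export
walker_diameters <- function(tracks, fluid, min_steps = 4) {
  per <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      n_steps = dplyr::n() - 1L,
      D_um2_s = {
        dt <- .track_dt(dplyr::pick(dplyr::everything()))
        mean(diff(.data$x_um)^2 + diff(.data$y_um)^2) / (4 * dt)
      }
    ) |>
    dplyr::filter(.data$n_steps >= min_steps, .data$D_um2_s > 0)
  per$diameter_um <- 2 * radius_from_diffusivity(per$D_um2_s * 1e-12,
                                                 fluid) * 1e6
  attr(per, "histogram") <- diameter_histogram(per$diameter_um)
  per
}

#' Histogram of estimated diameters
#'
#' @param diameters_um Diameters (um).
#' @param bin_width Bin width (um), 0.1 by default.
#' @return Tibble `bin_left`, `bin_right`, `mid`, `count`.
#' @export
diameter_histogram <- function(diameters_um, bin_width = 0.1) {
  if (length(diameters_um) == 0)
    return(tibble(bin_left = numeric(), bin_right = numeric(),
                  mid = numeric(), count = integer()))
  breaks <- seq(0, (floor(max(diameters_um) / bin_width) + 1) * bin_width,
                by = bin_width)
  h <- graphics::hist(diameters_um, breaks = breaks, plot = FALSE)
  tibble(bin_left = utils::head(h$breaks, -1),
         bin_right = utils::tail(h$breaks, -1),
         mid = h$mids, count = h$counts)
}

#' Per-particle size, density and Strouhal estimation
#'
#' The full per-track chain: (ensemble lateral drift subtraction) ->
#' lateral MSD diffusivity -> hydrodynamic radius -> axial OLS velocity ->
#' Stokes density difference -> Strouhal number and motion regime. Every
#' quantity is measured on each particle independently, because the strong
#' (r^-4) size dependence of the Strouhal number makes population-level
#' shortcuts unreliable. Stages that fail leave `NA`s and a reason in
#' `flags`; the result is deterministic given the tracks.
#'
#' @param tracks Track tibble (um coordinates, z down).
#' @param env A [mission_environment()]; its fluid supplies T and eta.
#' @param fluid Fluid used for the Einstein-Stokes inversion; defaults to
#'   `env$fluid`.
#' @param radius_source `"diffusivity"` (per-track, from the lateral MSD)
#'   or `"fixed"` (use `fixed_radius_um` for all tracks, e.g. when sizes
#'   are known independently).
#' @param fixed_radius_um Radius used when `radius_source = "fixed"`.
#' @param dims,max_lag Passed to [msd_diffusivity()].
#' @param subtract_xy_drift Estimate and remove ensemble lateral drift
#'   before the MSD fit? (Axial drift is the signal; it is never removed.)
#' @return A `pm_estimates` tibble: `track_id`, `n_steps`, `D_um2_s`,
#'   `r_um`, `vz_um_s`, `delta_rho_kg_m3`, `strouhal`, `regime`, `flags`.
#' @examples
#' env <- mission_environment("Earth", fluid = fluid_medium(293.15, 1.002e-3, 998))
#' pop <- sample_population(
#'   population_spec("Alumina", 3, size_fixed(0.75), env), seed = 1)
#' sim <- simulate_population(pop, recording_spec(duration = 10), env, seed = 1)
#' estimate_particles(sim$tracks, env)
#' @export
estimate_particles <- function(tracks, env, fluid = env$fluid,
                               radius_source = c("diffusivity", "fixed"),
                               fixed_radius_um = NULL,
                               dims = 2, max_lag = 3,
                               subtract_xy_drift = TRUE) {
  radius_source <- match.arg(radius_source)
  if (radius_source == "fixed" && is.null(fixed_radius_um))
    abort("`fixed_radius_um` is required when radius_source = \"fixed\".")
  lat <- tracks
  if (subtract_xy_drift && dplyr::n_distinct(tracks$track_id) >= 1) {
    lat <- subtract_drift(tracks, estimate_drift(tracks, axes = c("x", "y")))
  }
  ids <- unique(tracks$track_id)
  est <- purrr::map_dfr(ids, function(id) {
    tr_lat <- dplyr::arrange(lat[lat$track_id == id, ], .data$frame)
    tr_ax <- dplyr::arrange(tracks[tracks$track_id == id, ], .data$frame)
    flags <- character()
    D <- withCallingHandlers(
      msd_diffusivity(tr_lat, dims = dims, max_lag = max_lag),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.na(D) || D <= 0) {
      flags <- c(flags, "short_or_nonpositive_D")
      D <- NA_real_
    }
    r_um <- switch(radius_source,
      diffusivity = if (is.na(D)) NA_real_ else
        radius_from_diffusivity(D * 1e-12, fluid) * 1e6,
      fixed = fixed_radius_um)
    vz <- withCallingHandlers(z_velocity(tr_ax),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.na(vz)) flags <- c(flags, "no_z_velocity")
    drho <- if (is.na(vz) || is.na(r_um)) NA_real_ else
      density_diff_from_velocity(vz * 1e-6, r_um * 1e-6, env)
    sr <- if (is.na(drho) || is.na(r_um)) NA_real_ else if (drho == 0) Inf else
      3 * kB * env$fluid$temperature /
        (4 * pi * abs(drho) * env$gravity * (r_um * 1e-6)^4)
    tibble(track_id = id, n_steps = nrow(tr_ax) - 1L,
           D_um2_s = D, r_um = r_um, vz_um_s = vz,
           delta_rho_kg_m3 = drho, strouhal = sr,
           regime = if (is.na(sr)) NA_character_ else motion_regime(sr),
           flags = if (length(flags)) paste(flags, collapse = ";") else "ok")
  })
  structure(est, class = c("pm_estimates", class(est)),
            env = env, fluid = fluid, radius_source = radius_source)
}

#' Drop estimates beyond an outlier cutoff
#'
#' Removes tracks whose named quantity exceeds `cutoff` — by default
#' diffusivities above 1.20 um^2/s, which for micron-scale particles in
#' water flag mislinked or partial tracks rather than plausible physics.
#' The number removed is reported via a message; `cutoff = Inf` is the
#' identity.
#'
#' @param estimates A [estimate_particles()] result (or any tibble).
#' @param quantity Column to filter on.
#' @param cutoff Upper cutoff; rows with `quantity > cutoff` are removed.
#' @return Filtered estimates (attributes preserved).
#' @export
filter_outliers <- function(estimates, quantity = "D_um2_s", cutoff = 1.20) {
  stopifnot(cutoff > 0)
  if (!quantity %in% names(estimates))
    abort(sprintf("Unknown quantity '%s'; available: %s.", quantity,
                  paste(names(estimates), collapse = ", ")))
  bad <- !is.na(estimates[[quantity]]) & estimates[[quantity]] > cutoff
  if (any(bad))
    rlang::inform(sprintf("filter_outliers: removed %d of %d estimates (%s > %g).",
                          sum(bad), nrow(estimates), quantity, cutoff))
  out <- estimates[!bad, ]
  if (nrow(out) == 0) warn("All estimates removed as outliers.")
  out
}

#' Summarise one estimated quantity over a population
#'
#' Mean, median, Student-t 95% confidence half-width of the mean, and a
#' histogram. Medians are reported because the underlying distributions
#' (sizes, diffusivities) are usually skewed and the median is the more
#' representative location.
#'
#' @param estimates Estimates tibble.
#' @param quantity Column to summarise.
#' @param bin_width Histogram bin width (data-driven when `NULL`).
#' @param conf Confidence level.
#' @return One-row tibble: `quantity`, `n`, `mean`, `median`,
#'   `ci_half_width` (`NA` when n < 2) and a nested `histogram` tibble
#'   whose counts sum to `n`.
#' @export
summarize_population <- function(estimates, quantity, bin_width = NULL,
                                 conf = 0.95) {
  x <- estimates[[quantity]]
  if (is.null(x)) abort(sprintf("Unknown quantity '%s'.", quantity))
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) {
    return(tibble(quantity = quantity, n = 0L, mean = NA_real_,
                  median = NA_real_, ci_half_width = NA_real_,
                  histogram = list(tibble(bin_left = numeric(),
                                          bin_right = numeric(),
                                          mid = numeric(),
                                          count = integer()))))
  }
  ci <- if (n >= 2) {
    stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
  } else NA_real_
  if (is.null(bin_width)) {
    h <- graphics::hist(x, plot = FALSE)
    hist_tb <- tibble(bin_left = utils::head(h$breaks, -1),
                      bin_right = utils::tail(h$breaks, -1),
                      mid = h$mids, count = h$counts)
  } else {
    lo <- floor(min(x) / bin_width) * bin_width
    hi <- (floor(max(x) / bin_width) + 1) * bin_width
    h <- graphics::hist(x, breaks = seq(lo, hi, by = bin_width), plot = FALSE)
    hist_tb <- tibble(bin_left = utils::head(h$breaks, -1),
                      bin_right = utils::tail(h$breaks, -1),
                      mid = h$mids, count = h$counts)
  }
  tibble(quantity = quantity, n = n,
         mean = if (n) mean(x) else NA_real_,
         median = if (n) stats::median(x) else NA_real_,
         ci_half_width = ci,
         histogram = list(hist_tb))
}
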