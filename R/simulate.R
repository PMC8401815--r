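# Ground-truthed Langevin simulator emulating holographic-microscope
# recordings: overdamped Brownian steps plus constant Stokes drift along z,
# exact Gaussian increments per frame (Brownian motion is exactly
# discretizable, so there is no time-step bias), reflecting walls at the
# chamber top and bottom. z increases downward; sinking is positive.

#' Derive a per-stage RNG stream from one global seed
#'
#' All randomness in the package flows through one user seed; each pipeline
#' stage hashes its name into that seed so stages can be rerun independently
#' yet reproducibly.
#' @param seed Integer master seed.
#' @param stage Stage name (character scalar).
#' @return An integer seed < 2^31.
#' @keywords internal
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629)
}

#' Recording geometry and noise of an emulated microscope run
#'
#' Defaults follow the instrument emulated by the simulator: 15 frames/s for
#' 30 s over a 356 x 365 um lateral field in a 1 mm deep chamber, with
#' localization noise reflecting 0.8 um lateral / 2 um axial optical
#' resolution.
#'
#' @param frame_rate Frames per second.
#' @param duration Recording length (s).
#' @param field_xy Lateral field of view, c(x, y) in um.
#' @param chamber_depth Chamber depth along z (um).
#' @param sigma_xy,sigma_z Gaussian localization noise SD per coordinate (um).
#' @param drift_xy Uniform lateral drift c(vx, vy) (um/s).
#' @return A `recording_spec` object.
#' @export
recording_spec <- function(frame_rate = 15, duration = 30,
                           field_xy = c(356, 365), chamber_depth = 1000,
                           sigma_xy = 0.2, sigma_z = 1.0,
                           drift_xy = c(0, 0)) {
  stopifnot(frame_rate > 0, duration > 0, chamber_depth > 0,
            sigma_xy >= 0, sigma_z >= 0, length(field_xy) == 2,
            length(drift_xy) == 2)
  structure(list(frame_rate = frame_rate, duration = duration,
                 field_xy = field_xy, chamber_depth = chamber_depth,
                 sigma_xy = sigma_xy, sigma_z = sigma_z,
                 drift_xy = drift_xy),
            class = "recording_spec")
}

#' Particle size models for population sampling
#'
#' * `size_fixed()`: every particle has the same radius.
#' * `size_lognormal()`: radii lognormal about a median (sigma on log scale).
#' * `size_cluster()`: aggregates of `1..max_multiplicity` monomers whose
#'   effective diameter is multiplicity x monomer diameter — the model for
#'   streptavidin-clustered gas vesicles, whose measured size histogram
#'   shows peaks at increments of the monomer diameter.
#'
#' @param radius_um,median_um,sigma,monomer_diameter_um,max_multiplicity,probabilities
#'   Model parameters; sizes in um. `probabilities` (optional) weights
#'   multiplicities `1..max_multiplicity`, uniform if omitted.
#' @return A `size_model` list consumed by [sample_population()].
#' @name size_model
NULL

#' @rdname size_model
#' @export
size_fixed <- function(radius_um) {
  stopifnot(radius_um > 0)
  structure(list(kind = "fixed", radius_um = radius_um), class = "size_model")
}

#' @rdname size_model
#' @export
size_lognormal <- function(median_um, sigma = 0.2) {
  stopifnot(median_um > 0, sigma >= 0)
  structure(list(kind = "lognormal", median_um = median_um, sigma = sigma),
            class = "size_model")
}

#' @rdname size_model
#' @export
size_cluster <- function(monomer_diameter_um = 0.8, max_multiplicity = 4,
                         probabilities = NULL) {
  stopifnot(monomer_diameter_um > 0, max_multiplicity >= 1)
  if (is.null(probabilities))
    probabilities <- rep(1 / max_multiplicity, max_multiplicity)
  stopifnot(length(probabilities) == max_multiplicity,
            all(probabilities >= 0), sum(probabilities) > 0)
  structure(list(kind = "cluster", monomer_diameter_um = monomer_diameter_um,
                 max_multiplicity = max_multiplicity,
                 probabilities = probabilities / sum(probabilities)),
            class = "size_model")
}

#' Specify a particle population to simulate
#'
#' @param material Material name from [material_library()].
#' @param n_particles Number of particles.
#' @param size_model A [size_fixed()], [size_lognormal()] or [size_cluster()].
#' @param env A [mission_environment()].
#' @return A `population_spec` object.
#' @export
population_spec <- function(material, n_particles, size_model,
                            env = mission_environment("Earth")) {
  stopifnot(n_particles >= 1, inherits(size_model, "size_model"),
            inherits(env, "mission_environment"))
  density <- material_density(material) # errors on unknown material
  structure(list(material = material, n_particles = as.integer(n_particles),
                 size_model = size_model, density = density, env = env),
            class = "population_spec")
}

#' Draw a ground-truthed particle population
#'
#' Radii follow the population's size model; densities come from the
#' material library. Deterministic given `seed`.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @return A tibble: `particle_id`, `material`, `radius_um`,
#'   `density_kg_m3`.
#' @export
sample_population <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_particles
  sm <- spec$size_model
  radii <- withr::with_seed(derive_seed(seed, "sample_population"), {
    switch(sm$kind,
      fixed = rep(sm$radius_um, n),
      lognormal = stats::rlnorm(n, meanlog = log(sm$median_um),
                                sdlog = sm$sigma),
      # diameter = multiplicity x monomer diameter, so radius = k * d_mono / 2
      cluster = sample.int(sm$max_multiplicity, n, replace = TRUE,
                           prob = sm$probabilities) *
        sm$monomer_diameter_um / 2
    )
  })
  tibble(particle_id = seq_len(n),
         material = spec$material,
         radius_um = radii,
         density_kg_m3 = spec$density)
}

#' Simulate recorded 3D tracks for a particle population
#'
#' Per frame, each particle takes an exact Brownian increment
#' sqrt(2 D dt) * N(0,1) on every axis, plus the uniform lateral drift and
#' the Stokes terminal velocity along z; z reflects at the chamber walls.
#' Lateral starting positions are uniform over the field.
#'
#' `init` controls axial placement: `"transit"` (default) starts each
#' sinking/floating particle so that its deterministic drift path fits
#' inside the chamber over the recording — emulating the fact that a
#' particle one can track for the whole recording is, by selection, one
#' traversing the field rather than parked at a wall; `"uniform"` draws z0
#' uniformly over the full depth.
#'
#' @param particles Tibble from [sample_population()] (columns
#'   `particle_id`, `radius_um`, `density_kg_m3`).
#' @param rec A [recording_spec()].
#' @param env A [mission_environment()].
#' @param seed Integer seed.
#' @param init `"transit"` or `"uniform"` axial placement.
#' @param D_override Diffusivity override in um^2/s (scalar, recycled);
#'   `0` switches diffusion off for drift-only checks. `NULL` uses the
#'   Einstein-Stokes value for each particle.
#' @return List of two tibbles: `tracks` (`track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`, `z_um`; z down, frames 0-based) and `truth`
#'   (`particle_id`, `radius_um`, `density_kg_m3`, `v_stokes_um_s`,
#'   `x0_um`, `y0_um`, `z0_um`).
#' @export
simulate_population <- function(particles, rec, env, seed = 1,
                                init = c("transit", "uniform"),
                                D_override = NULL) {
  init <- match.arg(init)
  stopifnot(inherits(rec, "recording_spec"),
            inherits(env, "mission_environment"))
  n <- nrow(particles)
  dt <- 1 / rec$frame_rate
  nstep <- floor(rec$duration * rec$frame_rate)
  r_m <- particles$radius_um * 1e-6
  v_um <- stokes_velocity(
    particle_spec(r_m, particles$density_kg_m3), env) * 1e6
  D_um <- if (is.null(D_override)) {
    diffusion_coefficient(r_m, env$fluid) * 1e12
  } else rep_len(D_override, n)
  sd_step <- sqrt(2 * D_um * dt)
  L <- rec$chamber_depth

  withr::with_seed(derive_seed(seed, "simulate_population"), {
    x0 <- stats::runif(n, 0, rec$field_xy[1])
    y0 <- stats::runif(n, 0, rec$field_xy[2])
    travel <- v_um * rec$duration
    z0 <- if (init == "uniform") {
      stats::runif(n, 0, L)
    } else {
      lo <- pmin(pmax(-travel, 0), L)
      hi <- pmax(pmin(L - travel, L), 0)
      stats::runif(n, pmin(lo, hi), pmax(lo, hi))
    }
    x <- matrix(0, nstep + 1, n); y <- x; z <- x
    x[1, ] <- x0; y[1, ] <- y0; z[1, ] <- z0
    for (k in seq_len(nstep)) {
      x[k + 1, ] <- x[k, ] + rec$drift_xy[1] * dt + sd_step * stats::rnorm(n)
      y[k + 1, ] <- y[k, ] + rec$drift_xy[2] * dt + sd_step * stats::rnorm(n)
      zn <- z[k, ] + v_um * dt + sd_step * stats::rnorm(n)
      # reflecting walls at z = 0 and z = L (fold until inside)
      while (any(bad <- zn < 0 | zn > L)) {
        zn[bad] <- ifelse(zn[bad] < 0, -zn[bad], 2 * L - zn[bad])
      }
      z[k + 1, ] <- zn
    }
    tracks <- tibble(
      track_id = rep(particles$particle_id, each = nstep + 1),
      frame = rep(0:nstep, times = n),
      t_s = rep((0:nstep) * dt, times = n),
      x_um = as.vector(x), y_um = as.vector(y), z_um = as.vector(z)
    )
    truth <- tibble(
      particle_id = particles$particle_id,
      radius_um = particles$radius_um,
      density_kg_m3 = particles$density_kg_m3,
      v_stokes_um_s = v_um,
      x0_um = x0, y0_um = y0, z0_um = z0
    )
    list(tracks = tracks, truth = truth)
  })
}

#' Simulate a single particle track
#'
#' Convenience wrapper around [simulate_population()] for one particle.
#'
#' @param particle A [particle_spec()] (SI units).
#' @inheritParams simulate_population
#' @return A track tibble (`track_id`, `frame`, `t_s`, `x_um`, `y_um`,
#'   `z_um`).
#' @export
simulate_track <- function(particle, rec, env, seed = 1,
                           init = "transit", D_override = NULL) {
  stopifnot(inherits(particle, "particle_spec"))
  pop <- tibble(particle_id = 1L,
                radius_um = particle$radius * 1e6,
                density_kg_m3 = particle$density)
  simulate_population(pop, rec, env, seed = seed, init = init,
                      D_override = D_override)$tracks
}

#' Add localization noise to tracks
#'
#' Independent Gaussian measurement noise per coordinate, `sigma_xy`
#' laterally and `sigma_z` axially (um); zero SDs return the input
#' unchanged. Deterministic given `seed`.
#'
#' @param tracks Track tibble.
#' @param rec A [recording_spec()] carrying the noise SDs.
#' @param seed Integer seed.
#' @return Track tibble with noisy coordinates.
#' @export
apply_localization_noise <- function(tracks, rec, seed = 1) {
  if (rec$sigma_xy == 0 && rec$sigma_z == 0) return(tracks)
  n <- nrow(tracks)
  withr::with_seed(derive_seed(seed, "apply_localization_noise"), {
    dplyr::mutate(tracks,
      x_um = .data$x_um + stats::rnorm(n, 0, rec$sigma_xy),
      y_um = .data$y_um + stats::rnorm(n, 0, rec$sigma_xy),
      z_um = .data$z_um + stats::rnorm(n, 0, rec$sigma_z))
  })
}

#' Render tracks into a 4D intensity volume series
#'
#' Stand-in for reconstructed holographic z-stacks: per time point a z-stack
#' with one anisotropic Gaussian blob per in-bounds particle (lateral and
#' axial widths from the optical resolutions, sigma = FWHM / 2.355) on a
#' constant background, optionally with shot-like Poisson noise. Voxel
#' `[iy, ix, iz]` (1-based) is centred at ((ix-1) dx, (iy-1) dy, (iz-1) dz)
#' in um.
#'
#' @param tracks Track tibble (`frame`, `x_um`, `y_um`, `z_um`, `track_id`).
#' @param rec A [recording_spec()].
#' @param px_um Lateral pixel pitch (um); default field_x / 2048.
#' @param z_step_um Axial slice spacing (um).
#' @param lateral_resolution_um,axial_resolution_um Optical resolutions
#'   (FWHM, um) setting the blob widths.
#' @param background Constant background intensity (0-1 scale).
#' @param shot_noise Add Poisson shot noise (at `counts_scale` photons at
#'   unit intensity)?
#' @param counts_scale Photon count corresponding to intensity 1.
#' @param seed Integer seed (noise only).
#' @return 4D numeric array `[y, x, z, t]`, intensities >= 0 on a unit-ish
#'   scale.
#' @export
render_volume_series <- function(tracks, rec, px_um = rec$field_xy[1] / 2048,
                                 z_step_um = 2,
                                 lateral_resolution_um = 0.8,
                                 axial_resolution_um = 2,
                                 background = 0.05, shot_noise = FALSE,
                                 counts_scale = 1000, seed = 1) {
  if (nrow(tracks) == 0) abort("Empty track list: nothing to render.")
  nx <- max(2L, as.integer(round(rec$field_xy[1] / px_um)))
  ny <- max(2L, as.integer(round(rec$field_xy[2] / px_um)))
  nz <- max(2L, as.integer(floor(rec$chamber_depth / z_step_um)) + 1L)
  frames <- sort(unique(tracks$frame))
  nt <- length(frames)
  sig_l <- lateral_resolution_um / 2.355
  sig_a <- axial_resolution_um / 2.355
  vol <- array(background, dim = c(ny, nx, nz, nt))
  half_l <- ceiling(4 * sig_l / px_um)
  half_a <- ceiling(4 * sig_a / z_step_um)
  for (it in seq_len(nt)) {
    pts <- tracks[tracks$frame == frames[it], ]
    for (p in seq_len(nrow(pts))) {
      cx <- pts$x_um[p] / px_um + 1; cy <- pts$y_um[p] / px_um + 1
      cz <- pts$z_um[p] / z_step_um + 1
      if (cx < 1 || cx > nx || cy < 1 || cy > ny || cz < 1 || cz > nz) next
      ix <- max(1, floor(cx - half_l)):min(nx, ceiling(cx + half_l))
      iy <- max(1, floor(cy - half_l)):min(ny, ceiling(cy + half_l))
      iz <- max(1, floor(cz - half_a)):min(nz, ceiling(cz + half_a))
      gx <- exp(-((ix - cx) * px_um)^2 / (2 * sig_l^2))
      gy <- exp(-((iy - cy) * px_um)^2 / (2 * sig_l^2))
      gz <- exp(-((iz - cz) * z_step_um)^2 / (2 * sig_a^2))
      blob <- outer(gy, gx) %o% gz
      vol[iy, ix, iz, it] <- vol[iy, ix, iz, it] + blob
    }
  }
  if (shot_noise) {
    vol[] <- withr::with_seed(derive_seed(seed, "render_volume_series"),
      stats::rpois(length(vol), lambda = vol * counts_scale) / counts_scale)
  }
  vol
}
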