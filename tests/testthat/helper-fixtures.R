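# Shared fixtures: the reference fluid/environment of the study conditions
# (water at 20 degC with the tabulated viscosity 1.002 mPa s, Earth
# gravity) and small simulation shortcuts.

ref_fluid <- function() fluid_medium(293.15, 1.002e-3, 998)

earth <- function(fluid = ref_fluid()) {
  mission_environment("Earth", gravity = 9.81, fluid = fluid)
}

# quick monodisperse population tibble
pop_tbl <- function(n, radius_um, density) {
  tibble::tibble(particle_id = seq_len(n), radius_um = radius_um,
                 density_kg_m3 = density)
}

# simulate n tracks of one species; noise off by default so estimator
# checks see the pure process
sim_tracks <- function(n, radius_um, density, duration, seed,
                       noise = FALSE, rec_args = list(), ...) {
  rec <- do.call(recording_spec, c(list(duration = duration), rec_args))
  sim <- simulate_population(pop_tbl(n, radius_um, density), rec, earth(),
                             seed = seed, ...)
  if (noise) sim$tracks <- apply_localization_noise(sim$tracks, rec,
                                                    seed = seed)
  sim
}

# brute-force optimal frame-to-frame assignment (test oracle for linking):
# enumerates all permutations, minimises total distance, gating at max_disp
oracle_link <- function(detections, max_disp) {
  frames <- sort(unique(detections$frame))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  prev <- detections[detections$frame == frames[1], ]
  prev$track_id <- seq_len(nrow(prev))
  out <- list(prev)
  for (f in frames[-1]) {
    cur <- detections[detections$frame == f, ]
    stopifnot(nrow(cur) == nrow(prev)) # fixture keeps counts constant
    best <- NULL; best_cost <- Inf
    for (p in perms(seq_len(nrow(cur)))) {
      d <- sqrt((prev$x_um - cur$x_um[p])^2 + (prev$y_um - cur$y_um[p])^2)
      if (all(d <= max_disp) && sum(d) < best_cost) {
        best <- p; best_cost <- sum(d)
      }
    }
    cur <- cur[best, ]
    cur$track_id <- prev$track_id
    out[[length(out) + 1]] <- cur
    prev <- cur
  }
  dplyr::arrange(dplyr::bind_rows(out), track_id, frame)
}
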