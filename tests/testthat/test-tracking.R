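# Projections, detection, greedy linking (against a brute-force assignment
# oracle) and drift handling.

test_that("maximum projections preserve single-voxel coordinates", {
  vol <- array(0, dim = c(12, 10, 8, 2))
  vol[5, 7, 3, 1] <- 1 # y=5, x=7, z=3
  vol[5, 7, 6, 2] <- 1
  xyt <- project_xyt(vol)
  expect_equal(which(xyt[, , 1] == 1, arr.ind = TRUE)[1, ],
               c(row = 5, col = 7))
  xzt <- project_xzt(vol)
  expect_equal(which(xzt[, , 1] == 1, arr.ind = TRUE)[1, ],
               c(row = 3, col = 7))
  expect_equal(which(xzt[, , 2] == 1, arr.ind = TRUE)[1, ],
               c(row = 6, col = 7))
  # max projection is idempotent: projecting an already-flat stack changes nothing
  flat <- array(xyt, dim = c(dim(xyt)[1:2], 1, 2))
  expect_equal(project_xyt(flat), xyt)
  expect_error(project_xyt(array(0, c(2, 2, 2))), "4D")
})

test_that("a sinking particle descends in the XZ projection", {
  rec <- recording_spec(frame_rate = 5, duration = 2, field_xy = c(30, 20),
                        chamber_depth = 40)
  tracks <- tibble::tibble(track_id = 1L, frame = 0:9, t_s = (0:9) / 5,
                           x_um = 15, y_um = 10, z_um = 5 + 3 * (0:9) / 5)
  vol <- render_volume_series(tracks, rec, px_um = 1, z_step_um = 1)
  xzt <- project_xzt(vol)
  zpos <- vapply(1:10, function(it)
    which(xzt[, , it] == max(xzt[, , it]), arr.ind = TRUE)[1, 1],
    numeric(1))
  expect_true(all(diff(zpos) >= 0))
  expect_gt(zpos[10] - zpos[1], 4)
})

test_that("detection finds weighted centroids to sub-pixel accuracy", {
  rec <- recording_spec(frame_rate = 1, duration = 1, field_xy = c(120, 60),
                        chamber_depth = 10)
  tracks <- tibble::tibble(track_id = 1L, frame = 0L, t_s = 0,
                           x_um = 100.0, y_um = 50.0, z_um = 5)
  vol <- render_volume_series(tracks, rec, px_um = 0.25, z_step_um = 2,
                              background = 0)
  det <- detect_particles(project_xyt(vol)[, , 1], px = c(0.25, 0.25))
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_um - 100.0), 0.1)
  expect_lt(abs(det$y_um - 50.0), 0.1)
  # blank frame: zero detections, no error
  blank <- matrix(0.1, 50, 50)
  expect_equal(nrow(detect_particles(blank)), 0)
  # two well-separated blobs, absolute threshold
  img <- matrix(0, 60, 60)
  img[20, 15] <- 1; img[45, 50] <- 0.9
  det2 <- detect_particles(img, threshold = 0.5, px = c(1, 1))
  expect_equal(nrow(det2), 2)
})

test_that("greedy linking recovers single and well-separated tracks", {
  # one particle drifting slowly: one track spanning all frames
  d1 <- tibble::tibble(frame = 0:9, x_um = (0:9) * 0.5, y_um = 2)
  t1 <- link_detections(d1, max_disp = 2)
  expect_equal(dplyr::n_distinct(t1$track_id), 1)
  expect_equal(nrow(t1), 10)
  # two far-apart particles: two tracks, no identity switches
  d2 <- dplyr::bind_rows(d1, dplyr::mutate(d1, y_um = 50))
  t2 <- link_detections(d2, max_disp = 2)
  expect_equal(dplyr::n_distinct(t2$track_id), 2)
  purity <- t2 |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(k = dplyr::n_distinct(y_um))
  expect_true(all(purity$k == 1)) # no identity switches
  # a jump beyond max_disp starts a new track
  d3 <- tibble::tibble(frame = 0:3, x_um = c(0, 0.5, 30, 30.5), y_um = 0)
  t3 <- link_detections(d3, max_disp = 2)
  expect_equal(dplyr::n_distinct(t3$track_id), 2)
})

test_that("gap closing bridges short dropouts", {
  d <- tibble::tibble(frame = c(0, 1, 2, 5, 6), x_um = c(0, 1, 2, 5, 6),
                      y_um = 0)
  linked <- link_detections(d, max_disp = 4, gap_max = 2)
  expect_equal(dplyr::n_distinct(linked$track_id), 1)
  strict <- link_detections(d, max_disp = 4, gap_max = 0)
  expect_equal(dplyr::n_distinct(strict$track_id), 2)
})

test_that("greedy linking matches the brute-force assignment oracle", {
  env <- earth()
  rec <- recording_spec(duration = 1)
  set.seed(41)
  for (rep in 1:5) {
    sim <- simulate_population(
      tibble::tibble(particle_id = 1:3, radius_um = 0.5,
                     density_kg_m3 = 1050),
      rec, env, seed = 41 + rep)
    det <- sim$tracks |>
      dplyr::transmute(frame, x_um, y_um)
    linked <- link_detections(det, max_disp = 5)
    oracle <- oracle_link(det, max_disp = 5)
    # same partition of detections into tracks (ids may be permuted)
    key <- function(tb) unname(split(paste(tb$frame, round(tb$x_um, 6)),
                                     tb$track_id))
    expect_setequal(key(linked), key(oracle))
  }
})

test_that("linking is invariant to detection order within frames", {
  env <- earth()
  sim <- simulate_population(pop_tbl(4, 0.5, 1050),
                             recording_spec(duration = 1), env, seed = 43)
  det <- dplyr::transmute(sim$tracks, frame, x_um, y_um)
  set.seed(2)
  shuffled <- det[sample(nrow(det)), ]
  a <- link_detections(det, max_disp = 5)
  b <- link_detections(shuffled, max_disp = 5)
  key <- function(tb) unname(split(paste(tb$frame, round(tb$x_um, 6)),
                                   tb$track_id))
  expect_setequal(key(a), key(b))
})

test_that("detect-link on a noise-free rendering recovers truth positions", {
  rec <- recording_spec(frame_rate = 5, duration = 2, field_xy = c(60, 60),
                        chamber_depth = 20, sigma_xy = 0, sigma_z = 0)
  env <- earth()
  pts <- tibble::tibble(particle_id = 1:3, radius_um = 0.75,
                        density_kg_m3 = 1050)
  sim <- simulate_population(pts, rec, env, seed = 47)
  # clamp inside the small rendered field
  tr <- dplyr::mutate(sim$tracks,
                      x_um = 10 + (track_id - 1) * 18 + (x_um - mean(x_um)) / 50,
                      y_um = 30 + (y_um - mean(y_um)) / 50,
                      z_um = 10)
  vol <- render_volume_series(tr, rec, px_um = 0.5, z_step_um = 2,
                              background = 0)
  det <- detect_series(project_xyt(vol), px = c(0.5, 0.5))
  linked <- link_detections(det, max_disp = 3, frame_rate = 5)
  expect_equal(dplyr::n_distinct(linked$track_id), 3)
  merged <- dplyr::inner_join(linked, tr, by = "frame",
                              relationship = "many-to-many") |>
    dplyr::group_by(track_id.x, frame) |>
    dplyr::slice_min(abs(x_um.x - x_um.y), n = 1) |>
    dplyr::ungroup()
  rmse <- sqrt(mean((merged$x_um.x - merged$x_um.y)^2 +
                      (merged$y_um.x - merged$y_um.y)^2))
  expect_lt(rmse, 0.3)
})

test_that("uniform drift is estimated exactly and subtraction idempotent", {
  # three stationary-in-co-moving-frame tracks sharing velocity u
  u <- c(0.8, -0.4)
  base <- tidyr::crossing(track_id = 1:3, frame = 0:20) |>
    dplyr::mutate(t_s = frame / 15,
                  x_um = 10 * track_id + u[1] * t_s,
                  y_um = 5 * track_id + u[2] * t_s,
                  z_um = 0)
  drift <- estimate_drift(base)
  expect_equal(mean(drift$dx_um) * 15, u[1], tolerance = 1e-10)
  expect_equal(mean(drift$dy_um) * 15, u[2], tolerance = 1e-10)
  corrected <- subtract_drift(base, drift)
  # residual tracks stationary in the ensemble mean
  expect_lt(max(abs(diff(corrected$x_um[corrected$track_id == 2]))), 1e-10)
  drift2 <- estimate_drift(corrected)
  expect_lt(max(abs(c(drift2$dx_um, drift2$dy_um))), 1e-10)
})

test_that("pure Brownian ensembles show no spurious drift", {
  sim <- sim_tracks(200, 0.5, 998, duration = 5, seed = 53)
  drift <- estimate_drift(sim$tracks)
  dt <- 1 / 15
  v_drift <- c(mean(drift$dx_um), mean(drift$dy_um)) / dt
  D <- diffusion_coefficient(0.5e-6, earth()$fluid) * 1e12
  se <- sqrt(2 * D * dt) / dt / sqrt(200 * (nrow(drift)))
  expect_lt(max(abs(v_drift)), 3 * se)
})

test_that("degenerate input yields zero drift with a warning", {
  single <- tibble::tibble(track_id = 1L, frame = 0L, t_s = 0,
                           x_um = 1, y_um = 1, z_um = 0)
  expect_warning(d <- estimate_drift(single), "undefined")
  expect_true(all(d$n == 0))
})
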