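# Per-track estimators: MSD diffusivity, Walker sizing, axial velocity,
# the chained per-particle estimate, outlier filtering, summaries.

test_that("two-point 1D track gives the definitional diffusivity", {
  dt <- 1 / 15
  delta <- 0.3
  tr <- tibble::tibble(track_id = 1L, frame = 0:1, t_s = c(0, dt),
                       x_um = c(0, delta), y_um = 0, z_um = 0)
  expect_equal(msd_diffusivity(tr, dims = 1, max_lag = 1),
               delta^2 / (2 * dt), tolerance = 1e-12)
  expect_warning(expect_true(is.na(msd_diffusivity(tr, max_lag = 3))),
                 "too short")
})

test_that("MSD diffusivity is unbiased on pure Brownian tracks", {
  env <- earth()
  # ~100 tracks x 150 steps = 1.5e4 steps total
  sim <- sim_tracks(100, 0.5, 998, duration = 10, seed = 61)
  D_true <- diffusion_coefficient(0.5e-6, env$fluid) * 1e12
  per <- sim$tracks |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(D = msd_diffusivity(dplyr::pick(dplyr::everything()),
                                         dims = 2, max_lag = 3))
  se <- sd(per$D) / sqrt(nrow(per))
  expect_lt(abs(mean(per$D) - D_true), 3 * se)
})

test_that("MSD of drift-free simulations matches 2 D dims dt lag", {
  env <- earth()
  sim <- sim_tracks(150, 0.5, 998, duration = 8, seed = 67)
  D <- diffusion_coefficient(0.5e-6, env$fluid) * 1e12
  dt <- 1 / 15
  for (k in c(1, 3, 5)) {
    msd2 <- sim$tracks |>
      dplyr::group_by(track_id) |>
      dplyr::reframe(d = (x_um - dplyr::lag(x_um, k))^2 +
                       (y_um - dplyr::lag(y_um, k))^2) |>
      dplyr::pull(d) |> mean(na.rm = TRUE)
    expect_equal(msd2, 2 * D * 2 * dt * k, tolerance = 0.05)
  }
})

test_that("pure linear motion after drift subtraction has near-zero D", {
  tr <- tibble::tibble(track_id = 1L, frame = 0:50, t_s = (0:50) / 15,
                       x_um = 2 * (0:50) / 15, y_um = -(0:50) / 15, z_um = 0)
  corrected <- subtract_drift(tr, estimate_drift(tr))
  expect_lt(msd_diffusivity(corrected, dims = 2, max_lag = 3), 1e-10)
})

test_that("z velocity is the OLS slope with sinking positive", {
  tr <- tibble::tibble(track_id = 1L, frame = 0:30, t_s = (0:30) / 15,
                       x_um = 0, y_um = 0, z_um = 2.36 * (0:30) / 15)
  expect_equal(z_velocity(tr), 2.36, tolerance = 1e-10)
  expect_warning(v <- z_velocity(tr[1, ]), "2 points")
  expect_true(is.na(v))
  # z-axis convention flip changes the sign
  up <- dplyr::mutate(tr, z_um = -z_um)
  expect_equal(z_velocity(up), -2.36, tolerance = 1e-10)
})

test_that("population z drift weights tracks by length", {
  mk <- function(id, n, slope) tibble::tibble(
    track_id = id, frame = 0:n, t_s = (0:n) / 15, x_um = 0, y_um = 0,
    z_um = slope * (0:n) / 15)
  same <- dplyr::bind_rows(mk(1, 30, 1.5), mk(2, 30, 1.5))
  expect_equal(population_z_drift(same), 1.5, tolerance = 1e-10)
  mixed <- dplyr::bind_rows(mk(1, 90, 1), mk(2, 30, 4))
  expect_equal(population_z_drift(mixed),
               (91 * 1 + 31 * 4) / (91 + 31), tolerance = 1e-10)
})

test_that("neutral ensembles drift by less than 3 SE", {
  sim <- sim_tracks(300, 0.5, 998, duration = 10, seed = 71)
  per <- sim$tracks |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(v = z_velocity(dplyr::pick(dplyr::everything())))
  se <- sd(per$v) / sqrt(nrow(per))
  expect_lt(abs(population_z_drift(sim$tracks)), 3 * se)
})

test_that("Walker sizing recovers a monodisperse 1.0 um population", {
  env <- earth()
  sim <- sim_tracks(400, 0.5, 1050, duration = 10, seed = 73)
  wd <- walker_diameters(sim$tracks, env$fluid)
  expect_equal(median(wd$diameter_um), 1.0, tolerance = 0.05)
  h <- attr(wd, "histogram")
  expect_equal(h$bin_right - h$bin_left, rep(0.1, nrow(h)))
  # histogram strongly peaked at the 1.0 um bin
  peak <- h$mid[which.max(h$count)]
  expect_lt(abs(peak - 1.0), 0.1)
  expect_gt(max(h$count) / nrow(wd), 0.15)
})

test_that("single-track Walker estimate sits within 2 SE of truth", {
  env <- earth()
  sim <- sim_tracks(1, 0.5, 1050, duration = 40, seed = 79)
  n_steps <- nrow(sim$tracks) - 1
  wd <- walker_diameters(sim$tracks, env$fluid)
  # D_ML is a mean of n exponentials: relative SE = 1/sqrt(n)
  expect_lt(abs(wd$diameter_um - 1.0), 2 / sqrt(n_steps) * 1.0 * 1.2)
})

test_that("cluster populations yield diameter modes at monomer increments", {
  env <- earth()
  pop <- sample_population(
    population_spec("Anabaena Gas Vesicles", 300, size_cluster(0.8, 3), env),
    seed = 83)
  rec <- recording_spec(duration = 15)
  sim <- simulate_population(pop, rec, env, seed = 83)
  wd <- walker_diameters(sim$tracks, env$fluid)
  truth_d <- 2 * pop$radius_um[match(wd$track_id, pop$particle_id)]
  for (k in 1:3) {
    sub <- wd$diameter_um[truth_d == 0.8 * k]
    expect_equal(median(sub), 0.8 * k, tolerance = 0.12)
  }
})

test_that("the chained per-particle estimate inverts a drift-only track", {
  sim <- sim_tracks(1, 0.75, 998 + 1932, duration = 10, seed = 89,
                    D_override = 0)
  est <- estimate_particles(sim$tracks, earth(), radius_source = "fixed",
                            fixed_radius_um = 0.75,
                            subtract_xy_drift = FALSE)
  expect_equal(est$vz_um_s, 2.364386, tolerance = 1e-6)
  expect_equal(est$delta_rho_kg_m3, 1932, tolerance = 0.01 * 1932)
  expect_equal(est$strouhal, 0.161, tolerance = 0.02)
  expect_equal(est$regime, "mixed") # Sr ~ 0.16 sits in the mixed band
})

test_that("estimate_particles is deterministic and flags bad tracks", {
  sim <- sim_tracks(5, 0.5, 1050, duration = 5, seed = 97)
  stub <- tibble::tibble(track_id = 99L, frame = 0:1, t_s = c(0, 1 / 15),
                         x_um = c(0, 1), y_um = 0, z_um = c(0, 1))
  tracks <- dplyr::bind_rows(sim$tracks, stub)
  e1 <- estimate_particles(tracks, earth())
  e2 <- estimate_particles(tracks, earth())
  expect_identical(tidy(e1), tidy(e2))
  bad <- e1[e1$track_id == 99, ]
  expect_match(bad$flags, "short_or_nonpositive_D")
  expect_true(is.na(bad$D_um2_s))
  expect_false(is.na(bad$vz_um_s)) # the z stage still ran
  # neutral particle: infinite Strouhal, brownian regime
  neutral <- tibble::tibble(track_id = 1L, frame = 0:20, t_s = (0:20) / 15,
                            x_um = cumsum(c(0, rep(0.2, 20))),
                            y_um = cumsum(c(0, rep(-0.2, 20))) , z_um = 3)
  en <- estimate_particles(neutral, earth(), radius_source = "fixed",
                           fixed_radius_um = 0.5, subtract_xy_drift = FALSE)
  expect_identical(en$strouhal, Inf)
  expect_identical(en$regime, "brownian")
})

test_that("outlier filtering removes planted diffusivity outliers", {
  est <- tibble::tibble(track_id = 1:4,
                        D_um2_s = c(0.4, 0.45, 1.5, 0.38))
  expect_message(kept <- filter_outliers(est, "D_um2_s", 1.20), "removed 1")
  expect_equal(kept$track_id, c(1, 2, 4))
  expect_identical(filter_outliers(est, "D_um2_s", Inf), est)
  expect_warning(none <- filter_outliers(est, "D_um2_s", 0.1), "All estimates")
  expect_equal(nrow(none), 0)
  expect_error(filter_outliers(est, "bogus", 1), "Unknown quantity")
})

test_that("population summaries report mean, median, t-CI and histogram", {
  est <- tibble::tibble(v = c(1, 2, 3))
  s <- summarize_population(est, "v")
  expect_equal(s$mean, 2)
  expect_equal(s$median, 2)
  expect_equal(s$ci_half_width, qt(0.975, 2) * sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(sum(s$histogram[[1]]$count), 3)
  # CI half-width shrinks like 1/sqrt(n)
  set.seed(3)
  x <- rnorm(6400)
  h1 <- summarize_population(tibble::tibble(v = x[1:100]), "v")$ci_half_width
  h2 <- summarize_population(tibble::tibble(v = x), "v")$ci_half_width
  expect_equal(h1 / h2, 8, tolerance = 0.25)
  # n = 1: no CI, still a summary
  s1 <- summarize_population(tibble::tibble(v = 5), "v")
  expect_true(is.na(s1$ci_half_width))
  expect_equal(s1$mean, 5)
})

test_that("tidy and glance views expose the population at a glance", {
  sim <- sim_tracks(10, 0.5, 1050, duration = 5, seed = 101)
  est <- estimate_particles(sim$tracks, earth())
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "pm_estimates"))
  gl <- glance(est)
  expect_equal(gl$n_tracks, 10)
  expect_true(all(c("mean_D_um2_s", "mean_vz_um_s") %in% names(gl)))
})
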