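# Simulators: dwell samples, track sets, movies, catalysis and adsorption
# traces.

test_that("dwell sample mean matches the exponential mean in the fine-grid limit", {
  s <- simulate_dwell_sample(1e5, alpha = 1, tau1_s = 2,
                             frame_interval_s = 1e-4, min_frames = 0,
                             seed = 11)
  expect_equal(mean(s$durations), 2, tolerance = 0.02)
})

test_that("fixed seed gives bit-identical simulator output", {
  a <- simulate_dwell_sample(500, 0.5, 0.5, 2, seed = 3)
  b <- simulate_dwell_sample(500, 0.5, 0.5, 2, seed = 3)
  expect_identical(a, b)
  acq <- acquisition_params(field_area_um2 = 100, n_frames = 50)
  cfg <- binding_sim_config(arrival_rate = 0.05, seed = 9)
  expect_identical(simulate_track_set(cfg, acq)$tracks,
                   simulate_track_set(cfg, acq)$tracks)
  tr1 <- simulate_adsorption_trace(0.1, 1, 0:60, noise_sd = 0.02, seed = 4)
  tr2 <- simulate_adsorption_trace(0.1, 1, 0:60, noise_sd = 0.02, seed = 4)
  expect_identical(tr1, tr2)
})

test_that("simulators do not disturb the caller's RNG stream", {
  set.seed(42)
  x1 <- runif(3)
  set.seed(42)
  invisible(simulate_dwell_sample(100, 0.5, 0.5, 2, seed = 1))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("degenerate mixture (tau1 = tau2) is a single exponential", {
  s <- simulate_dwell_sample(1e4, alpha = 0.5, tau1_s = 1, tau2_s = 1,
                             frame_interval_s = 1e-4, min_frames = 0,
                             seed = 5)
  ks <- suppressWarnings(ks.test(s$durations, pexp, rate = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("recorded dwells are frame-quantized and respect the 2-frame minimum", {
  s <- simulate_dwell_sample(2000, 0.54, 0.55, 1.44, 0.052, min_frames = 2,
                             seed = 6)
  expect_equal(s$n, 2000L)
  expect_true(all(s$durations >= 0.052 - 1e-12))
  k <- s$durations / 0.052
  expect_equal(k, round(k), tolerance = 1e-9)
  dropped <- simulate_dwell_sample(2000, 0.54, 0.55, 1.44, 0.052,
                                   min_frames = 2, short_events = "drop",
                                   seed = 6)
  expect_lt(dropped$n, 2000L)
})

test_that("dwell simulator validates parameters", {
  expect_error(simulate_dwell_sample(10, 1.2, 1), "alpha")
  expect_error(simulate_dwell_sample(10, 0.5, -1), "tau1_s")
  expect_error(simulate_dwell_sample(10, 0.5, 1, frame_interval_s = 0),
               "frame_interval_s")
})

test_that("empirical survival converges to the mixture survival", {
  n <- 2e4
  s <- simulate_dwell_sample(n, 0.54, 0.55, 1.44, frame_interval_s = 1e-3,
                             min_frames = 0, seed = 12)
  tg <- seq(0, 6, by = 0.05)
  emp <- vapply(tg, function(t) mean(s$durations >= t), numeric(1))
  gap <- max(abs(emp - oracle_mix_survival(tg, 0.54, 0.55, 1.44)))
  expect_lt(gap, 3 / sqrt(n))
})

test_that("zero arrival rate yields an empty track set", {
  acq <- acquisition_params(field_area_um2 = 100, n_frames = 20)
  ts <- simulate_track_set(binding_sim_config(arrival_rate = 0, seed = 1),
                           acq)
  expect_s3_class(ts, "TrackSet")
  expect_equal(nrow(ts$tracks), 0L)
})

test_that("track steps have MSD 4*D*dt and pass a Rayleigh fit", {
  acq <- acquisition_params(0.052, field_area_um2 = 400, n_frames = 400)
  cfg <- binding_sim_config(arrival_rate = 0.02, dwell_alpha = 1,
                            dwell_tau1_s = 1, dwell_tau2_s = 1,
                            diff_alpha = 1, D1_um2_s = 1, D2_um2_s = 1,
                            seed = 21)
  ts <- simulate_track_set(cfg, acq)
  st <- compute_steps(ts)
  expect_gt(st$n_steps, 2000)
  se <- sd(st$r^2) / sqrt(st$n_steps)
  expect_lt(abs(mean(st$r^2) - 4 * 1 * 0.052), 3 * se)
  sigma <- sqrt(2 * 1 * 0.052)
  ks <- suppressWarnings(
    ks.test(st$r, function(q) 1 - exp(-q^2 / (2 * sigma^2))))
  expect_gt(ks$p.value, 0.01)
})

test_that("track frames stay within the movie and ids are unique per track", {
  acq <- acquisition_params(field_area_um2 = 200, n_frames = 30)
  ts <- simulate_track_set(binding_sim_config(arrival_rate = 0.1, seed = 2),
                           acq)
  expect_true(all(ts$tracks$frame >= 0 & ts$tracks$frame < 30))
  per <- split(ts$tracks$frame, ts$tracks$track_id)
  expect_true(all(vapply(per, function(f) all(diff(f) > 0), logical(1))))
})

test_that("rebinding extends tracks beyond the no-hopping dwell", {
  acq <- acquisition_params(field_area_um2 = 200, n_frames = 200)
  base <- binding_sim_config(arrival_rate = 0.05, dwell_alpha = 1,
                             dwell_tau1_s = 0.3, dwell_tau2_s = 0.3,
                             seed = 31)
  hop <- binding_sim_config(arrival_rate = 0.05, dwell_alpha = 1,
                            dwell_tau1_s = 0.3, dwell_tau2_s = 0.3,
                            rebind_prob = 0.8, rebind_radius_um = 0.05,
                            seed = 31)
  d0 <- mean(tapply(simulate_track_set(base, acq)$tracks$frame,
                    simulate_track_set(base, acq)$tracks$track_id, length))
  d1 <- mean(tapply(simulate_track_set(hop, acq)$tracks$frame,
                    simulate_track_set(hop, acq)$tracks$track_id, length))
  expect_gt(d1, d0 * 1.5)
})

test_that("empty track set renders to pure background noise", {
  acq <- acquisition_params(image_shape = c(32, 32), n_frames = 5)
  ts <- track_set(data.frame(track_id = integer(), frame = integer(),
                             x_um = numeric(), y_um = numeric()), acq)
  mv <- render_movie(ts, acq, imaging_params(1.5, 500, background_photons = 10,
                                             read_noise_sd = 0, seed = 1))
  expect_equal(mean(mv), 10, tolerance = 0.05)
})

test_that("noiseless rendered spot has centroid at the particle position", {
  acq <- acquisition_params(pixel_size_um = 0.1, image_shape = c(48, 48),
                            n_frames = 1)
  ts <- track_set(data.frame(track_id = 1L, frame = 0L,
                             x_um = 2.03, y_um = 3.17), acq)
  mv <- render_movie(ts, acq,
                     imaging_params(psf_sigma_px = 1.5,
                                    photons_per_particle = 1e5,
                                    background_photons = 0,
                                    read_noise_sd = 0, seed = 1))
  img <- unclass(mv)[, , 1]
  xs <- 0:(ncol(img) - 1); ys <- 0:(nrow(img) - 1)
  cx <- sum(colSums(img) * xs) / sum(img)
  cy <- sum(rowSums(img) * ys) / sum(img)
  expect_equal(cx, 20.3, tolerance = 1e-6)
  expect_equal(cy, 31.7, tolerance = 1e-6)
})

test_that("movie TIFF round-trips through disk", {
  acq <- acquisition_params(image_shape = c(16, 16), n_frames = 3)
  ts <- track_set(data.frame(track_id = 1L, frame = 0:2,
                             x_um = 0.8, y_um = 0.8), acq)
  mv <- render_movie(ts, acq, imaging_params(1.2, 300, 5, 1, seed = 2))
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(mv, path)
  back <- read_movie_tiff(path, 0.1, 0.052)
  expect_equal(dim(back), dim(mv))
  expect_equal(unclass(back), pmin(pmax(round(unclass(mv)), 0), 65535),
               ignore_attr = TRUE)
})

test_that("catalysis trace follows the depletion closed form and conserves substrate", {
  cfg <- catalysis_sim_config(57, 0.2, 2.8e4, t_grid_s = seq(0, 5000, 10),
                              noise_sd_frac = 0, seed = 1)
  tr <- simulate_catalysis_trace(cfg)
  truth <- attr(tr, "truth")
  expect_equal(truth$initial_rate, 11.4)
  expect_true(all(truth$product_density <= 2.8e4 + 1e-9))
  # numerical initial slope ~ kcat * E
  expect_equal((truth$product_density[2] - truth$product_density[1]) / 10,
               11.4, tolerance = 0.01)
  flat <- simulate_catalysis_trace(
    catalysis_sim_config(0, 0.2, 2.8e4, t_grid_s = 0:10, seed = 1))
  expect_true(all(flat$intensities == 0))
})

test_that("adsorption trace matches its closed form", {
  tr <- simulate_adsorption_trace(0.1, 1, t_grid_s = seq(0, 60, 0.1))
  i10 <- which.min(abs(tr$times_s - 10))
  expect_equal(tr$intensities[i10], 1 - exp(-1), tolerance = 1e-12)
})

test_that("pooled step sample matches the Rayleigh mixture density", {
  s <- simulate_step_sample(5e4, 0.6, 0.23, 0.88, 0.052, seed = 13)
  expect_equal(s$n_steps, 5e4)
  m2 <- 0.6 * 4 * 0.23 * 0.052 + 0.4 * 4 * 0.88 * 0.052
  expect_equal(mean(s$r^2), m2, tolerance = 0.03)
})
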