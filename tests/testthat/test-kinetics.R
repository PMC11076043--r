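# Sensor-trace normalization, product conversion, initial rates, kcat,
# adsorption fits, and synergy folds.

test_that("normalization maps baseline to 0 and plateau to 1", {
  tr <- sensor_trace(0:100, c(rep(100, 20), seq(100, 600, length.out = 61),
                              rep(600, 20)))
  norm <- normalize_sensor_trace(tr, c(0, 19), c(81, 100))
  expect_equal(norm$intensities[1], 0)
  expect_equal(norm$intensities[101], 1)
  i350 <- which.min(abs(tr$intensities - 350))
  expect_equal(norm$intensities[i350], 0.5, tolerance = 0.02)
  flat <- sensor_trace(0:100, rep(100, 101))
  expect_error(normalize_sensor_trace(flat, c(0, 19), c(81, 100)),
               "did not complete")
  expect_error(normalize_sensor_trace(tr, c(0, 50), c(40, 100)), "overlap")
})

test_that("normalized catalysis trace matches P(t)/S0 within the noise scale", {
  kk <- 57 * 0.2 / 2.8e4
  cfg <- catalysis_sim_config(57, 0.2, 2.8e4,
                              t_grid_s = seq(0, 6 / kk, length.out = 1500),
                              noise_sd_frac = 0.02, seed = 31)
  tr <- simulate_catalysis_trace(cfg, plateau_au = 350)
  norm <- normalize_sensor_trace(tr, c(0, 0), c(5.4 / kk, 6 / kk))
  frac <- attr(tr, "truth")$product_density / 2.8e4
  expect_lt(stats::quantile(abs(norm$intensities - frac), 0.95), 3 * 0.02)
})

test_that("product conversion scales, clips, and preserves monotonicity", {
  norm <- sensor_trace(0:10, seq(0, 1.05, length.out = 11))
  pt <- trace_to_product_density(norm, 2.8e4)
  expect_equal(pt$product_density[6], 0.525 * 2.8e4)
  expect_true(all(pt$product_density <= 2.8e4))
  expect_true(all(diff(pt$product_density) >= 0))
  raw <- sensor_trace(0:10, seq(-1, 2, length.out = 11))
  expect_error(trace_to_product_density(raw, 2.8e4), "normalized")
})

test_that("initial rate recovers exact and depletion-model slopes", {
  t <- seq(0, 100, by = 1)
  lin <- structure(list(times_s = t, product_density = 5 * t,
                        total_density = 1e4), class = "ProductTrace")
  expect_equal(initial_rate(lin, 0.1)$rate, 5)
  # noiseless depletion model: secant bias under a 10% cap is below 5%
  S0 <- 2.8e4; k <- 11.4 / S0
  td <- seq(0, 3 / k, length.out = 2000)
  dep <- structure(list(times_s = td,
                        product_density = S0 * (1 - exp(-k * td)),
                        total_density = S0), class = "ProductTrace")
  ir <- initial_rate(dep, 0.1)
  # closed-form oracle: continuous-time OLS slope of S0(1 - e^(-kt)) over
  # the capped window [0, T], T = ln(1/0.9)/k (10% depletion)
  T10 <- log(1 / 0.9) / k
  tbar <- T10 / 2
  num <- integrate(function(x) (x - tbar) * S0 * (1 - exp(-k * x)), 0, T10,
                   rel.tol = 1e-10)$value
  den <- integrate(function(x) (x - tbar)^2, 0, T10, rel.tol = 1e-10)$value
  expect_equal(ir$rate, num / den, tolerance = 5e-3)
  expect_lte(ir$rate, 11.4)        # the secant underestimates the tangent
  expect_gt(ir$rate, 11.4 * 0.94)  # bias stays ~5% under a 10% cap
  flat <- structure(list(times_s = t, product_density = rep(0, length(t)),
                         total_density = 1e4), class = "ProductTrace")
  expect_equal(initial_rate(flat, 0.1)$rate, 0)
  short <- structure(list(times_s = 0:3, product_density = c(0, 1, 2, 3) * 1e3,
                          total_density = 1e4), class = "ProductTrace")
  expect_error(initial_rate(short, 0.1), "5 points")
})

test_that("kcat arithmetic reproduces the printed per-enzyme rates", {
  expect_equal(compute_kcat(11.4, 0.2), 57)
  expect_equal(compute_kcat(0.6, 0.2), 3)
  expect_equal(compute_kcat(0, 0.2), 0)
  expect_error(compute_kcat(1, 0), "enzyme_density")
})

test_that("trace-to-kcat pipeline recovers the generating kcat within 10%", {
  kcats <- vapply(1:20, function(seed) {
    kk <- 57 * 0.2 / 2.8e4
    cfg <- catalysis_sim_config(57, 0.2, 2.8e4,
                                t_grid_s = seq(0, 6 / kk, length.out = 2000),
                                noise_sd_frac = 0.02, seed = seed)
    tr <- simulate_catalysis_trace(cfg)
    estimate_kcat_from_trace(tr, 2.8e4, 0.2)$kcat
  }, numeric(1))
  expect_lt(abs(median(kcats) / 57 - 1), 0.1)
})

test_that("kcat is invariant to the arbitrary sensor intensity scale", {
  kk <- 57 * 0.2 / 2.8e4
  t_grid <- seq(0, 6 / kk, length.out = 1500)
  k <- vapply(c(1, 40, 5000), function(plateau) {
    cfg <- catalysis_sim_config(57, 0.2, 2.8e4, t_grid, 0.01, seed = 77)
    tr <- simulate_catalysis_trace(cfg, plateau_au = plateau)
    estimate_kcat_from_trace(tr, 2.8e4, 0.2)$kcat
  }, numeric(1))
  expect_equal(k[2], k[1], tolerance = 1e-9)
  expect_equal(k[3], k[1], tolerance = 1e-9)
})

test_that("adsorption fit round-trips noiseless and noisy traces", {
  tr <- simulate_adsorption_trace(0.05, 2.5, seq(0, 120, 0.2))
  fit <- fit_adsorption(tr)
  expect_equal(fit$k_obs, 0.05, tolerance = 1e-6)
  expect_equal(fit$plateau, 2.5, tolerance = 1e-6)
  expect_error(fit_adsorption(sensor_trace(0:10, rep(1, 11))), "degenerate")
  ks <- vapply(1:20, function(seed) {
    tn <- simulate_adsorption_trace(0.1, 1, seq(0, 60, 0.1),
                                    noise_sd = 0.02, seed = seed)
    fit_adsorption(tn)$k_obs
  }, numeric(1))
  expect_lt(abs(median(ks) / 0.1 - 1), 0.05)
  expect_warning(
    fit_adsorption(simulate_adsorption_trace(0.01, 1, seq(0, 50, 0.5))),
    "3/k_obs")
})

test_that("synergy fold is the ratio of per-enzyme rates", {
  # per-enzyme rates 13 vs 3 at a 1.8-fold density difference
  E <- 0.2
  expect_equal(synergy_fold(13 * 1.8 * E, 3 * E, 1.8 * E, E), 13 / 3)
  expect_equal(synergy_fold(1, 1, 1, 1), 1)
  # doubling both test rate and test density leaves the fold unchanged
  expect_equal(synergy_fold(2 * 13 * 1.8 * E, 3 * E, 2 * 1.8 * E, E), 13 / 3)
  expect_error(synergy_fold(1, 0, 1, 1), "positive")
})

test_that("two-phase synergy simulation returns the density-normalized fold", {
  folds <- vapply(1:10, function(seed) {
    S0 <- 2.8e4; E <- 0.2
    k_ref <- 3 * E / S0
    ref_cfg <- catalysis_sim_config(3, E, S0,
                                    seq(0, 6 / k_ref, length.out = 1500),
                                    0.02, seed = seed)
    k_test <- 13 * 1.8 * E / S0
    test_cfg <- catalysis_sim_config(13, 1.8 * E, S0,
                                     seq(0, 6 / k_test, length.out = 1500),
                                     0.02, seed = seed + 1000)
    r_ref <- estimate_kcat_from_trace(simulate_catalysis_trace(ref_cfg),
                                      S0, E)$initial_rate
    r_test <- estimate_kcat_from_trace(simulate_catalysis_trace(test_cfg),
                                       S0, 1.8 * E)$initial_rate
    synergy_fold(r_test, r_ref, 1.8 * E, E)
  }, numeric(1))
  expect_equal(median(folds), 13 / 3, tolerance = 0.05)
})

test_that("sensor trace CSV round-trips", {
  tr <- simulate_adsorption_trace(0.1, 1, 0:20, noise_sd = 0.01, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_equal(back$times_s, tr$times_s)
  expect_equal(back$intensities, tr$intensities, tolerance = 1e-12)
})
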