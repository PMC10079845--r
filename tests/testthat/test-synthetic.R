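test_that("generated soils honour the compositional constraints", {
  s <- make_soil("oxisol_default")
  expect_equal(bulk_soil_material(s)$density, 2.04, tolerance = 1e-3)
  r1 <- make_soil("randomized", seed = 4)
  r2 <- make_soil("randomized", seed = 4)
  expect_identical(r1, r2)
  r3 <- make_soil("randomized", seed = 5)
  expect_false(identical(r1$solid_fractions, r3$solid_fractions))
  for (s in list(r1, r3)) {
    expect_equal(sum(s$solid_fractions), 1, tolerance = 1e-9)
    expect_gte(sum(s$solid_fractions[c("O", "Si", "Al")]), 0.88)
    expect_length(s$solid_fractions, 9)
  }
})

test_that("packaged scenarios carry the experimental protocol parameters", {
  e1 <- fixture_scenario("E1R1")
  expect_equal(e1$meta$si_filter_mm, 0.36)
  expect_equal(e1$protocol$current_ma, 10)
  expect_equal(e1$protocol$full_time_s, 41.35)
  expect_equal(e1$protocol$start_angle_deg, 180)
  expect_equal(e1$beam$fov_mm, 2.9)
  expect_equal(2 * e1$geometry$soil_radius, 2.9)
  e3 <- fixture_scenario("E3R2")
  expect_equal(e3$protocol$current_ma, 40)
  expect_equal(e3$protocol$full_time_s, 7.68)
  expect_equal(e3$protocol$start_angle_deg, 240)
  expect_equal(e3$meta$si_filter_mm, 2.45)
  expect_error(make_scenario("E9R9"), "valid names")
})

test_that("cone-beam scenarios pair sample size, energy and FOV", {
  d <- fixture_scenario("mognoB_d_high")
  expect_equal(2 * d$geometry$soil_radius, 40)
  expect_equal(d$meta$si_filter_mm, 7.07)
  expect_equal(d$beam$fov_mm, 40)
  expect_equal(d$geometry$root_offset, 0)
  dz <- make_scenario("mognoB_d_high", fov_mm = 0.0775)
  expect_equal(dz$beam$fov_mm, 0.0775, tolerance = 1e-9)
  expect_equal(2 * dz$geometry$soil_radius, 40)
  # quoted at-sample fluxes are preserved after filtering
  expect_equal(spectrum_stats(d$spectrum)$total, 1.47e8, tolerance = 1e-9)
  lo <- fixture_scenario("mognoB_b_low")
  expect_equal(spectrum_stats(lo$spectrum)$total, 6.01e9, tolerance = 1e-9)
})

test_that("scenarios round-trip through YAML", {
  sc <- fixture_scenario("E2R2")
  path <- tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$name, "E2R2")
  expect_equal(back$protocol$full_time_s, 583.8)
  scb <- make_scenario("mognoB_c_mid", fov_mm = 0.0775)
  write_scenario(scb, path)
  backb <- read_scenario(path)
  expect_equal(backb$beam$fov_mm, 0.0775, tolerance = 1e-9)
})

test_that("growth generator obeys its clamp and determinism contracts", {
  cfg0 <- growth_sim_config(baseline_mm_h = 0.65,
                            sensitivity_mm_h_per_gy = 0,
                            noise_sd_mm_h = 0, n_tp = 4,
                            grid = c(12, 12, 1200), root_radius_mm = 0.01)
  sim0 <- simulate_growth_series(cfg0)
  expect_equal(sim0$rates_mm_h, rep(0.65, 3))
  # strong sensitivity arrests growth and keeps it arrested
  cfgA <- growth_sim_config(baseline_mm_h = 0.65,
                            sensitivity_mm_h_per_gy = 1e-3,
                            noise_sd_mm_h = 0, n_tp = 4,
                            grid = c(12, 12, 400), root_radius_mm = 0.01)
  simA <- simulate_growth_series(cfgA)
  expect_equal(simA$rates_mm_h, rep(0, 3))
  # monotone decline without noise
  cfgM <- growth_sim_config(baseline_mm_h = 0.7,
                            sensitivity_mm_h_per_gy = 2e-5,
                            noise_sd_mm_h = 0, n_tp = 5,
                            grid = c(12, 12, 1500), root_radius_mm = 0.01)
  simM <- simulate_growth_series(cfgM)
  expect_true(all(diff(simM$rates_mm_h) < 0))
  # bit-reproducible under a fixed seed
  s1 <- simulate_growth_series(growth_sim_config(seed = 9,
                                                 grid = c(10, 10, 1500),
                                                 root_radius_mm = 0.01))
  s2 <- simulate_growth_series(growth_sim_config(seed = 9,
                                                 grid = c(10, 10, 1500),
                                                 root_radius_mm = 0.01))
  expect_identical(s1$rates_mm_h, s2$rates_mm_h)
  expect_identical(s1$series$masks, s2$series$masks)
})

test_that("mask series from the generator satisfy the series invariants", {
  sim <- simulate_growth_series(growth_sim_config(
    baseline_mm_h = 0.6, noise_sd_mm_h = 0.01, n_tp = 4,
    grid = c(14, 14, 1400), root_radius_mm = 0.012, seed = 3))
  ser <- sim$series
  expect_s3_class(ser, "root_mask_series")
  expect_length(ser$masks, 4)
  # masks are nested (the root only grows)
  for (i in 1:3) {
    expect_true(all(ser$masks[[i]] <= ser$masks[[i + 1]]))
  }
  # measured rates track the generated rates up to voxel quantisation
  r <- growth_rates(ser)
  expect_equal(r$rate_mm_h, sim$rates_mm_h, tolerance = 0.02)
})

test_that("the full pipeline recovers the generator's dose sensitivity", {
  # the stated reference case: slope -0.02 mm/h per kGy, sigma 0.02, n = 4
  cfg <- growth_sim_config(baseline_mm_h = 0.7,
                           sensitivity_mm_h_per_gy = 2e-5,
                           noise_sd_mm_h = 0.02, n_tp = 5,
                           grid = c(12, 12, 1500), root_radius_mm = 0.01,
                           seed = 42)
  sim <- simulate_growth_series(cfg)
  rates <- growth_rates(sim$series)$rate_mm_h
  fit <- dose_response(rates, sim$cum_dose_gy)
  expect_lt(abs(fit$slope - (-2e-5)), 2 * fit$slope_se)
})

test_that("sensitivity recovery coverage holds across many seeds", {
  # +/- 2 SE coverage approaches its nominal level only with enough
  # residual degrees of freedom, so the recovery experiment uses a longer
  # series (16 timepoints, 1.5 kGy per scan) than the 4-point example
  hits <- vapply(1:200, function(s) {
    cfg <- growth_sim_config(baseline_mm_h = 0.7,
                             sensitivity_mm_h_per_gy = 2e-5,
                             noise_sd_mm_h = 0.02,
                             dose_per_tp_gy = 1500, n_tp = 16, seed = s)
    sim <- simulate_growth_series(cfg, masks = FALSE)
    fit <- dose_response(sim$rates_mm_h, sim$cum_dose_gy)
    abs(fit$slope - (-2e-5)) < 2 * fit$slope_se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("fixture writer emits readable plain-text artefacts", {
  dir <- tempfile("fixtures")
  write_fixtures(dir)
  expect_true(file.exists(file.path(dir, "soil_default.csv")))
  sp <- read_spectrum(file.path(dir, "spectrum_E1.txt"))
  expect_s3_class(sp, "xray_spectrum")
  sc <- read_scenario(file.path(dir, "E3R1.yaml"))
  expect_equal(sc$protocol$start_angle_deg, 135)
  mk <- read_root_mask(file.path(dir, "mask_tp1.csv"))
  expect_true(any(mk$mask))
})
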