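# mass/size conversion, LOQ, concentrations, QC, distribution summaries

test_that("event_mass subtracts the intercept, scales with slope, drops non-positive", {
  m <- calibration_model(response_slope = 10, response_intercept = 2)
  expect_equal(as.numeric(event_mass(c(12, 22), m)), c(1, 2))
  # at or below the intercept: rejected with a warning
  expect_warning(out <- event_mass(c(2, 12), m), "dropped")
  expect_equal(as.numeric(out), 1)
  expect_identical(attr(out, "n_dropped"), 1L)
  # doubling the slope halves every mass
  m2 <- calibration_model(response_slope = 20, response_intercept = 2)
  expect_equal(as.numeric(event_mass(c(12, 22), m2)),
               as.numeric(event_mass(c(12, 22), m)) / 2)
})

test_that("ESD from mass matches closed forms and inverts sphere_mass", {
  expect_equal(esd_from_mass(2.0e-17, 10.49), 15.4, tolerance = 0.002)
  # cube-root scaling: mass x8 -> diameter x2
  expect_equal(esd_from_mass(8 * 3e-18, 10.49), 2 * esd_from_mass(3e-18, 10.49))
  # hand-derived closed form: rho = 6/pi g/cm^3, m = 1e-21 g -> d = 1 nm
  expect_equal(esd_from_mass(1e-21, 6 / pi), 1)
  # exact round trip for arbitrary positive density
  for (rho in c(0.7, 10.49, 19.3)) {
    d <- c(1, 15.4, 120)
    expect_equal(esd_from_mass(sphere_mass(d, rho), rho), d)
  }
})

test_that("size LOQ is the threshold-equivalent diameter", {
  bg <- structure(list(mu = 10, sigma = 2, n_sigma = 5, threshold = 20),
                  class = "background_stats")
  model <- calibration_model(response_slope = 1e18, response_intercept = 0)
  expect_equal(size_loq(bg, model, 10.49),
               esd_from_mass(20 / 1e18, 10.49))
  # a threshold mapping to 2.0e-17 g is a 15.4 nm LOQ
  bg2 <- structure(list(mu = 10, sigma = 2, n_sigma = 5,
                        threshold = 2.0e-17 * 1e18),
                   class = "background_stats")
  expect_equal(size_loq(bg2, model, 10.49), 15.4, tolerance = 0.002)
  # sigma = 0 with mu at the intercept: LOQ collapses to 0+
  bg0 <- structure(list(mu = 3, sigma = 0, n_sigma = 5, threshold = 3),
                   class = "background_stats")
  model3 <- calibration_model(response_slope = 1e18, response_intercept = 3)
  expect_equal(size_loq(bg0, model3, 10.49), .Machine$double.xmin)
  # threshold below the intercept is an error
  model9 <- calibration_model(response_slope = 1e18, response_intercept = 30)
  expect_error(size_loq(bg, model9, 10.49), "below calibration intercept")
})

test_that("E174-like preset lands its size LOQ in the 11-23 nm window", {
  p <- sample_preset("e174")
  tr <- simulate_trace(p$config, p$population, seed = 91)
  ev <- detect_particles(tr)
  loq <- size_loq(ev$background, truth_model(p), p$population$density)
  expect_gt(loq, 11)
  expect_lt(loq, 23)
})

test_that("concentrations scale counts and masses back to the sample", {
  p <- sample_preset("nm300k", n_dwells = 30000)
  run <- run_pipeline(p, seed = 101)
  res <- run$result
  # consistency identity: C_m = mean event mass * C_p
  masses <- event_mass(run$events, run$model)
  expect_equal(res$particle_mass_conc,
               mean(masses) * res$particle_number_conc)
  # doubling the dilution factor doubles both concentrations
  res2 <- concentrations(run$events, run$model, flow = p$config$sample_flow,
                         duration = acq_duration(p$config),
                         dilution_factor = 2 * p$config$dilution_factor)
  expect_equal(res2$particle_number_conc, 2 * res$particle_number_conc)
  # sample mass ratio divides
  res3 <- concentrations(run$events, run$model, flow = p$config$sample_flow,
                         duration = acq_duration(p$config),
                         dilution_factor = p$config$dilution_factor,
                         sample_mass_per_dispersion_mass = 0.5)
  expect_equal(res3$particle_number_conc, 2 * res$particle_number_conc)
})

test_that("zero and low event counts are flagged", {
  cfg <- acquisition_config(n_dwells = 2000, background_mean = 50)
  pop <- particle_population("normal", 15.4, 2.2, number_concentration = 0)
  tr <- simulate_trace(cfg, pop, seed = 102)
  ev <- detect_particles(tr)
  model <- calibration_model(1e19)
  res <- concentrations(ev, model, flow = 1e-3, duration = 6)
  expect_lte(res$n_events, 2)  # rare false positives at most
  if (res$n_events == 0) {
    expect_equal(res$particle_number_conc, 0)
    expect_equal(res$particle_mass_conc, 0)
  }
  expect_true("count_window" %in% res$qc_flags)
})

test_that("dilution proportionality passes consistent pairs and fails 2x count mismatch", {
  p <- sample_preset("nm300k", n_dwells = 30000)
  runA <- run_pipeline(p, seed = 103)
  pB <- p
  pB$config$dilution_factor <- 2 * p$config$dilution_factor
  pB$population$number_concentration <- p$population$number_concentration
  runB <- run_pipeline(pB, seed = 104)
  verdict <- dilution_proportionality(runA$result, runB$result)
  expect_true(verdict$pass)

  # same raw counts at 2x differing dilution: back-calculated ratio 2
  bad <- runA$result
  bad$dilution_factor <- 2 * runA$result$dilution_factor
  bad$particle_number_conc <- 2 * runA$result$particle_number_conc
  verdict2 <- dilution_proportionality(bad, runA$result)
  expect_false(verdict2$pass)
  expect_equal(verdict2$conc_ratio, 2, tolerance = 1e-12)

  expect_error(dilution_proportionality(runA$result, runA$result),
               "different dilution")
})

test_that("mode and HWHM of a normal sample match sqrt(2 log 2) * sd", {
  set.seed(7)
  x <- rnorm(1e5, 15.4, 2.6 / sqrt(2 * log(2)))  # HWHM 2.6 by construction
  s <- distribution_summary(x)
  expect_equal(s$mode, 15.4, tolerance = 0.1 / 15.4)
  expect_equal(s$hwhm, 2.6, tolerance = 0.1 / 2.6)
  expect_equal(s$median, 15.4, tolerance = 0.002)
})

test_that("degenerate and small samples fall back gracefully", {
  expect_warning(s <- distribution_summary(rep(12, 100)), "bandwidth")
  expect_equal(s$mode, 12)
  expect_equal(s$hwhm, 0)
  expect_warning(s2 <- distribution_summary(c(10, 11, 12)), "fewer than 50")
  expect_true(is.na(s2$mode))
  expect_equal(s2$median, 11)
})

test_that("lognormal samples put the mode below the median", {
  set.seed(8)
  x <- rlnorm(2e4, log(18.7), 0.35)
  s <- distribution_summary(x)
  expect_lt(s$mode, s$median)
})

test_that("number recovery correction reweights the observed distribution", {
  set.seed(9)
  d <- size_distribution(rnorm(500, 15.4, 2.2), size_loq = 12)
  expect_equal(number_recovery_correction(d, 0)$observed_weight, 1)
  corrected <- number_recovery_correction(d, 0.14)
  expect_equal(corrected$observed_weight, 0.86)
  expect_true(corrected$normalized)
  expect_equal(number_recovery_correction(d, 0.5)$observed_weight, 0.5)
  expect_error(number_recovery_correction(d, 1), "below_loq_number_fraction")
  # summaries are recomputable from the stored diameters
  s <- distribution_summary(corrected)
  expect_equal(s$median, corrected$median)
})
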