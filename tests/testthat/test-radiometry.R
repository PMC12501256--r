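sweep_C <- seq(31.7, 39.8, by = 0.9)

test_that("noiseless blackbody sweep recovers per-pixel gain and offset", {
  set.seed(61)
  p <- 11; q <- 13
  Cstar <- matrix(runif(p * q, 0.8, 1.2), p, q)
  Dstar <- matrix(runif(p * q, -5, 5), p, q)
  truth <- calibration_model(p, q, Cstar, Dstar)
  frames <- list(); temps <- numeric(0)
  for (tC in sweep_C) for (r in 1:5) {
    frames <- c(frames,
                list(radiance_from_temperature(celsius_to_kelvin(tC), truth)))
    temps <- c(temps, celsius_to_kelvin(tC))
  }
  # 10 preset levels, 5 replicates, 143 pixels: 715 samples per level
  expect_equal(length(sweep_C), 10)
  expect_equal(5 * p * q, 715)
  fit <- fit_calibration(frames, temps)
  expect_lt(max(abs(fit$C / Cstar - 1)), 1e-9)
  expect_lt(max(abs(fit$Delta - Dstar)), 1e-6)
  expect_true(all(fit$fit_residuals < 1e-8))
  expect_false(any(fit$bad_gain))
})

test_that("calibration requires at least two distinct temperatures", {
  f <- list(matrix(1, 3, 5), matrix(1, 3, 5))
  expect_error(fit_calibration(f, c(310, 310)), "distinct")
  expect_error(fit_calibration(f, 310), "one preset")
})

test_that("temperature mapping inverts the radiometric law", {
  model <- calibration_model(3, 5, C = 2, Delta = 7)
  for (tC in c(10, 31.7, 37, 39.8, 80)) {
    rad <- radiance_from_temperature(celsius_to_kelvin(tC), model)
    tm <- temperature_map(rad, model)
    expect_all_equal(tm$T_C, matrix(tC, 3, 5), tol = 1e-9)
    expect_true(all(tm$valid))
  }
  # monotonicity in intensity above the offset
  xs <- seq(8, 50, length.out = 20)
  ts <- vapply(xs, function(x)
    temperature_map(matrix(x, 3, 5), model)$T_K[1, 1], numeric(1))
  expect_true(all(diff(ts) > 0))
})

test_that("non-positive radicand is flagged invalid", {
  model <- calibration_model(3, 5, C = 1, Delta = 2)
  tm <- temperature_map(matrix(2, 3, 5), model)   # x == Delta exactly
  expect_true(all(tm$T_K == 0))
  expect_false(any(tm$valid))
  tm2 <- temperature_map(matrix(1, 3, 5), model)  # below the offset
  expect_true(all(is.na(tm2$T_K)))
  expect_error(temperature_map(matrix(1, 3, 5), list()), "calibration_model")
})

test_that("uniform 37.0 degC scene round-trips through the full chain", {
  model <- calibration_model(11, 13, C = 1.3, Delta = 4)
  scene <- thermal_scene(radiance_from_temperature(celsius_to_kelvin(37),
                                                   model))
  rec <- simulate_full_scan(scene, S143)
  img <- reconstruct(laplace_interpolate(rec), S143)
  tm <- temperature_map(img, model)
  expect_all_equal(tm$T_C, matrix(37, 11, 13), tol = 1e-9)
  stats <- region_mean_temperature(tm, matrix(TRUE, 11, 13))
  expect_equal(stats$mean_C, 37, tolerance = 1e-9)
  expect_equal(stats$sd_C, 0, tolerance = 1e-9)
  expect_false(stats$fever)
})

test_that("region means use valid pixels only and flag fever at 37.1", {
  model <- calibration_model(3, 5)
  hot <- matrix(radiance_from_temperature(celsius_to_kelvin(37.5), model)[1],
                3, 5)
  tm <- temperature_map(hot, model)
  region <- matrix(FALSE, 3, 5); region[1:2, 1:2] <- TRUE
  st <- region_mean_temperature(tm, region)
  expect_equal(st$mean_C, 37.5, tolerance = 1e-9)
  expect_true(st$fever)
  expect_equal(st$n_pixels, 4)
  expect_error(region_mean_temperature(tm, matrix(FALSE, 3, 5)), "no valid")
  # two-level map: region restricted to the hot level reads the hot value
  rad <- radiance_from_temperature(celsius_to_kelvin(33), model)
  rad[1, ] <- radiance_from_temperature(celsius_to_kelvin(38), model)[1, ]
  tm2 <- temperature_map(rad, model)
  reg <- matrix(FALSE, 3, 5); reg[1, ] <- TRUE
  expect_equal(region_mean_temperature(tm2, reg)$mean_C, 38, tolerance = 1e-9)
})

test_that("noisy sweep recovery is unbiased and tightens with less noise", {
  set.seed(71)
  model <- calibration_model(11, 13)
  sch <- scheme143(143)
  spread <- c()
  for (sigma in c(20, 5)) {
    errs <- c()
    for (tC in c(32.6, 36.2)) {
      scene <- thermal_scene(radiance_from_temperature(celsius_to_kelvin(tC),
                                                       model))
      for (r in 1:3) {
        rec <- simulate_scan(scene, S143, sch, noise_sigma = sigma)
        img <- reconstruct(laplace_interpolate(rec, sch), S143)
        tm <- temperature_map(img, model)
        errs <- c(errs, tm$T_C[tm$valid] - tC)
      }
    }
    expect_lt(abs(mean(errs)), 4 * sd(errs) / sqrt(length(errs)) + 0.01)
    spread <- c(spread, sd(errs))
  }
  expect_lt(spread[2], spread[1])
})

test_that("temperature resolution definitions behave on synthetic sweeps", {
  set.seed(81)
  # tight spread: adjacent interquartile boxes separate at the sweep step
  rec_tight <- lapply(sweep_C, function(tC) tC + rnorm(715, 0, 0.1))
  res <- temperature_resolution(rec_tight, sweep_C)
  expect_equal(res$step_resolution_C, 0.9, tolerance = 1e-9)
  expect_equal(res$rms_error_C, 0.1, tolerance = 0.15)
  # heavy spread: boxes overlap, no resolution at this sweep
  rec_wide <- lapply(sweep_C, function(tC) tC + rnorm(715, 0, 2.5))
  expect_true(is.na(temperature_resolution(rec_wide, sweep_C)$step_resolution_C))
})
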