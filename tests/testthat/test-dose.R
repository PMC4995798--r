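make_flat <- function(value, wl = seq(400, 800, by = 2), ...) {
  uv_spectrum(wl, rep(value, length(wl)), ...)
}

test_that("uv_spectrum validates its inputs", {
  expect_error(uv_spectrum(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(uv_spectrum(c(2, 1, 3), c(0, 0, 0)), "strictly increasing")
  expect_error(uv_spectrum(450, 0.1), "at least 2")
})

test_that("baseline subtraction is exact pointwise and keeps negatives", {
  s <- make_flat(0.5)
  expect_equal(subtract_baseline(s, s)$absorbance,
               rep(0, length(s$wavelength)))
  zero <- make_flat(0)
  expect_equal(subtract_baseline(s, zero)$absorbance, s$absorbance)
  # a synthetic peak plus known baseline: subtraction recovers the peak
  model <- spectrum_model(noise_sd = 0)
  sample <- synth_spectrum(10, model)
  base <- synth_spectrum(0, model)
  recovered <- subtract_baseline(sample, base)
  hw <- model$peak_width / 2
  peak <- 10 * model$peak_height_per_conc * hw^2 /
    ((sample$wavelength - model$peak_center)^2 + hw^2)
  expect_equal(recovered$absorbance, peak, tolerance = 1e-12)
  # keeps negative differences
  dimmer <- make_flat(0.2)
  expect_true(all(subtract_baseline(dimmer, s)$absorbance < 0))
})

test_that("baseline subtraction interpolates the control but refuses extrapolation", {
  sample <- uv_spectrum(seq(450, 650, 1), rep(1, 201))
  control <- uv_spectrum(seq(400, 800, 4), seq(400, 800, 4) / 1000)
  out <- subtract_baseline(sample, control)
  expect_equal(out$absorbance, 1 - seq(450, 650, 1) / 1000,
               tolerance = 1e-12)
  narrow <- uv_spectrum(seq(500, 600, 2), rep(0, 51))
  expect_error(subtract_baseline(sample, narrow), "extrapolation")
})

test_that("spectral_area integrates simple shapes exactly", {
  # constant 0.5 over a 200 nm window
  expect_equal(spectral_area(make_flat(0.5)), 100)
  # symmetric triangle of height 1 spanning the window
  wl <- seq(400, 800, by = 1)
  tri <- pmax(0, 1 - abs(wl - 550) / 100)
  expect_equal(spectral_area(uv_spectrum(wl, tri), c(450, 650)), 100)
  # edge clipping by interpolation: grid not aligned with the window
  wl2 <- seq(400.5, 800.5, by = 3)
  expect_equal(spectral_area(uv_spectrum(wl2, rep(2, length(wl2)))), 400,
               tolerance = 1e-12)
  expect_error(spectral_area(uv_spectrum(c(500, 600), c(1, 1))), "window")
})

test_that("trapezoidal area matches a fine-grid quadrature oracle on a Lorentzian", {
  model <- spectrum_model(noise_sd = 0)
  coarse <- synth_spectrum(10, model, wavelength = seq(400, 800, 1))
  fine <- synth_spectrum(10, model, wavelength = seq(400, 800, 0.01))
  expect_equal(spectral_area(coarse), spectral_area(fine), tolerance = 1e-3)
  # and the fine-grid area matches the closed-form Lorentzian integral
  base <- synth_spectrum(0, model, wavelength = seq(400, 800, 0.01))
  expect_equal(spectral_area(fine) - spectral_area(base),
               10 * model_peak_area(model), tolerance = 1e-6)
})

test_that("spectral_area is linear: additive and homogeneous", {
  wl <- seq(400, 800, 2)
  set.seed(21)
  a <- uv_spectrum(wl, runif(length(wl)))
  b <- uv_spectrum(wl, runif(length(wl)))
  expect_equal(spectral_area(uv_spectrum(wl, a$absorbance + b$absorbance)),
               spectral_area(a) + spectral_area(b), tolerance = 1e-12)
  expect_equal(spectral_area(uv_spectrum(wl, 3 * a$absorbance)),
               3 * spectral_area(a), tolerance = 1e-12)
})

test_that("averaging replicates and integrating commute", {
  wl <- seq(400, 800, 2)
  set.seed(22)
  reps <- lapply(1:3, function(i) uv_spectrum(wl, runif(length(wl))))
  area_of_mean <- spectral_area(average_spectra(reps))
  mean_of_areas <- mean(vapply(reps, spectral_area, numeric(1)))
  expect_equal(area_of_mean, mean_of_areas, tolerance = 1e-12)
})

test_that("calibration fitting recovers exact and noisy lines", {
  conc <- c(0, 1, 2, 3, 4)
  cal <- fit_calibration(2 * conc + 1, conc)
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 1, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  # through-origin variant
  cal0 <- fit_calibration(2 * conc + 0.001, conc, through_origin = TRUE)
  expect_equal(cal0$intercept, 0)
  expect_equal(cal0$slope, 2, tolerance = 1e-3)
  # 2% multiplicative noise at 5 concentrations: slope within 5% per seed
  errs <- vapply(1:100, function(seed) {
    areas <- withr::with_seed(seed, (10 * conc + 2) *
                                (1 + stats::rnorm(5, sd = 0.02)))
    abs(fit_calibration(areas, conc)$slope - 10) / 10
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
  expect_lt(unname(stats::quantile(errs, 0.95)), 0.05)
  expect_error(fit_calibration(c(1, 2, 3), c(2, 2, 2)), "degenerate")
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "at least 3")
})

test_that("concentration_from_area inverts the calibration and clamps negatives", {
  cal <- fit_calibration(2 * (0:4) + 1, 0:4)
  expect_equal(as.numeric(concentration_from_area(5, cal)), 2)
  expect_equal(as.numeric(concentration_from_area(1, cal)), 0)
  res <- concentration_from_area(0.5, cal)
  expect_equal(as.numeric(res), 0)
  expect_true(attr(res, "clamped"))
  # round-trip on noiseless areas
  areas <- 2 * (0:4) + 1
  expect_equal(as.numeric(concentration_from_area(areas, cal)), 0:4,
               tolerance = 1e-12)
})

test_that("deposition kinetics turns areas into deposited fractions", {
  model <- spectrum_model(noise_sd = 0)
  control <- synth_spectrum(0, model, condition = "control_medium")
  tps <- c(0, 6, 24, 72)
  # constant concentration: all fractions zero
  const <- lapply(tps, function(t) {
    synth_spectrum(50, model, timepoint = t, condition = "with_cells")
  })
  kin <- deposition_kinetics(const, control)
  expect_equal(kin$fraction_deposited, rep(0, 4), tolerance = 1e-12)
  # area dropping to a quarter of t = 0 means 75% deposited
  dep <- lapply(seq_along(tps), function(i) {
    synth_spectrum(50 * c(1, 0.9, 0.5, 0.25)[i], model,
                   timepoint = tps[i], condition = "with_cells")
  })
  kin2 <- deposition_kinetics(dep, control)
  expect_equal(kin2$fraction_deposited, c(0, 0.1, 0.5, 0.75),
               tolerance = 1e-9)
  expect_false(any(kin2$sd_flag, na.rm = TRUE))
  # missing t = 0 is an error
  expect_error(deposition_kinetics(dep[-1], control), "t = 0")
})

test_that("per-cell particle numbers scale the administered load", {
  expect_equal(nps_per_cell(6.24e8, 0.75), 6.7e3, tolerance = 0.01)
  expect_equal(nps_per_cell(4.56e8, 0.52), 3.4e3, tolerance = 0.01)
  expect_equal(nps_per_cell(1e9, 0), 0)
  expect_error(nps_per_cell(-1, 0.5), "nonnegative")
  expect_error(nps_per_cell(1e9, 0.5, 0), "positive")
})
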