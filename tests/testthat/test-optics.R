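# Sharpness metric, depth of field, and focus-sweep calibration.

test_that("depth of field follows the diffraction formula", {
  expect_equal(compute_dof(optics_model(500, 1.4)), 500 / (2 * 1.4^2),
               tolerance = 1e-12)
  expect_equal(round(compute_dof(optics_model(500, 1.4)), 2), 127.55)
  expect_equal(dof_reported(optics_model(500, 1.4)), 130)
  expect_equal(compute_dof(optics_model(600, 1.0)), 300)
  # formula limit: DOF vanishes with the wavelength
  expect_lt(compute_dof(optics_model(1e-9, 1.4)), 1e-9)
  expect_error(optics_model(-500, 1.4), "wavelength")
  expect_error(optics_model(500, 0), "numerical_aperture")
  expect_error(optics_model(500, 2.5), "numerical_aperture")
})

test_that("tenenbaum gradient matches a brute-force Sobel oracle exactly", {
  set.seed(101)
  for (k in 1:50) {
    img <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
    expect_identical(tenenbaum_gradient(img), tbg_brute(img))
  }
})

test_that("tenenbaum gradient is quadratic in intensity and offset-invariant", {
  set.seed(102)
  for (k in 1:10) {
    img <- matrix(sample(0:255, 48 * 48, replace = TRUE), 48, 48)
    t0 <- tenenbaum_gradient(img)
    expect_identical(tenenbaum_gradient(2 * img), 4 * t0)
    expect_identical(tenenbaum_gradient(img + 17), t0)
    a <- stats::runif(1, 0.5, 3)
    expect_equal(tenenbaum_gradient(a * img), a^2 * t0, tolerance = 1e-12)
  }
})

test_that("tenenbaum gradient handles degenerate input", {
  expect_identical(tenenbaum_gradient(matrix(5, 10, 10)), 0)
  expect_error(tenenbaum_gradient(matrix(1, 2, 5)), "at least")
  bad <- matrix(1, 5, 5); bad[3, 3] <- NA
  expect_error(tenenbaum_gradient(bad), "non-finite")
})

test_that("sweep curves peak at the focus position and flag flat sweeps", {
  m <- tiny_model()
  sw <- render_focus_sweep(m, data.frame(x_um = 11, y_um = 11),
                           z_range_um = c(3, 7), step_um = 0.1,
                           z_focus_um = 5, seed = 3)
  cv <- sweep_to_curve(sw$sweep, c(100, 100), 60)
  expect_s3_class(cv, "sharpness_curve")
  expect_lte(abs(cv$z_set_um[which.max(cv$tbg)] - 5), 0.1 + 1e-9)
  # identical frames: constant curve, flagged
  flat <- focus_sweep(rep(list(matrix(0.5, 64, 64)), 6), seq(0, 1, 0.2))
  expect_warning(cvf <- sweep_to_curve(flat, c(32, 32), 50), "no focus")
  expect_true("no focus found" %in% cvf$flags)
  expect_equal(diff(range(cvf$tbg)), 0)
})

test_that("rising-flank fit recovers noiseless and noisy slopes", {
  z <- seq(0, 6, by = 0.1)
  tbg <- ifelse(z <= 3, 50 * z + 20, 170 - 30 * (z - 3))
  fit <- fit_calibration(sharpness_curve(z, tbg))
  expect_equal(fit$slope, 50, tolerance = 1e-9)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-7)
  expect_gte(fit$r_squared, 1 - 1e-12)
  expect_equal(fit$inverse_slope_um_per_tbg, 1 / 50, tolerance = 1e-9)
  # noisy flank: true slope inside the 95% CI of the fit
  set.seed(5)
  for (k in 1:5) {
    tbgn <- pmax(tbg + stats::rnorm(length(z), sd = 2), 0)
    fn <- fit_calibration(sharpness_curve(z, tbgn))
    se <- sqrt(fn$covariance[2, 2])
    expect_lte(abs(fn$slope - 50), stats::qt(0.975, 1000) * 3 * se)
  }
  # too few samples below the peak
  expect_error(fit_calibration(sharpness_curve(0:3, c(1, 2, 9, 1))),
               "calibration failure")
})

test_that("tbg_to_z inverts the calibration and flags extrapolation", {
  z <- seq(0, 6, by = 0.1)
  tbg <- ifelse(z <= 3, 50 * z + 20, 170 - 30 * (z - 3))
  fit <- fit_calibration(sharpness_curve(z, tbg))
  # forward map then inverse is the identity on the flank
  zf <- seq(fit$z_reference_um, fit$z_reference_um + fit$flank_length_um, 0.05)
  pred <- tbg_to_z(fit$intercept + fit$slope * zf, fit)
  expect_equal(pred$z_um, zf - fit$z_reference_um, tolerance = 1e-9)
  expect_false(any(pred$extrapolated))
  # the reference TBG maps to z = 0
  expect_equal(tbg_to_z(fit$tbg_reference, fit)$z_um, 0, tolerance = 1e-9)
  # values beyond the fitted TBG range are flagged
  expect_true(tbg_to_z(max(tbg) * 2, fit)$extrapolated)
})

test_that("an inverse slope of 0.029 um/TBG maps +100 TBG to +2.9 um", {
  z <- seq(0, 6, by = 0.1)
  tbg <- ifelse(z <= 3, z / 0.029 + 5, 3 / 0.029 + 5 - 20 * (z - 3))
  fit <- fit_calibration(sharpness_curve(z, tbg))
  expect_equal(fit$inverse_slope_um_per_tbg, 0.029, tolerance = 1e-9)
  d <- tbg_to_z(fit$tbg_reference + 100, fit)$z_um -
    tbg_to_z(fit$tbg_reference, fit)$z_um
  expect_equal(d, 2.9, tolerance = 1e-9)
})

test_that("propagated z uncertainty has near-nominal coverage", {
  set.seed(2024)
  z <- seq(0, 4.5, by = 0.05)
  a <- 30; b <- 100; sd_n <- 1.5
  shape <- ifelse(z <= 3, a * z + b, a * 3 + b - 60 * (z - 3))
  z0 <- 1.5
  hits <- 0; n_rep <- 1000
  for (r in seq_len(n_rep)) {
    curve <- sharpness_curve(z, pmax(shape + stats::rnorm(length(z), sd = sd_n), 0))
    fit <- tryCatch(fit_calibration(curve), error = function(e) NULL)
    if (is.null(fit)) next
    obs <- a * z0 + b + stats::rnorm(1, sd = sd_n)
    est <- tbg_to_z(obs, fit)
    z_hat_abs <- est$z_um + fit$z_reference_um
    if (abs(z_hat_abs - z0) <= 1.96 * est$z_sigma_um) hits <- hits + 1
  }
  cover <- hits / n_rep
  expect_gte(cover, 0.90)
  expect_lte(cover, 0.99)
})

test_that("calibration stability criterion compares before/after TBG", {
  expect_true(calibration_stable(1000, 1000, 0.10))
  expect_false(calibration_stable(1000, 1200, 0.10))
  expect_true(calibration_stable(1000, 1050, 0.10))
  expect_true(calibration_stable(1050, 1000, 0.10))
  expect_error(calibration_stable(-1, 10), ">= 0")
})
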