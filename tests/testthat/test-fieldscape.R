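# Stripe-pattern stray field, external pulses, and the effective field.

test_that("harmonic mode matches the exact closed-form field", {
  set.seed(41)
  pat <- stripe_pattern(mode = "harmonic")
  x <- stats::runif(40, -7, 17); z <- stats::runif(40, 1, 8)
  H <- stripe_mfl(x, z, pat)
  cf <- field_closed_form(x, z)
  mag <- sqrt(cf$Hx_Am^2 + cf$Hz_Am^2)
  expect_lt(max(abs(H$Hx_Am - cf$Hx_Am) / mag), 1e-9)
  expect_lt(max(abs(H$Hz_Am - cf$Hz_Am) / mag), 1e-9)
})

test_that("truncated line-charge sum agrees with 25 harmonics to <1%", {
  pat_h <- stripe_pattern(mode = "harmonic")
  pat_l <- stripe_pattern(mode = "line_charge")
  g <- expand.grid(x = seq(0, 10, 0.5), z = seq(2.5, 10, 0.5))
  Ha <- stripe_mfl(g$x, g$z, pat_h)
  Hl <- stripe_mfl(g$x, g$z, pat_l)
  mag <- sqrt(Ha$Hx_Am^2 + Ha$Hz_Am^2)
  rel <- sqrt((Ha$Hx_Am - Hl$Hx_Am)^2 + (Ha$Hz_Am - Hl$Hz_Am)^2) / mag
  expect_lt(max(rel), 0.01)
})

test_that("half-period shift flips the field sign in every mode", {
  pats <- list(stripe_pattern(mode = "harmonic"),
               stripe_pattern(mode = "line_charge"),
               with_fitted_forms(stripe_pattern()))
  x <- seq(-3, 12, 0.7); z <- 3
  tols <- c(1e-9, 1e-3, 1e-9)   # truncated line-charge sum is approximate
  for (k in seq_along(pats)) {
    H1 <- stripe_mfl(x, z, pats[[k]])
    H2 <- stripe_mfl(x + 5, z, pats[[k]])
    scale <- max(abs(H1$Hz_Am))
    expect_lt(max(abs(H1$Hz_Am + H2$Hz_Am)) / scale, tols[k])
    expect_lt(max(abs(H1$Hx_Am + H2$Hx_Am)) / scale, tols[k])
  }
})

test_that("the field is periodic and its magnitude hh/tt degenerate", {
  x <- seq(0, 10, 0.25); z <- 2
  for (mode in c("harmonic", "line_charge")) {
    pat <- stripe_pattern(mode = mode)
    H1 <- stripe_mfl(x, z, pat)
    H2 <- stripe_mfl(x + 10, z, pat)
    scale <- max(abs(H1$Hz_Am))
    tol <- if (mode == "harmonic") 1e-12 else 1e-3
    expect_lt(max(abs(H1$Hz_Am - H2$Hz_Am)) / scale, tol)
    m1 <- sqrt(H1$Hx_Am^2 + H1$Hz_Am^2)
    H5 <- stripe_mfl(x + 5, z, pat)
    m5 <- sqrt(H5$Hx_Am^2 + H5$Hz_Am^2)
    expect_equal(m1, m5, tolerance = if (mode == "harmonic") 1e-12 else 1e-3)
  }
})

test_that("far-field decay is governed by the first harmonic", {
  pat <- stripe_pattern(mode = "harmonic")
  x <- 1.3
  r <- sqrt(sum(unlist(stripe_mfl(x, 10, pat))^2)) /
    sqrt(sum(unlist(stripe_mfl(x, 5, pat))^2))
  expect_equal(r, exp(-pi), tolerance = 0.01)
})

test_that("numerical divergence and curl vanish above the source plane", {
  h <- 1e-3
  for (mode in c("harmonic", "line_charge")) {
    pat <- stripe_pattern(mode = mode)
    g <- expand.grid(x = seq(0.3, 9.7, 0.9), z = seq(0.8, 5, 0.7))
    dHx_dx <- (stripe_mfl(g$x + h, g$z, pat)$Hx_Am -
                 stripe_mfl(g$x - h, g$z, pat)$Hx_Am) / (2 * h)
    dHz_dz <- (stripe_mfl(g$x, g$z + h, pat)$Hz_Am -
                 stripe_mfl(g$x, g$z - h, pat)$Hz_Am) / (2 * h)
    dHx_dz <- (stripe_mfl(g$x, g$z + h, pat)$Hx_Am -
                 stripe_mfl(g$x, g$z - h, pat)$Hx_Am) / (2 * h)
    dHz_dx <- (stripe_mfl(g$x + h, g$z, pat)$Hz_Am -
                 stripe_mfl(g$x - h, g$z, pat)$Hz_Am) / (2 * h)
    scale <- abs(dHx_dx) + abs(dHz_dz) + abs(dHx_dz) + abs(dHz_dx)
    expect_lt(max(abs(dHx_dx + dHz_dz) / scale), 1e-6)
    expect_lt(max(abs(dHx_dz - dHz_dx) / scale), 1e-6)
  }
})

test_that("z must be above the source plane", {
  pat <- stripe_pattern()
  expect_error(stripe_mfl(1, 0, pat), "z must be > 0")
  expect_error(stripe_mfl(1, -2, pat), "z must be > 0")
  expect_error(stripe_mfl(1, 1, stripe_pattern(mode = "fitted")),
               "fit_mfl_forms")
})

test_that("fitted separable forms reproduce the line-charge field", {
  pat <- stripe_pattern(mode = "line_charge")
  forms <- fit_mfl_forms(pat, z_range_um = c(2.5, 8))
  expect_equal(forms$degree, 6L)
  expect_length(forms$poly_x, 7)
  expect_length(forms$poly_z, 7)
  # first-harmonic dominance: decay constants near period / (2 pi)
  expect_lt(abs(forms$zeta_z_um - 10 / (2 * pi)) / (10 / (2 * pi)), 0.10)
  expect_lt(abs(forms$zeta_x_um - 10 / (2 * pi)) / (10 / (2 * pi)), 0.10)
  expect_lt(forms$max_rel_error, 0.05)
})

test_that("external field follows the trapezoidal schedule", {
  pu <- pulse_sequence()     # +8 mT plateau, ramp 20 ms, -8 mT plateau
  mu0 <- 4e-7 * pi
  ef <- external_field(c(45, 100, 150), pu)
  expect_equal(ef$Hz_Am * mu0 * 1e3, c(8, 0, -8), tolerance = 1e-9)
  expect_equal(ef$Hx_Am * mu0 * 1e3, rep(1, 3), tolerance = 1e-9)
  expect_error(external_field(1000, pu), "outside")
  expect_error(external_field(-1, pu), "outside")
  # plateau signs beyond a full cycle
  pu3 <- pulse_sequence(signs = c(1, -1, 1))
  expect_equal(external_field(pu3$duration_ms - 1, pu3)$Hz_Am * mu0 * 1e3, 8,
               tolerance = 1e-9)
})

test_that("effective field superposes stray and external components", {
  pu <- pulse_sequence()
  pat0 <- stripe_pattern(wall_charge_A = 0)
  H <- effective_field(3, 2, 50, pat0, pu)
  ex <- external_field(50, pu)
  expect_equal(H$Hx_Am, ex$Hx_Am)
  expect_equal(H$Hz_Am, ex$Hz_Am)
  # |H_eff|^2 - |H_mfl|^2 - |H_ext|^2 = 2 H_ext . H_mfl
  pat <- stripe_pattern()
  x <- c(1, 3, 7); z <- c(2, 3, 4)
  Hm <- stripe_mfl(x, z, pat)
  He <- effective_field(x, z, 50, pat, pu)
  lhs <- (He$Hx_Am^2 + He$Hz_Am^2) - (Hm$Hx_Am^2 + Hm$Hz_Am^2) -
    (ex$Hx_Am^2 + ex$Hz_Am^2)
  rhs <- 2 * (ex$Hx_Am * Hm$Hx_Am + ex$Hz_Am * Hm$Hz_Am)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("field maps export on a tidy grid", {
  g <- field_map_grid(stripe_pattern(), x_um = seq(0, 10, 1),
                      z_um = c(1, 2))
  expect_equal(nrow(g), 22)
  expect_named(g, c("x_um", "z_um", "Hx_Am", "Hz_Am"))
})
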