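# Potential energy, vertical force balance, equilibrium separation, and
# lateral minimum tracking.

pat <- stripe_pattern()
pu <- pulse_sequence()                  # +8 mT then -8 mT, Hx = 1 mT
part <- micromer_bead()
inter <- interaction_params()
t_plus <- 45                            # inside the +Hz plateau
t_minus <- pu$duration_ms - 45          # inside the -Hz plateau

test_that("potential energy is quadratic in the field amplitudes", {
  pat0 <- stripe_pattern(wall_charge_A = 0)
  pu0 <- pulse_sequence(Hz_amplitude_mT = 1e-12, Hx_plateau_mT = 1e-12)
  expect_equal(potential_energy(1, 2, t_plus, part, pat0, pu0), 0,
               tolerance = 1e-40)
  U1 <- potential_energy(1.3, 2.5, t_plus, part, pat, pu)
  pat2 <- stripe_pattern(wall_charge_A = 2 * pat$wall_charge_A)
  pu2 <- pulse_sequence(Hz_amplitude_mT = 16, Hx_plateau_mT = 2)
  U2 <- potential_energy(1.3, 2.5, t_plus, part, pat2, pu2)
  expect_equal(U2, 4 * U1, tolerance = 1e-9)
  expect_lt(U1, 0)
})

wall_dist <- function(x, wall, period = 10) {
  d <- (x - wall) %% period
  pmin(d, period - d)
}

test_that("potential minima sit above hh walls under +Hz and tt under -Hz", {
  z <- 2.3
  mp <- lateral_minimum(z, t_plus, part, pat, pu, c(-5, 15))
  expect_false(mp$degenerate)
  expect_lt(wall_dist(mp$x_um, 0), 0.3)           # hh wall at x = 0 mod 10
  mm <- lateral_minimum(z, t_minus, part, pat, pu, c(-5, 15))
  expect_lt(wall_dist(mm$x_um, 5), 0.3)           # tt wall at x = 5 mod 10
  # degeneracy at (numerically) zero external field
  pu0 <- pulse_sequence(Hz_amplitude_mT = 1e-9, Hx_plateau_mT = 1e-9)
  u_hh <- potential_energy(0, z, t_plus, part, pat, pu0)
  u_tt <- potential_energy(5, z, t_plus, part, pat, pu0)
  expect_equal(u_hh, u_tt, tolerance = 1e-9)
})

test_that("a flat potential is flagged degenerate", {
  pat0 <- stripe_pattern(wall_charge_A = 0)
  pu0 <- pulse_sequence(Hz_amplitude_mT = 1e-12, Hx_plateau_mT = 1e-12)
  expect_warning(mp <- lateral_minimum(2, t_plus, part, pat0, pu0, c(0, 10)),
                 "degenerate")
  expect_true(mp$degenerate)
})

test_that("an x-bias field shifts all minima by the same signed offset", {
  z <- 2.3
  pu_x <- pulse_sequence(Hx_plateau_mT = 0.5)
  m1 <- lateral_minimum(z, t_plus, part, pat, pu_x, c(-5, 5))
  m2 <- lateral_minimum(z, t_plus, part, pat, pu_x, c(5, 15))
  d1 <- m1$x_um - 0; d2 <- m2$x_um - 10
  expect_equal(d1, d2, tolerance = 1e-3)
  expect_gt(d1, 0)                       # shifted towards +x for +Hx, +Hz
  expect_lt(abs(d1), 1)                  # sub-um offset
  # direction agrees with a fine brute-force grid argmin
  xs <- seq(-2, 2, by = 5e-4)
  U <- potential_energy(xs, z, t_plus, part, pat, pu_x)
  expect_lt(abs(m1$x_um - xs[which.min(U)]), 2e-3)
})

test_that("with only DLVO forces the net force root matches a dense scan", {
  pat0 <- stripe_pattern(wall_charge_A = 0)
  pu0 <- pulse_sequence(Hz_amplitude_mT = 1e-12, Hx_plateau_mT = 1e-12)
  neutral <- particle_model(4, 0.15, density_kgm3 = 998)
  f <- function(g) net_vertical_force(0, g, t_plus, neutral, inter, pat0, pu0)
  # repulsion-only: positive everywhere
  i0 <- interaction_params(hamaker_J = 0, el_prefactor_N = 1e-10)
  expect_true(all(net_vertical_force(0, c(0.01, 0.1, 1, 10), t_plus, neutral,
                                     i0, pat0, pu0) > 0))
  # electrostatic + van der Waals root against a brute-force log grid
  gaps <- exp(seq(log(1e-3), log(50), length.out = 1e5))
  fg <- f(gaps)
  i_root <- which(fg[-1e5] > 0 & fg[-1] <= 0)[1]
  brute <- gaps[i_root]
  eq <- equilibrium_gap(0, t_plus, neutral, inter, pat0, pu0)
  expect_true(eq$bracketed)
  expect_lt(abs(eq$gap_um - brute), 1e-3)   # within the scan spacing
})

test_that("reversing the z-field flips the magnetic force above a wall", {
  # magnetic-only configuration: neutral buoyancy, no DLVO terms
  i0 <- interaction_params(hamaker_J = 0, el_prefactor_N = 0)
  neutral <- particle_model(4, 0.15, density_kgm3 = 998)
  Fp <- net_vertical_force(0, 0.5, t_plus, neutral, i0, pat, pu)
  Fm <- net_vertical_force(0, 0.5, t_minus, neutral, i0, pat, pu)
  expect_lt(Fp, 0)                          # attractive above hh under +Hz
  expect_gt(Fm, 0)                          # repulsive after reversal
})

test_that("equilibrium separation equals the brute-force scan and is monotone", {
  set.seed(55)
  for (k in 1:10) {
    ii <- interaction_params(
      hamaker_J = 10^stats::runif(1, -21, -19.5),
      debye_nm = stats::runif(1, 50, 300),
      el_prefactor_N = 10^stats::runif(1, -10.5, -9.5))
    tt <- stats::runif(1, 0, pu$duration_ms)
    xx <- stats::runif(1, 0, 10)
    eq <- suppressWarnings(equilibrium_gap(xx, tt, part, ii, pat, pu))
    gaps <- exp(seq(log(1e-3), log(50), length.out = 1e5))
    fg <- net_vertical_force(xx, gaps, tt, part, ii, pat, pu)
    i_root <- which(fg[-1e5] > 0 & fg[-1] <= 0)[1]
    if (eq$bracketed && !is.na(i_root)) {
      expect_lt(abs(eq$gap_um - gaps[i_root]), 2e-3)
    }
  }
  # monotonicity: more double-layer repulsion lifts the bead, more van der
  # Waals attraction lowers it
  g_el <- suppressWarnings(vapply(c(0.5, 1, 2, 4) * 1.1e-10, function(p)
    equilibrium_gap(0, t_plus, part,
                    interaction_params(el_prefactor_N = p), pat, pu)$gap_um,
    numeric(1)))
  expect_true(all(diff(g_el) >= -1e-4))
  g_ah <- suppressWarnings(vapply(c(0.25, 1, 4, 16) * 1e-20, function(a)
    equilibrium_gap(0, t_plus, part,
                    interaction_params(hamaker_J = a), pat, pu)$gap_um,
    numeric(1)))
  expect_true(all(diff(g_ah) <= 1e-4))
  expect_error(net_vertical_force(0, -1, t_plus, part, inter, pat, pu),
               "gap")
})

test_that("switching to the repulsive phase increases the equilibrium gap", {
  g_att <- equilibrium_gap(0, t_plus, part, inter, pat, pu)$gap_um
  g_rep <- equilibrium_gap(0, t_minus, part, inter, pat, pu)$gap_um
  expect_gt(g_rep, g_att)
})

test_that("the transport step width equals the domain width", {
  hs <- hop_step_width(part, pat, pulse_sequence(signs = c(1, -1, 1)))
  expect_equal(hs$step_um, 5, tolerance = 1e-3)
  expect_equal(sum(hs$steps_um), 10, tolerance = 2e-3)
  # the two single reversals alternate symmetrically around the domain width
  expect_equal(hs$steps_um[1] + hs$steps_um[2], 10, tolerance = 2e-3)
  # without the x-bias field each single reversal is exactly one domain width
  pu_no_x <- pulse_sequence(Hx_plateau_mT = 1e-9, signs = c(1, -1, 1))
  hs0 <- hop_step_width(part, pat, pu_no_x)
  expect_equal(hs0$steps_um[1], 5, tolerance = 1e-3)
  expect_equal(hs0$steps_um[2], 5, tolerance = 1e-3)
})

test_that("a resting bead above a wall has a flat elevation profile", {
  trk <- data.frame(t_ms = seq(10, 80, 2), x_um = 0)
  prof <- transport_elevation_profile(trk, part, inter, pat, pu, dt_ms = 2)
  expect_true(all(prof$bracketed))
  expect_lt(max(prof$z_eq_um), 1e-3)
})

test_that("a hopping trajectory rises, peaks between walls, and returns", {
  pu2 <- pulse_sequence(plateau_ms = 150)
  tg <- seq(0, pu2$duration_ms, 2)
  x <- 5 / (1 + exp(-(tg - 190) / 7.5))
  prof <- transport_elevation_profile(data.frame(t_ms = tg, x_um = x),
                                      part, inter, pat, pu2, dt_ms = 2)
  expect_true(all(prof$bracketed))
  i_pk <- which.max(prof$z_eq_um)
  expect_gt(prof$x_um[i_pk], 0.3)
  expect_lt(prof$x_um[i_pk], 4.7)            # interior x, strictly between walls
  expect_lt(prof$z_eq_um[1], 0.05)
  expect_lt(prof$z_eq_um[nrow(prof)], 0.05)  # returns to the initial elevation
  expect_gt(max(prof$z_eq_um), 1)
})

test_that("a full pulse cycle gives a periodic quasi-static profile", {
  pu3 <- pulse_sequence(signs = c(1, -1, 1))
  tg <- seq(0, pu3$duration_ms, 2)
  x <- 5 / (1 + exp(-(tg - 130) / 7.5)) + 5 / (1 + exp(-(tg - 240) / 7.5))
  prof <- transport_elevation_profile(data.frame(t_ms = tg, x_um = x),
                                      part, inter, pat, pu3, dt_ms = 2)
  expect_equal(prof$z_eq_um[1], prof$z_eq_um[nrow(prof)], tolerance = 0.05)
  expect_error(transport_elevation_profile(
    data.frame(t_ms = c(-5, 10), x_um = 0), part, inter, pat, pu3),
    "not covered")
})
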