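# Quasi-static vertical force balance for a superparamagnetic bead above the
# stripe-patterned substrate, and lateral potential-minimum tracking.
#
# Coordinate bookkeeping (two axes, z and z'):
#  - gap (z'): surface-to-surface separation between the bead and the
#    substrate top surface; the electrostatic and van der Waals forces act on
#    this coordinate.
#  - magnetic height: the field is evaluated at the bead centre, at
#    gap + radius + source_plane_depth above the buried wall lines
#    (point-probe approximation; no volume averaging over the bead).
# The model is quasi-static: no inertia or hydrodynamic drag, so at every time
# step the bead sits at the equilibrium separation where the vertical forces
# balance.

#' Superparamagnetic particle model
#'
#' Linear-magnetization bead: the moment follows the field with an effective
#' volume susceptibility and no remanence.
#'
#' @param diameter_um Bead diameter in um.
#' @param susceptibility Effective volume susceptibility (dimensionless, > 0).
#' @param density_kgm3 Bead density in kg/m^3 (must exceed the fluid density
#'   for sedimenting beads).
#' @param optical_template `"core_shell"` (superparamagnetic shell around an
#'   organic core; bright rim, dark core) or `"homogeneous"` (uniformly filled
#'   bead; dark disk) - the bead's appearance in bright-field images.
#' @return An object of class `particle_model`.
#' @export
particle_model <- function(diameter_um = 4, susceptibility = 0.15,
                           density_kgm3 = 1350,
                           optical_template = c("core_shell", "homogeneous")) {
  .assert_scalar_pos(diameter_um, "diameter_um")
  .assert_scalar_pos(susceptibility, "susceptibility")
  .assert_scalar_pos(density_kgm3, "density_kgm3")
  optical_template <- match.arg(optical_template)
  r_m <- diameter_um / 2 * 1e-6
  structure(list(diameter_um = diameter_um, radius_um = diameter_um / 2,
                 susceptibility = susceptibility, density_kgm3 = density_kgm3,
                 volume_m3 = 4 / 3 * pi * r_m^3,
                 optical_template = optical_template),
            class = "particle_model")
}

#' @rdname particle_model
#' @param diameter_preset Diameter preset for the core-shell bead family
#'   (3 or 4 um).
#' @details `micromer_bead()` and `dynabead_m270()` are presets for the two
#'   prototypical bead families studied: core-shell beads of 3 or 4 um and
#'   homogeneous 2.8 um beads.
#' @export
micromer_bead <- function(diameter_preset = 4) {
  particle_model(diameter_um = diameter_preset, susceptibility = 0.15,
                 density_kgm3 = 1350, optical_template = "core_shell")
}

#' @rdname particle_model
#' @export
dynabead_m270 <- function() {
  particle_model(diameter_um = 2.8, susceptibility = 0.17,
                 density_kgm3 = 1600, optical_template = "homogeneous")
}

#' Particle-substrate interaction parameters
#'
#' Constants of the DLVO-type force laws: exponential electrostatic
#' double-layer repulsion, sphere-plane van der Waals attraction, and
#' effective gravity (gravity minus buoyancy). Defaults are plausible
#' configuration fixtures for polymer beads in water over a polymer-coated
#' substrate, not measured values.
#'
#' @param hamaker_J Hamaker constant in J (default 1e-20).
#' @param debye_nm Debye screening length in nm (default 150).
#' @param el_prefactor_N Amplitude of the sphere-plane double-layer force in N
#'   (default 1.1e-10; see [electrostatic_prefactor()]).
#' @param fluid_density_kgm3 Fluid density in kg/m^3 (default 998, water).
#' @param temperature_K Temperature in K (informational; default 298).
#' @param spacer_um Thickness of the polymer spacer layer in um (default
#'   0.15; informational - the magnetic source depth lives in the pattern).
#' @return An object of class `interaction_params`.
#' @export
interaction_params <- function(hamaker_J = 1e-20, debye_nm = 150,
                               el_prefactor_N = 1.1e-10,
                               fluid_density_kgm3 = 998,
                               temperature_K = 298, spacer_um = 0.15) {
  .assert_scalar_pos(debye_nm, "debye_nm")
  if (hamaker_J < 0) stop("'hamaker_J' must be >= 0", call. = FALSE)
  if (el_prefactor_N < 0) stop("'el_prefactor_N' must be >= 0", call. = FALSE)
  if (spacer_um < 0) stop("'spacer_um' must be >= 0", call. = FALSE)
  structure(list(hamaker_J = hamaker_J, debye_nm = debye_nm,
                 el_prefactor_N = el_prefactor_N,
                 fluid_density_kgm3 = fluid_density_kgm3,
                 temperature_K = temperature_K, spacer_um = spacer_um),
            class = "interaction_params")
}

#' Electrostatic prefactor from surface potentials
#'
#' Linearized sphere-plane double-layer amplitude
#' `P_el = 4 pi eps0 eps_r R psi_p psi_s / lambda_D`, so that
#' `F_el(gap) = P_el exp(-gap / lambda_D)`.
#'
#' @param psi_particle_mV,psi_surface_mV Surface potentials in mV.
#' @param radius_um Bead radius in um.
#' @param debye_nm Debye length in nm.
#' @param rel_permittivity Relative permittivity of the medium (default 80).
#' @return Prefactor in N (positive = repulsive for like-signed potentials).
#' @export
electrostatic_prefactor <- function(psi_particle_mV = -30,
                                    psi_surface_mV = -30, radius_um = 2,
                                    debye_nm = 150, rel_permittivity = 80) {
  eps0 <- 8.8541878128e-12
  4 * pi * eps0 * rel_permittivity * (radius_um * 1e-6) *
    (psi_particle_mV * 1e-3) * (psi_surface_mV * 1e-3) / (debye_nm * 1e-9)
}

#' Magnetic potential energy of a bead in the effective field
#'
#' Linear-magnetization model: `U_p = -(mu0/2) V chi |H_eff|^2`, with the
#' effective field `H_eff = H_ext + H_MFL` evaluated at the bead centre.
#' The magnetic force is the negative gradient of this potential.
#'
#' @param x_um Lateral position(s) in um.
#' @param z_um Height(s) of the bead centre above the magnetic source plane,
#'   in um (> 0).
#' @param t_ms Time in ms (scalar).
#' @param particle A [particle_model()].
#' @param pattern A [stripe_pattern()].
#' @param pulses A [pulse_sequence()].
#' @return Potential energy in J (vectorized over positions).
#' @export
potential_energy <- function(x_um, z_um, t_ms, particle, pattern, pulses) {
  stopifnot(inherits(particle, "particle_model"))
  H <- effective_field(x_um, z_um, t_ms, pattern, pulses)
  -(.mu0 / 2) * particle$volume_m3 * particle$susceptibility *
    (H$Hx_Am^2 + H$Hz_Am^2)
}

#' Net vertical force on a bead at a given gap
#'
#' Balance components (positive = away from the substrate):
#' \itemize{
#'   \item magnetic: `F_M,z = -dU_p/dz` (central difference, 1 nm step);
#'   \item electrostatic: `F_el = P_el exp(-gap/lambda_D)` (repulsive);
#'   \item van der Waals: `F_vdW = -A_H R / (6 gap^2)` (sphere-plane);
#'   \item effective gravity: `F_Grav = -(rho_p - rho_f) V g`.
#' }
#'
#' @param x_um Lateral position in um (scalar).
#' @param gap_um Surface-to-surface separation(s) in um; must be > 0.
#' @param t_ms Time in ms (scalar).
#' @param particle A [particle_model()].
#' @param interactions An [interaction_params()].
#' @param pattern A [stripe_pattern()].
#' @param pulses A [pulse_sequence()].
#' @return Net force in N, vectorized over `gap_um`.
#' @export
net_vertical_force <- function(x_um, gap_um, t_ms, particle, interactions,
                               pattern, pulses) {
  stopifnot(inherits(interactions, "interaction_params"))
  if (any(gap_um <= 0)) stop("gap must be > 0", call. = FALSE)
  z_mag <- gap_um + particle$radius_um + pattern$source_plane_depth_um
  dz <- 1e-3                                 # 1 nm, in um
  Up <- potential_energy(x_um, z_mag + dz, t_ms, particle, pattern, pulses)
  Um <- potential_energy(x_um, z_mag - dz, t_ms, particle, pattern, pulses)
  F_M <- -(Up - Um) / (2 * dz * 1e-6)
  gap_m <- gap_um * 1e-6
  F_el <- interactions$el_prefactor_N *
    exp(-gap_um / (interactions$debye_nm * 1e-3))
  F_vdW <- -interactions$hamaker_J * (particle$radius_um * 1e-6) /
    (6 * gap_m^2)
  F_grav <- -(particle$density_kgm3 - interactions$fluid_density_kgm3) *
    particle$volume_m3 * .g0
  F_M + F_el + F_vdW + F_grav
}

#' Equilibrium particle-substrate separation
#'
#' Scans the net vertical force on a log-spaced gap grid, selects the smallest
#' sign change where the force decreases through zero as the gap grows (a
#' stabilizing root: the bead is pushed back towards it from both sides), and
#' refines it by bisection to 0.1 nm. The smallest stable root is chosen
#' because the bead approaches from the contact side during the attractive
#' phase. If no stable root is bracketed, the grid cap is returned with
#' `bracketed = FALSE` and a warning.
#'
#' @inheritParams net_vertical_force
#' @param gap_range_um Scan range in um (default `c(1e-3, 50)`).
#' @param n_grid Number of log-spaced scan points (default 2000).
#' @param tol_um Bisection tolerance in um (default 1e-4, i.e. 0.1 nm).
#' @return A list with `gap_um` and `bracketed`.
#' @export
equilibrium_gap <- function(x_um, t_ms, particle, interactions, pattern,
                            pulses, gap_range_um = c(1e-3, 50),
                            n_grid = 2000L, tol_um = 1e-4) {
  gaps <- exp(seq(log(gap_range_um[1]), log(gap_range_um[2]),
                  length.out = n_grid))
  f <- net_vertical_force(x_um, gaps, t_ms, particle, interactions, pattern,
                          pulses)
  idx <- which(f[-length(f)] > 0 & f[-1] <= 0)
  if (!length(idx)) {
    # no stable root: net attraction at the smallest gap drives the bead to
    # contact; net repulsion everywhere pushes it beyond the scan cap
    if (f[1] <= 0) {
      warning("no stable force equilibrium; net attraction down to the ",
              "scan floor (contact)", call. = FALSE)
      return(list(gap_um = gap_range_um[1], bracketed = FALSE))
    }
    warning("no stable force equilibrium bracketed; returning scan cap",
            call. = FALSE)
    return(list(gap_um = gap_range_um[2], bracketed = FALSE))
  }
  lo <- gaps[idx[1]]; hi <- gaps[idx[1] + 1L]
  flo <- f[idx[1]]
  while (hi - lo > tol_um) {
    mid <- (lo + hi) / 2
    fm <- net_vertical_force(x_um, mid, t_ms, particle, interactions,
                             pattern, pulses)
    if (fm > 0) { lo <- mid; flo <- fm } else hi <- mid
  }
  list(gap_um = (lo + hi) / 2, bracketed = TRUE)
}

#' Lateral position of the potential-energy minimum
#'
#' Argmin of the bead potential `U_p(x)` at fixed height, located on a coarse
#' grid and refined by golden-section/parabolic search (stats::optimize) to
#' nm resolution. A flat potential (zero fields) is flagged degenerate.
#'
#' @inheritParams potential_energy
#' @param x_window_um Length-2 search window in um; must span at least one
#'   pattern period.
#' @param n_grid Coarse grid size (default 2001).
#' @param tol_um Refinement tolerance in um (default 1e-4).
#' @return A list with `x_um`, `U_J` and `degenerate`.
#' @export
lateral_minimum <- function(z_um, t_ms, particle, pattern, pulses,
                            x_window_um, n_grid = 2001L, tol_um = 1e-4) {
  if (diff(x_window_um) < pattern$period_um)
    stop("'x_window_um' must span at least one period", call. = FALSE)
  xs <- seq(x_window_um[1], x_window_um[2], length.out = n_grid)
  U <- potential_energy(xs, z_um, t_ms, particle, pattern, pulses)
  if (max(U) - min(U) <= 1e-12 * max(abs(U), 1e-300)) {
    warning("flat potential: lateral minimum is degenerate", call. = FALSE)
    return(list(x_um = NA_real_, U_J = U[1], degenerate = TRUE))
  }
  i <- which.min(U)
  lo <- xs[max(1L, i - 1L)]; hi <- xs[min(n_grid, i + 1L)]
  opt <- stats::optimize(function(x)
    potential_energy(x, z_um, t_ms, particle, pattern, pulses),
    interval = c(lo, hi), tol = tol_um)
  list(x_um = opt$minimum, U_J = opt$objective, degenerate = FALSE)
}

#' Transport step width of the hopping motion
#'
#' Tracks the occupied lateral potential minimum through the plateaus of a
#' full pulse cycle (+Hz, -Hz, +Hz) and returns the displacement per z-field
#' reversal. After each reversal the bead hops forward (+x) to the nearest
#' minimum of the transformed landscape, which sits above the adjacent domain
#' wall. Because the landscape is strictly periodic, the displacements of the
#' two reversals of a cycle sum to exactly one period, so their mean - the
#' transport step width - equals the domain width. (The constant x-bias field
#' offsets the individual minima slightly off the wall centres, making the two
#' single-reversal displacements alternate symmetrically around the domain
#' width; `steps_um` exposes them.)
#'
#' @param particle A [particle_model()].
#' @param pattern A [stripe_pattern()].
#' @param pulses A [pulse_sequence()]; needs at least 3 plateaus (a full
#'   cycle). The default schedule is extended to `signs = c(1, -1, 1)` if
#'   shorter.
#' @param z_um Evaluation height of the bead centre above the source plane in
#'   um; default: bead radius + source depth + 0.15 um gap (the bead near its
#'   attractive-phase elevation).
#' @param n_grid Lateral grid resolution per period for the minimum search.
#' @return A list with `step_um` (mean displacement per reversal), `steps_um`
#'   (individual displacements) and `minima_um` (occupied minima per plateau).
#' @export
hop_step_width <- function(particle = micromer_bead(),
                           pattern = stripe_pattern(),
                           pulses = pulse_sequence(signs = c(1, -1, 1)),
                           z_um = NULL, n_grid = 2001L) {
  if (length(pulses$signs) < 3)
    pulses <- pulse_sequence(Hz_amplitude_mT = pulses$Hz_amplitude_mT,
                             Hx_plateau_mT = pulses$Hx_plateau_mT,
                             ramp_ms = pulses$ramp_ms,
                             plateau_ms = pulses$plateau_ms,
                             signs = c(pulses$signs[1], -pulses$signs[1],
                                       pulses$signs[1]))
  if (is.null(z_um))
    z_um <- particle$radius_um + pattern$source_plane_depth_um + 0.15
  P <- pattern$period_um
  # plateau mid-times
  t_mid <- pulses$plateau_ms / 2 +
    (seq_along(pulses$signs) - 1) * (pulses$plateau_ms + pulses$ramp_ms)
  # initial occupied minimum near x = 0
  x_occ <- lateral_minimum(z_um, t_mid[1], particle, pattern, pulses,
                           x_window_um = c(-P / 2, P / 2),
                           n_grid = n_grid)$x_um
  minima <- x_occ
  for (s in 2:length(pulses$signs)) {
    # hop forward: nearest minimum at x >= current position
    nxt <- lateral_minimum(z_um, t_mid[s], particle, pattern, pulses,
                           x_window_um = c(x_occ + 1e-3, x_occ + 1e-3 + P),
                           n_grid = n_grid)$x_um
    minima <- c(minima, nxt)
    x_occ <- nxt
  }
  steps <- diff(minima)
  list(step_um = mean(steps), steps_um = steps, minima_um = minima)
}

#' Quasi-static elevation profile along a transport trajectory
#'
#' Evaluates the equilibrium separation at each time step of an observed (or
#' synthetic) lateral trajectory `x(t_i)`: the bead is assumed to sit at the
#' vertical force equilibrium at every instant. The profile is normalized so
#' its smallest bracketed separation is zero, matching how relative
#' elevations are reported.
#'
#' @param track A `track2d` or any data.frame with columns `t_ms` and `x_um`.
#' @param particle A [particle_model()].
#' @param interactions An [interaction_params()].
#' @param pattern A [stripe_pattern()].
#' @param pulses A [pulse_sequence()]; the trajectory timestamps must lie
#'   within the schedule.
#' @param dt_ms Evaluation time step in ms (default 1); the trajectory is
#'   linearly interpolated onto this grid.
#' @return A data.frame of class `equilibrium_profile` with columns `t_ms`,
#'   `x_um`, `z_eq_um` (normalized), `gap_um` (raw separation), `bracketed`;
#'   the normalization offset is stored in attribute `offset_um`.
#' @export
transport_elevation_profile <- function(track, particle, interactions,
                                        pattern, pulses, dt_ms = 1) {
  df <- as.data.frame(track)
  if (!all(c("t_ms", "x_um") %in% names(df)))
    stop("track must have columns 't_ms' and 'x_um'", call. = FALSE)
  if (min(df$t_ms) < 0 || max(df$t_ms) > pulses$duration_ms)
    stop("trajectory timestamps not covered by the pulse schedule",
         call. = FALSE)
  tg <- seq(min(df$t_ms), max(df$t_ms), by = dt_ms)
  xg <- stats::approx(df$t_ms, df$x_um, xout = tg, rule = 2)$y
  gap <- numeric(length(tg)); br <- logical(length(tg))
  for (k in seq_along(tg)) {
    eq <- equilibrium_gap(xg[k], tg[k], particle, interactions, pattern,
                          pulses)
    gap[k] <- eq$gap_um; br[k] <- eq$bracketed
  }
  off <- if (any(br)) min(gap[br]) else min(gap)
  out <- data.frame(t_ms = tg, x_um = xg, z_eq_um = gap - off, gap_um = gap,
                    bracketed = br)
  attr(out, "offset_um") <- off
  class(out) <- c("equilibrium_profile", "data.frame")
  out
}
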