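# Stray-field landscape of a head-to-head / tail-to-tail parallel-stripe
# domain pattern, trapezoidal external field pulses, and their superposition.
#
# The magnetic field landscape (MFL) is modelled by straight domain-wall lines
# carrying alternating magnetic line charge: head-to-head walls (positive
# charge) at x = 0 mod period, tail-to-tail walls (negative) at x =
# domain_width mod period, all buried `source_plane_depth_um` below the
# substrate top surface. Three interchangeable evaluations are provided:
#  - "line_charge": direct truncated sum of 2D line-charge fields
#    H_r = q_l / (2 pi r); the reference oracle.
#  - "harmonic": odd-harmonic Fourier series of the same charge pattern,
#    H_z = sum_{n odd} (2 q_l / P) cos(k_n x) e^{-k_n z} (and sin for H_x),
#    k_n = 2 pi n / P; converges rapidly for z > 0.
#  - "fitted": separable closed forms (exponential decay in z, sixth-degree
#    polynomial in x per half-period) produced by [fit_mfl_forms()].
# All internal fields are in A/m; configuration accepts mT via B = mu0 H.

#' Stripe-domain pattern model
#'
#' @param domain_width_um Stripe domain width in um (default 5; the pattern
#'   period is twice that).
#' @param wall_charge_A Magnetic line-charge density of a domain wall, in A.
#'   The default (0.03 A) gives a stray field of a few mT (in mu0 H units) at
#'   bead height and is a configuration fixture, not a measured value.
#' @param source_plane_depth_um Depth of the wall lines below the substrate
#'   top surface in um (default 0.16: a 150 nm spacer plus 10 nm capping).
#' @param mode One of `"line_charge"`, `"harmonic"`, `"fitted"`.
#' @param n_harmonics Number of odd harmonics summed in harmonic mode
#'   (default 25, i.e. n = 1, 3, ..., 49).
#' @param n_periods Truncation half-width of the line-charge sum, in periods
#'   per side (default 50).
#' @param forms Fitted coefficients from [fit_mfl_forms()] (required for
#'   `mode = "fitted"`).
#' @return An object of class `stripe_pattern`.
#' @export
stripe_pattern <- function(domain_width_um = 5, wall_charge_A = 0.03,
                           source_plane_depth_um = 0.16,
                           mode = c("harmonic", "line_charge", "fitted"),
                           n_harmonics = 25L, n_periods = 50L, forms = NULL) {
  mode <- match.arg(mode)
  .assert_scalar_pos(domain_width_um, "domain_width_um")
  if (wall_charge_A < 0) stop("'wall_charge_A' must be >= 0", call. = FALSE)
  if (source_plane_depth_um < 0)
    stop("'source_plane_depth_um' must be >= 0", call. = FALSE)
  structure(list(domain_width_um = domain_width_um,
                 period_um = 2 * domain_width_um,
                 wall_charge_A = wall_charge_A,
                 source_plane_depth_um = source_plane_depth_um,
                 mode = mode, n_harmonics = as.integer(n_harmonics),
                 n_periods = as.integer(n_periods), forms = forms),
            class = "stripe_pattern")
}

#' @export
print.stripe_pattern <- function(x, ...) {
  cat(sprintf("<stripe_pattern> %g um domains (period %g um), q_l = %g A, mode '%s'\n",
              x$domain_width_um, x$period_um, x$wall_charge_A, x$mode))
  invisible(x)
}

#' Stray field of the stripe pattern
#'
#' Evaluates the MFL components `(Hx, Hz)` at lateral position `x_um` and
#' height `z_um` above the source plane of the wall lines. `x_um` and `z_um`
#' are recycled to a common length.
#'
#' @param x_um Lateral position(s) in um (x perpendicular to the stripes).
#' @param z_um Height(s) above the source plane in um; must be > 0.
#' @param pattern A [stripe_pattern()].
#' @return A list with numeric vectors `Hx_Am` and `Hz_Am` (A/m).
#' @export
stripe_mfl <- function(x_um, z_um, pattern) {
  stopifnot(inherits(pattern, "stripe_pattern"))
  n <- max(length(x_um), length(z_um))
  x <- rep_len(as.numeric(x_um), n); z <- rep_len(as.numeric(z_um), n)
  if (any(!is.finite(x)) || any(!is.finite(z)))
    stop("positions must be finite", call. = FALSE)
  if (any(z <= 0))
    stop("z must be > 0 (above the source plane)", call. = FALSE)
  switch(pattern$mode,
    line_charge = .mfl_line_charge(x, z, pattern),
    harmonic = .mfl_harmonic(x, z, pattern),
    fitted = .mfl_fitted(x, z, pattern))
}

.mfl_line_charge <- function(x, z, pattern) {
  q <- pattern$wall_charge_A
  dw <- pattern$domain_width_um * 1e-6
  xm <- x * 1e-6; zm <- z * 1e-6
  M <- 2L * pattern$n_periods
  Hx <- Hz <- numeric(length(x))
  for (m in -M:M) {
    sgn <- if (m %% 2 == 0) 1 else -1
    # half-weighted outermost walls: averages the two last partial sums of
    # the alternating series, suppressing the truncation tail by ~100x
    if (abs(m) == M) sgn <- sgn / 2
    dx <- xm - m * dw
    r2 <- dx * dx + zm * zm
    c0 <- sgn * q / (2 * pi * r2)
    Hx <- Hx + c0 * dx
    Hz <- Hz + c0 * zm
  }
  list(Hx_Am = Hx, Hz_Am = Hz)
}

.mfl_harmonic <- function(x, z, pattern) {
  q <- pattern$wall_charge_A
  P <- pattern$period_um * 1e-6
  xm <- x * 1e-6; zm <- z * 1e-6
  a0 <- 2 * q / P
  Hx <- Hz <- numeric(length(x))
  for (n_odd in seq(1, by = 2, length.out = pattern$n_harmonics)) {
    k <- 2 * pi * n_odd / P
    e <- a0 * exp(-k * zm)
    Hx <- Hx + e * sin(k * xm)
    Hz <- Hz + e * cos(k * xm)
  }
  list(Hx_Am = Hx, Hz_Am = Hz)
}

# Map x to the fundamental half-period [0, P/2) and a sign from the hh/tt
# alternation: H(x + P/2) = -H(x) for both components.
.fold_half_period <- function(x, period) {
  u <- x %% period
  flip <- u >= period / 2
  u[flip] <- u[flip] - period / 2
  list(u = u, sgn = ifelse(flip, -1, 1))
}

.mfl_fitted <- function(x, z, pattern) {
  if (is.null(pattern$forms))
    stop("pattern has no fitted forms; run fit_mfl_forms() first", call. = FALSE)
  f <- pattern$forms
  fold <- .fold_half_period(x, pattern$period_um)
  px <- outer(fold$u, 0:6, `^`)
  list(Hx_Am = fold$sgn * exp(-z / f$zeta_x_um) * drop(px %*% f$poly_x),
       Hz_Am = fold$sgn * exp(-z / f$zeta_z_um) * drop(px %*% f$poly_z))
}

#' Fit separable closed forms to the stripe-pattern field
#'
#' Approximates each MFL component by the separable form
#' `H_c(x, z) = P_c(x) exp(-z / zeta_c)` with a sixth-degree polynomial
#' `P_c` on one half-period (extended by the hh/tt antisymmetry
#' `H(x + P/2) = -H(x)`) and an exponential decay in z. The line-charge sum is
#' the data source; the decay constant comes from an OLS fit of
#' `log` RMS amplitude against z, the polynomial from least squares on the
#' decay-compensated profiles. For heights beyond `period/(2 pi)` the first
#' harmonic dominates, so `zeta` approaches `period/(2 pi)`.
#'
#' @param pattern A [stripe_pattern()] (evaluated in line-charge mode).
#' @param z_range_um Height window of the fit in um (default `c(2.5, 8)`).
#' @param x_samples Number of x samples on the half-period (default 51).
#' @param z_samples Number of z samples (default 40).
#' @return An object of class `mfl_forms` with elements `poly_x`, `poly_z`
#'   (degree-6 coefficient vectors), `zeta_x_um`, `zeta_z_um`,
#'   `max_rel_error` (against the line-charge oracle over the fit window,
#'   normalized by the per-height field amplitude) and `condition_number` of
#'   the polynomial design matrix. Ill-conditioned fits trigger a warning.
#' @export
fit_mfl_forms <- function(pattern, z_range_um = c(2.5, 8), x_samples = 51L,
                          z_samples = 40L) {
  stopifnot(inherits(pattern, "stripe_pattern"))
  src <- pattern; src$mode <- "line_charge"
  P <- pattern$period_um
  xs <- seq(0, P / 2, length.out = x_samples)
  zs <- seq(z_range_um[1], z_range_um[2], length.out = z_samples)
  g <- expand.grid(x = xs, z = zs)
  H <- stripe_mfl(g$x, g$z, src)
  Hx <- matrix(H$Hx_Am, x_samples, z_samples)
  Hz <- matrix(H$Hz_Am, x_samples, z_samples)
  X <- outer(xs, 0:6, `^`)
  cond <- kappa(X, exact = TRUE)
  if (cond > 1e10)
    warning(sprintf("ill-conditioned polynomial fit (condition number %.3g)",
                    cond), call. = FALSE)
  fit_component <- function(Hc) {
    amp <- sqrt(colMeans(Hc^2))              # RMS amplitude per height
    dfit <- stats::lm(log(amp) ~ zs)
    zeta <- -1 / unname(stats::coef(dfit)[2])
    # given zeta, least squares of H = p(x) exp(-z/zeta) over the full grid
    eh <- exp(-g$z / zeta)
    Xd <- X[rep(seq_len(x_samples), z_samples), ] * eh
    beta <- qr.solve(Xd, as.vector(Hc))      # least squares via QR
    list(zeta = zeta, beta = drop(beta))
  }
  fx <- fit_component(Hx); fz <- fit_component(Hz)
  forms <- structure(list(poly_x = fx$beta, poly_z = fz$beta,
                          zeta_x_um = fx$zeta, zeta_z_um = fz$zeta,
                          degree = 6L, condition_number = cond,
                          z_range_um = z_range_um),
                     class = "mfl_forms")
  # fit-quality gate: relative error against the oracle, per-height amplitude
  fitted_pat <- pattern; fitted_pat$mode <- "fitted"; fitted_pat$forms <- forms
  Hf <- stripe_mfl(g$x, g$z, fitted_pat)
  ampn <- rep(pmax(sqrt(colMeans(Hx^2 + Hz^2)), 1e-300), each = x_samples)
  forms$max_rel_error <- max(abs(Hf$Hx_Am - H$Hx_Am) / ampn,
                             abs(Hf$Hz_Am - H$Hz_Am) / ampn)
  forms
}

#' Attach fitted closed forms to a pattern
#'
#' Convenience wrapper: fits the separable forms and returns a copy of the
#' pattern in `"fitted"` mode.
#'
#' @inheritParams fit_mfl_forms
#' @return A [stripe_pattern()] with `mode = "fitted"` and forms attached.
#' @export
with_fitted_forms <- function(pattern, z_range_um = c(2.5, 8),
                              x_samples = 51L, z_samples = 40L) {
  pattern$forms <- fit_mfl_forms(pattern, z_range_um, x_samples, z_samples)
  pattern$mode <- "fitted"
  pattern
}

#' Trapezoidal external field pulse sequence
#'
#' The external drive: a constant in-plane field `Hx` and a z-field that
#' alternates between `+Hz` and `-Hz` plateaus with linear ramps (piecewise
#' linear and continuous in time). Amplitudes are given in mT and converted
#' internally to A/m via `B = mu0 H`.
#'
#' @param Hz_amplitude_mT z-field plateau amplitude in mT (default 8).
#' @param Hx_plateau_mT Constant x-field in mT (default 1).
#' @param ramp_ms Ramp duration between plateaus in ms (default 20: the z
#'   field swings from +8 mT to -8 mT within 20 ms).
#' @param plateau_ms Plateau duration in ms (default 90).
#' @param signs Ordered plateau signs of the z-field (default `c(1, -1)`).
#' @return An object of class `pulse_sequence` with the piecewise-linear
#'   schedule and its total `duration_ms`.
#' @export
pulse_sequence <- function(Hz_amplitude_mT = 8, Hx_plateau_mT = 1,
                           ramp_ms = 20, plateau_ms = 90, signs = c(1, -1)) {
  .assert_scalar_pos(ramp_ms, "ramp_ms")
  .assert_scalar_pos(plateau_ms, "plateau_ms")
  if (!length(signs) || !all(signs %in% c(-1, 1)))
    stop("'signs' must be a vector of +1/-1", call. = FALSE)
  t <- 0; tt <- numeric(0); vv <- numeric(0)
  for (s in seq_along(signs)) {
    if (s > 1) {                      # ramp from previous plateau
      tt <- c(tt, t + ramp_ms); vv <- c(vv, signs[s])
      t <- t + ramp_ms
    } else {
      tt <- c(tt, 0); vv <- c(vv, signs[1])
    }
    tt <- c(tt, t + plateau_ms); vv <- c(vv, signs[s])
    t <- t + plateau_ms
  }
  structure(list(Hz_amplitude_mT = Hz_amplitude_mT,
                 Hx_plateau_mT = Hx_plateau_mT,
                 ramp_ms = ramp_ms, plateau_ms = plateau_ms, signs = signs,
                 t_break_ms = tt, sign_break = vv, duration_ms = t),
            class = "pulse_sequence")
}

#' @export
print.pulse_sequence <- function(x, ...) {
  cat(sprintf("<pulse_sequence> Hz +/-%g mT, Hx %g mT; ramp %g ms, plateau %g ms, signs [%s], %g ms total\n",
              x$Hz_amplitude_mT, x$Hx_plateau_mT, x$ramp_ms, x$plateau_ms,
              paste(ifelse(x$signs > 0, "+", "-"), collapse = ""),
              x$duration_ms))
  invisible(x)
}

#' External field at a point in time
#'
#' @param t_ms Time(s) in ms; must lie within the schedule span.
#' @param pulses A [pulse_sequence()].
#' @return A list with vectors `Hx_Am` and `Hz_Am` (A/m).
#' @export
external_field <- function(t_ms, pulses) {
  stopifnot(inherits(pulses, "pulse_sequence"))
  if (any(t_ms < 0 | t_ms > pulses$duration_ms))
    stop("t outside the pulse schedule span", call. = FALSE)
  s <- stats::approx(pulses$t_break_ms, pulses$sign_break, xout = t_ms,
                     rule = 1)$y
  list(Hx_Am = rep_len(pulses$Hx_plateau_mT * 1e-3 / .mu0, length(t_ms)),
       Hz_Am = s * pulses$Hz_amplitude_mT * 1e-3 / .mu0)
}

#' Effective field: external plus stray field
#'
#' `H_eff = H_ext + H_MFL`, component-wise.
#'
#' @param x_um,z_um Position (um); `z_um` above the source plane.
#' @param t_ms Time (ms).
#' @param pattern A [stripe_pattern()].
#' @param pulses A [pulse_sequence()].
#' @return A list with vectors `Hx_Am` and `Hz_Am` (A/m).
#' @export
effective_field <- function(x_um, z_um, t_ms, pattern, pulses) {
  mfl <- stripe_mfl(x_um, z_um, pattern)
  ext <- external_field(t_ms, pulses)
  list(Hx_Am = mfl$Hx_Am + ext$Hx_Am, Hz_Am = mfl$Hz_Am + ext$Hz_Am)
}

#' Export a field map on a regular grid
#'
#' @param pattern A [stripe_pattern()].
#' @param x_um,z_um Grid axis vectors (um).
#' @return A data.frame with columns `x_um`, `z_um`, `Hx_Am`, `Hz_Am`,
#'   suitable for CSV export and plotting.
#' @export
field_map_grid <- function(pattern, x_um = seq(0, 20, by = 0.25),
                           z_um = seq(0.5, 10, by = 0.25)) {
  g <- expand.grid(x_um = x_um, z_um = z_um)
  H <- stripe_mfl(g$x_um, g$z_um, pattern)
  g$Hx_Am <- H$Hx_Am; g$Hz_Am <- H$Hz_Am
  g
}
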