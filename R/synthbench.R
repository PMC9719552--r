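# Synthetic focus sweeps and transport videos with known 3D ground truth.
#
# Defocus is modelled as a z-dependent Gaussian blur of an in-focus bead
# template, with independent blur growth below and above the focal plane (the
# observed sharpness curves are asymmetric: the rising flank below focus is
# steeper than the falling one). This is not a physical diffraction model; the
# downstream pipeline only needs a monotone, asymmetric sharpness response,
# and a Gaussian keeps the generator analytic and fast. Illumination is a
# low-order polynomial surface; noise is Poisson-equivalent shot noise plus
# Gaussian read noise.

#' Imaging model for the synthetic generator
#'
#' @param template `"core_shell"` (bright rim, dark core) or `"homogeneous"`
#'   (dark disk): the bead's in-focus appearance in bright-field reflection.
#' @param bead_diameter_um Bead diameter in um (default 4).
#' @param contrast Peak template contrast relative to the background level.
#' @param blur_at_focus_px Gaussian blur sigma at best focus, px.
#' @param blur_growth_below_px_um,blur_growth_above_px_um Blur growth rate in
#'   px per um of defocus below / above the focal plane. The below-focus rate
#'   is larger by default (asymmetry factor > 1), giving the steeper rising
#'   flank.
#' @param background_level Mean illumination level in `[0, 1]`.
#' @param illumination Coefficients `c(cx, cy, cxy, cxx, cyy)` of the
#'   relative low-order illumination polynomial over the frame (u, v in
#'   `[-1, 1]`); the default gives a smooth ~10% inhomogeneity.
#' @param noise_gain Poisson-equivalent shot-noise gain: the intensity
#'   variance contribution is `noise_gain * I`.
#' @param read_noise_sd Gaussian read noise standard deviation.
#' @param pixel_size_um Pixel size, um/px (default 0.11).
#' @param frame_w_px,frame_h_px Frame size in px (default 800 x 600).
#' @return An object of class `imaging_model`.
#' @export
imaging_model <- function(template = c("core_shell", "homogeneous"),
                          bead_diameter_um = 4, contrast = 0.4,
                          blur_at_focus_px = 2,
                          blur_growth_below_px_um = 0.8,
                          blur_growth_above_px_um = 0.5,
                          background_level = 0.55,
                          illumination = c(0.05, -0.08, 0.03, -0.06, 0.04),
                          noise_gain = 2e-4, read_noise_sd = 0.01,
                          pixel_size_um = 0.11,
                          frame_w_px = 800L, frame_h_px = 600L) {
  template <- match.arg(template)
  stopifnot(blur_at_focus_px >= 0, blur_growth_below_px_um > 0,
            blur_growth_above_px_um > 0, contrast > 0)
  structure(list(template = template, bead_diameter_um = bead_diameter_um,
                 contrast = contrast, blur_at_focus_px = blur_at_focus_px,
                 blur_growth_below_px_um = blur_growth_below_px_um,
                 blur_growth_above_px_um = blur_growth_above_px_um,
                 background_level = background_level,
                 illumination = illumination, noise_gain = noise_gain,
                 read_noise_sd = read_noise_sd,
                 pixel_size_um = pixel_size_um,
                 frame_w_px = as.integer(frame_w_px),
                 frame_h_px = as.integer(frame_h_px)),
            class = "imaging_model")
}

# Blur sigma (px) at a given defocus (um): asymmetric growth.
.blur_sigma <- function(z_rel_um, model) {
  g <- if (z_rel_um < 0) model$blur_growth_below_px_um else
    model$blur_growth_above_px_um
  model$blur_at_focus_px + g * abs(z_rel_um)
}

# In-focus template contrast (additive, relative to background) at radial
# distance r_um from the bead centre; 1-px anti-aliased edges.
.bead_template <- function(r_um, model) {
  R <- model$bead_diameter_um / 2
  aa <- model$pixel_size_um
  edge <- function(r0) .clip01((r0 - r_um) / aa + 0.5)   # 1 inside, 0 outside
  if (model$template == "homogeneous") {
    -model$contrast * edge(R)
  } else {
    core <- edge(0.55 * R)
    disk <- edge(R)
    rim <- disk - core
    model$contrast * rim - 0.6 * model$contrast * core
  }
}

#' Render one defocused bead onto a canvas
#'
#' Adds the bead template, blurred with the defocus-dependent Gaussian kernel,
#' to the canvas at a sub-pixel centre position. Deterministic (noise is
#' applied at the frame level, not here).
#'
#' @param canvas Numeric matrix to draw onto.
#' @param center_um Length-2 `(x, y)` bead centre in um; must lie inside the
#'   canvas.
#' @param z_rel_um Defocus in um (negative = below the focal plane).
#' @param model An [imaging_model()].
#' @return The canvas with the bead added.
#' @export
render_particle <- function(canvas, center_um, z_rel_um, model) {
  px <- model$pixel_size_um
  cx <- center_um[1] / px; cy <- center_um[2] / px     # 0-based px coords
  nr <- nrow(canvas); nc <- ncol(canvas)
  if (cx < 0 || cy < 0 || cx > nc - 1 || cy > nr - 1)
    stop("bead centre outside the canvas", call. = FALSE)
  sig <- .blur_sigma(z_rel_um, model)
  R_px <- model$bead_diameter_um / 2 / px
  half <- ceiling(R_px + 4 * sig + 3)
  r0 <- max(1L, floor(cy) + 1L - half); r1 <- min(nr, floor(cy) + 1L + half)
  c0 <- max(1L, floor(cx) + 1L - half); c1 <- min(nc, floor(cx) + 1L + half)
  yy <- ((r0:r1) - 1) - cy
  xx <- ((c0:c1) - 1) - cx
  r_um <- sqrt(outer(yy^2, xx^2, `+`)) * px
  patch <- .bead_template(r_um, model)
  dim(patch) <- c(length(yy), length(xx))
  patch <- .gauss_blur(patch, sig)
  canvas[r0:r1, c0:c1] <- canvas[r0:r1, c0:c1] + patch
  canvas
}

# Illumination surface for a model (cached per call site).
.illumination_surface <- function(model) {
  u <- seq(-1, 1, length.out = model$frame_w_px)
  v <- seq(-1, 1, length.out = model$frame_h_px)
  cc <- model$illumination
  rel <- outer(v, u, function(vv, uu)
    1 + cc[1] * uu + cc[2] * vv + cc[3] * uu * vv + cc[4] * uu^2 + cc[5] * vv^2)
  model$background_level * rel
}

# Render a full frame: illumination + beads + noise. `beads` is a data.frame
# with x_um, y_um, z_rel_um. Assumes the RNG state is already set.
.render_frame <- function(model, beads, base = NULL, noise = TRUE) {
  canvas <- if (is.null(base)) .illumination_surface(model) else base
  if (nrow(beads)) {
    for (b in seq_len(nrow(beads))) {
      canvas <- render_particle(canvas, c(beads$x_um[b], beads$y_um[b]),
                                beads$z_rel_um[b], model)
    }
  }
  if (noise) {
    sd <- sqrt(model$read_noise_sd^2 + model$noise_gain * pmax(canvas, 0))
    canvas <- canvas + stats::rnorm(length(canvas)) * sd
  }
  .clip01(canvas)
}

#' Render a synthetic focus sweep
#'
#' Steps the sample axially past the fixed focal plane: at piezo position
#' `z_set` every bead sits at defocus `z_rel = z_set - z_focus`. One frame is
#' recorded per step, with illumination and noise applied.
#'
#' @param model An [imaging_model()].
#' @param particles_xy Matrix or data.frame with columns `x_um`, `y_um` of
#'   bead positions (one row per bead).
#' @param z_range_um Length-2 sweep range of the piezo set position (um).
#' @param step_um Piezo step in um (default 0.05, i.e. 50 nm; use 0.025 for
#'   small beads).
#' @param z_focus_um Piezo position at which the beads are in focus.
#' @param seed RNG seed for the noise (generation is deterministic given the
#'   seed).
#' @return A list with `sweep` (a [focus_sweep()]) and `truth` (data.frame
#'   with `frame`, `z_set_um`, `z_rel_um`).
#' @export
render_focus_sweep <- function(model, particles_xy, z_range_um = c(0, 8),
                               step_um = 0.05, z_focus_um = 5, seed = 1L) {
  stopifnot(step_um > 0)
  particles_xy <- as.data.frame(particles_xy)
  z_set <- seq(z_range_um[1], z_range_um[2], by = step_um)
  base <- .illumination_surface(model)
  frames <- with_seed_(seed, lapply(z_set, function(zs) {
    beads <- data.frame(x_um = particles_xy$x_um, y_um = particles_xy$y_um,
                        z_rel_um = zs - z_focus_um)
    .render_frame(model, beads, base = base)
  }))
  list(sweep = focus_sweep(frames, z_set),
       truth = data.frame(frame = seq_along(z_set) - 1L, z_set_um = z_set,
                          z_rel_um = z_set - z_focus_um))
}

#' Render a synthetic transport video
#'
#' Renders beads at their true `(x, y, z_rel)` for every frame of a ground
#' truth table, plus illumination and noise.
#'
#' @param model An [imaging_model()].
#' @param truth Data.frame with columns `frame` (0-based), `bead`, `x_um`,
#'   `y_um`, `z_rel_um`; every frame index from 0 to `max(frame)` must be
#'   covered.
#' @param frame_rate_fps Frame rate (default 1000).
#' @param seed RNG seed.
#' @return A [video_stack()].
#' @export
render_transport_video <- function(model, truth, frame_rate_fps = 1000,
                                   seed = 1L) {
  fr_ids <- sort(unique(truth$frame))
  if (!identical(fr_ids, seq(0L, max(truth$frame))))
    stop("truth must cover all frames 0..max(frame)", call. = FALSE)
  base <- .illumination_surface(model)
  frames <- with_seed_(seed, lapply(fr_ids, function(f) {
    .render_frame(model, truth[truth$frame == f, , drop = FALSE], base = base)
  }))
  video_stack(frames, frame_rate_fps)
}

#' Ground-truth 3D trajectory of hopping transport
#'
#' Builds the lateral time course of the hopping motion - after every z-field
#' reversal of the pulse schedule, a smooth sigmoid transit of one domain
#' width towards the adjacent wall over `transit_time_ms` - and derives the
#' axial coordinate from the quasi-static force balance along it
#' ([transport_elevation_profile()]). y is constant. Transport is
#' unidirectional (+x): each reversal moves the bead one domain width
#' forward.
#'
#' @param pattern A [stripe_pattern()].
#' @param pulses A [pulse_sequence()] (one transit per ramp in the schedule).
#' @param particle A [particle_model()].
#' @param interactions An [interaction_params()].
#' @param transit_time_ms Duration of each lateral transit (default 60 ms).
#' @param x_start_um Starting wall position (default 0).
#' @param t_span_ms Length-2 time window; defaults to the full schedule.
#' @param dt_ms Sample spacing (default 1 ms).
#' @return A data.frame with `t_ms`, `x_um`, `z_um` (elevation above the
#'   pre-step equilibrium, min = 0), `gap_um`, `bracketed`.
#' @export
ground_truth_trajectory <- function(pattern, pulses, particle, interactions,
                                    transit_time_ms = 60, x_start_um = 0,
                                    t_span_ms = NULL, dt_ms = 1) {
  stopifnot(transit_time_ms > 0)
  if (is.null(t_span_ms)) t_span_ms <- c(0, pulses$duration_ms)
  tg <- seq(t_span_ms[1], t_span_ms[2], by = dt_ms)
  # mid-ramp reversal times of the schedule
  n_rev <- length(pulses$signs) - 1L
  t_rev <- pulses$plateau_ms + pulses$ramp_ms / 2 +
    (seq_len(n_rev) - 1L) * (pulses$plateau_ms + pulses$ramp_ms)
  tau <- transit_time_ms / 8
  x <- rep(x_start_um, length(tg))
  for (tr in t_rev) {
    x <- x + pattern$domain_width_um /
      (1 + exp(-(tg - (tr + transit_time_ms / 2)) / tau))
  }
  prof <- transport_elevation_profile(
    data.frame(t_ms = tg, x_um = x), particle, interactions, pattern, pulses,
    dt_ms = dt_ms)
  data.frame(t_ms = prof$t_ms, x_um = prof$x_um, z_um = prof$z_eq_um,
             gap_um = prof$gap_um, bracketed = prof$bracketed)
}

#' Default synthetic benchmark
#'
#' The standard study conditions for end-to-end validation: five 4-um
#' core-shell beads resting above adjacent head-to-head walls, a 50-nm-step
#' focus sweep, and a 1000-fps transport video of one field-reversal-induced
#' hopping step. The video window is centred on the step (equal pre- and
#' post-step rolls), so each bead dwells about equally at its start and end
#' wall; the bead "ghosts" of the mean-frame background then attenuate the
#' TBG equally before and after the step, as required for the
#' calibration-stability criterion. All randomness is seeded.
#'
#' @param seed RNG seed.
#' @param n_beads Number of beads (default 5; placed 10 um apart on
#'   successive hh walls).
#' @param video_ms Video duration in ms (default: the pulse schedule minus
#'   the start offset).
#' @param video_t0_ms Schedule time of the first video frame (default 60,
#'   which centres the hop in the default schedule).
#' @param delta0_um Defocus of the resting beads (default -1.5 um: below the
#'   focal plane, on the rising flank).
#' @param transit_time_ms Lateral transit duration per hop (default 60 ms).
#' @param model An [imaging_model()].
#' @param pattern,pulses,particle,interactions Physical models; defaults are
#'   the package defaults with 150 ms plateaus.
#' @return A list with `model`, `sweep` (+ sweep truth), `video`, `truth`
#'   (per-frame, per-bead 3D ground truth with `x_um`, `y_um`, `z_um`
#'   absolute elevation change and `z_rel_um` defocus; `t_ms` is schedule
#'   time), `trajectory` (the shared 1-ms ground-truth trajectory) and the
#'   physical model objects.
#' @export
default_benchmark <- function(seed = 1L, n_beads = 5L, video_ms = NULL,
                              video_t0_ms = 60, delta0_um = -1.5,
                              transit_time_ms = 60,
                              model = imaging_model(),
                              pattern = stripe_pattern(),
                              pulses = pulse_sequence(plateau_ms = 150),
                              particle = micromer_bead(),
                              interactions = interaction_params()) {
  if (is.null(video_ms)) video_ms <- pulses$duration_ms - video_t0_ms
  px <- model$pixel_size_um
  w_um <- (model$frame_w_px - 1) * px
  h_um <- (model$frame_h_px - 1) * px
  x0 <- pattern$period_um * seq_len(n_beads)          # hh walls at 0 mod P
  n_hops <- length(pulses$signs) - 1L
  if (max(x0) + n_hops * pattern$domain_width_um + 4 > w_um)
    stop("frame too small for the requested number of beads", call. = FALSE)
  y0 <- seq(0.25 * h_um, 0.75 * h_um, length.out = n_beads)
  traj <- ground_truth_trajectory(pattern, pulses, particle, interactions,
                                  transit_time_ms = transit_time_ms,
                                  t_span_ms = c(0, video_t0_ms + video_ms))
  n_frames <- as.integer(video_ms)                    # 1000 fps, 1 frame/ms
  tf <- video_t0_ms + (seq_len(n_frames) - 1)
  xf <- stats::approx(traj$t_ms, traj$x_um, xout = tf, rule = 2)$y
  zf <- stats::approx(traj$t_ms, traj$z_um, xout = tf, rule = 2)$y
  truth <- do.call(rbind, lapply(seq_len(n_beads), function(b) {
    data.frame(frame = seq_len(n_frames) - 1L, t_ms = tf, bead = b,
               x_um = x0[b] + (xf - traj$x_um[1]),
               y_um = y0[b], z_um = zf, z_rel_um = delta0_um + zf)
  }))
  # The sweep moves the *sample* past the fixed focal plane; with the focus
  # crossing at z_set = 5 um, the resting transport state (defocus delta0)
  # corresponds to z_set = 5 + delta0.
  sw <- render_focus_sweep(model, data.frame(x_um = x0, y_um = y0),
                           z_range_um = c(0, 8), step_um = 0.05,
                           z_focus_um = 5, seed = seed)
  video <- render_transport_video(model, truth, seed = seed + 1L)
  list(model = model, pattern = pattern, pulses = pulses, particle = particle,
       interactions = interactions, sweep = sw$sweep, sweep_truth = sw$truth,
       video = video, truth = truth, trajectory = traj,
       z_set_reference_um = 5 + delta0_um, delta0_um = delta0_um,
       seed = seed)
}
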