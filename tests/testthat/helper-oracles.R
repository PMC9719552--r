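# Independent oracles and shared fixtures, built in code.

# Brute-force Tenenbaum gradient: explicit nested-loop Sobel correlation over
# interior pixels. Written independently of the package implementation.
tbg_brute <- function(img) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # columns -1, 0, +1
  ky <- t(kx)
  nr <- nrow(img); nc <- ncol(img)
  acc <- 0
  for (i in 2:(nr - 1)) {
    for (j in 2:(nc - 1)) {
      patch <- img[(i - 1):(i + 1), (j - 1):(j + 1)]
      gx <- sum(patch * kx)
      gy <- sum(patch * ky)
      acc <- acc + gx^2 + gy^2
    }
  }
  acc
}

# Exact field of the infinite alternating line-charge array: positive walls at
# x = 0 mod P, negative at P/2 mod P. Complex closed form
# Hx - i Hz = (q/P) / sin(2 pi (x + i z) / P), lengths in metres.
field_closed_form <- function(x_um, z_um, wall_charge_A = 0.03,
                              period_um = 10) {
  w <- (x_um + 1i * z_um) * 1e-6
  P <- period_um * 1e-6
  f <- (wall_charge_A / P) / sin(2 * pi * w / P)
  list(Hx_Am = Re(f), Hz_Am = -Im(f))
}

# Small imaging model for fast single-bead rendering tests.
tiny_model <- function(...) {
  imaging_model(frame_w_px = 200L, frame_h_px = 200L, ...)
}

# TBG of a single bead rendered at a given defocus on a clean (noise-free)
# canvas; used for curve-shape properties.
render_tbg <- function(model, z_rel_um, roi_size = 60L, noise = FALSE,
                       center_px = 100) {
  base <- magbead3d:::.illumination_surface(model)
  ctr_um <- center_px * model$pixel_size_um
  fr <- magbead3d:::.render_frame(
    model, data.frame(x_um = ctr_um, y_um = ctr_um, z_rel_um = z_rel_um),
    base = base, noise = noise)
  sub <- subtract_background(fr, base)
  roi <- crop_roi(sub, c(ctr_um, ctr_um), roi_size, model$pixel_size_um)
  tenenbaum_gradient(roi)
}

# Scaled-down end-to-end benchmark: two beads on a 320x240 px canvas, one
# hopping step with symmetric pre/post rolls.
small_benchmark <- function(seed = 7L, ...) {
  default_benchmark(
    seed = seed, n_beads = 2L,
    model = imaging_model(frame_w_px = 320L, frame_h_px = 240L),
    pulses = pulse_sequence(plateau_ms = 70),
    transit_time_ms = 30, video_t0_ms = 30, ...)
}

# Match each 3D track of a pipeline result to the ground-truth bead whose
# starting position it shares; returns per-track accuracy summaries.
benchmark_accuracy <- function(bm, res, z_focus_um = 5) {
  starts <- vapply(split(bm$truth, bm$truth$bead),
                   function(d) d$x_um[1], numeric(1))
  out <- NULL
  for (pid in names(res$tracks)) {
    tr <- res$tracks[[pid]]
    b <- which.min(abs(starts - tr$x_um[1]))
    if (abs(starts[b] - tr$x_um[1]) > 1) next   # clutter track, not a bead
    tt <- bm$truth[bm$truth$bead == b, ]
    m <- merge(tr, tt, by = "frame", suffixes = c("", ".true"))
    fit <- res$fits[[pid]]
    z_est_abs <- m$z_um + fit$z_reference_um
    z_true_abs <- m$z_rel_um + z_focus_um
    onflank <- z_true_abs >= fit$z_reference_um &
      z_true_abs <= fit$z_reference_um + fit$flank_length_um & m$roi_ok
    out <- rbind(out, data.frame(
      particle_id = pid, bead = b, n = nrow(m),
      x_rmse_um = sqrt(mean((m$x_um - m$x_um.true)^2)),
      y_rmse_um = sqrt(mean((m$y_um - m$y_um.true)^2)),
      n_flank = sum(onflank),
      z_mae_um = mean(abs(z_est_abs - z_true_abs)[onflank]),
      flank_length_um = fit$flank_length_um))
  }
  out
}
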