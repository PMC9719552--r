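# End-to-end 3D tracking: preprocessing, detection/linking, per-particle
# focus-sweep calibration, per-frame TBG evaluation and z mapping, with a
# calibration-stability gate.

#' Pipeline configuration
#'
#' Collects the tunable parameters of [track3d_pipeline()]. Units are
#' explicit in the names.
#'
#' @param pixel_size_um Pixel size (um/px).
#' @param roi_size ROI side length in px for the TBG computation (50 px for
#'   beads up to 3 um, 60 px for 4 um beads).
#' @param threshold Detection threshold on smoothed absolute contrast.
#' @param min_separation_um Minimum particle separation (um).
#' @param max_displacement_um Maximum frame-to-frame displacement (um).
#' @param lowpass_cutoff Fourier low-pass cutoff as a fraction of Nyquist.
#' @param equalize Apply histogram equalization during enhancement. Off by
#'   default: synthetic frames already span the full intensity range, and
#'   per-frame equalization rescales the TBG frame-dependently; enable it for
#'   low-contrast camera data.
#' @param r2_min Flank linearity criterion for [fit_calibration()].
#' @param stability_rel_tol Relative tolerance of the before/after TBG
#'   stability check ([calibration_stable()]).
#' @param match_radius_um Maximum distance between a video track start and its
#'   sweep detection for calibration matching.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_um = 0.11, roi_size = 60L,
                            threshold = 0.04, min_separation_um = 5,
                            max_displacement_um = 0.5, lowpass_cutoff = 0.35,
                            equalize = FALSE, r2_min = 0.98,
                            stability_rel_tol = 0.10, match_radius_um = 3) {
  structure(list(pixel_size_um = pixel_size_um, roi_size = as.integer(roi_size),
                 threshold = threshold, min_separation_um = min_separation_um,
                 max_displacement_um = max_displacement_um,
                 lowpass_cutoff = lowpass_cutoff, equalize = equalize,
                 r2_min = r2_min, stability_rel_tol = stability_rel_tol,
                 match_radius_um = match_radius_um),
            class = "pipeline_config")
}

#' Full 3D tracking pipeline
#'
#' Runs the complete evaluation chain on a transport video and the focus
#' sweep recorded in the same session:
#' \enumerate{
#'   \item enhance all frames (Fourier low-pass, optional equalization);
#'   \item estimate the illumination background as the mean over all video
#'     frames and subtract it from video and sweep frames alike;
#'   \item detect particles per video frame and link them into 2D tracks;
#'   \item locate each particle in the sweep (sharpest frame), compute its
#'     sharpness curve and fit the rising-flank calibration;
#'   \item evaluate the TBG in a fixed-size ROI around the tracked centre in
#'     every frame and map it to a relative z with uncertainty;
#'   \item keep only particles whose TBG before and after the lateral
#'     movement agrees within the stability tolerance.
#' }
#' Particles without a matched calibration, with a failed flank fit, with
#' out-of-frame ROIs, or failing the stability check are excluded from the
#' axial analysis with a logged reason (their 2D track is still reported).
#'
#' @param video A [video_stack()].
#' @param sweep A [focus_sweep()] sharing optics and session background with
#'   the video.
#' @param config A [pipeline_config()].
#' @return An object of class `track3d_result`: a list with `tracks` (list of
#'   per-particle data.frames: `frame`, `t_ms`, `x_um`, `y_um`, `z_um`,
#'   `z_sigma_um`, `tbg`, `extrapolated`, `roi_ok`), `fits` (per-particle
#'   calibration fits), `excluded` (named reasons) and `report` (counts,
#'   flank lengths, slopes, config echo).
#' @export
track3d_pipeline <- function(video, sweep, config = pipeline_config()) {
  stopifnot(inherits(video, "video_stack"), inherits(sweep, "focus_sweep"))
  cfg <- config
  enh <- function(fr) enhance_frame(fr, cfg$lowpass_cutoff, cfg$equalize)
  # single pass: enhance, detect, accumulate the background sum
  # (detection runs on the enhanced frames directly: its band-pass contrast
  # removes the illumination surface per frame and, unlike the mean
  # background, carries no "ghosts" of the moving particles; the TBG path
  # below keeps the mean background, on which the calibration is defined)
  n_fr <- length(video$frames)
  vsub <- vector("list", n_fr)
  detections <- vector("list", n_fr)
  bg_sum <- NULL
  for (i in seq_len(n_fr)) {
    e <- enh(video$frames[[i]])
    detections[[i]] <- detect_particles(e, cfg$pixel_size_um,
                                        cfg$min_separation_um, cfg$threshold)
    bg_sum <- if (is.null(bg_sum)) e else bg_sum + e
    vsub[[i]] <- e
  }
  background <- bg_sum / n_fr
  for (i in seq_len(n_fr))
    vsub[[i]] <- subtract_background(vsub[[i]], background)
  tracks2d <- link_trajectories(detections, cfg$max_displacement_um,
                                video$frame_rate_fps)

  # locate sweep particles on the sharpest (highest-variance) subtracted frame
  ssub <- lapply(sweep$frames, function(fr)
    subtract_background(enh(fr), background))
  sharpest <- which.max(vapply(ssub, function(fr)
    stats::var(as.vector(fr)), numeric(1)))
  sweep_det <- detect_particles(enh(sweep$frames[[sharpest]]),
                                cfg$pixel_size_um, cfg$min_separation_um,
                                cfg$threshold)
  sweep_sub <- focus_sweep(ssub, sweep$z_set_um)

  out_tracks <- list(); fits <- list(); excluded <- character()
  for (tr in tracks2d) {
    pid <- attr(tr, "particle_id")
    x0 <- tr$x_um[1]; y0 <- tr$y_um[1]
    if (!nrow(sweep_det)) { excluded[pid] <- "no sweep detections"; next }
    d <- sqrt((sweep_det$x_um - x0)^2 + (sweep_det$y_um - y0)^2)
    if (min(d) > cfg$match_radius_um) {
      excluded[pid] <- "no matching sweep particle"
      next
    }
    k <- which.min(d)
    ctr_px <- c(sweep_det$x_px[k], sweep_det$y_px[k])
    # flags are inspected programmatically below; no need to re-warn
    curve <- tryCatch(
      suppressWarnings(
        sweep_to_curve(sweep_sub, ctr_px, cfg$roi_size, particle_id = pid)),
      error = function(e) NULL)
    if (is.null(curve) || "no focus found" %in% curve$flags) {
      excluded[pid] <- "sweep curve unusable"
      next
    }
    fit <- tryCatch(fit_calibration(curve, r2_min = cfg$r2_min),
                    error = function(e) NULL)
    if (is.null(fit)) { excluded[pid] <- "calibration fit failed"; next }

    tbg <- rep(NA_real_, nrow(tr)); roi_ok <- rep(FALSE, nrow(tr))
    for (i in seq_len(nrow(tr))) {
      roi <- tryCatch(
        crop_roi(vsub[[tr$frame[i] + 1L]], c(tr$x_um[i], tr$y_um[i]),
                 cfg$roi_size, cfg$pixel_size_um),
        error = function(e) NULL)
      if (!is.null(roi)) { tbg[i] <- tenenbaum_gradient(roi); roi_ok[i] <- TRUE }
    }
    if (!any(roi_ok)) { excluded[pid] <- "all ROIs out of frame"; next }
    nhead <- min(5L, sum(roi_ok))
    tbg_ok <- tbg[roi_ok]
    tbg_start <- mean(utils::head(tbg_ok, nhead))
    tbg_end <- mean(utils::tail(tbg_ok, nhead))
    if (!calibration_stable(tbg_start, tbg_end, cfg$stability_rel_tol)) {
      excluded[pid] <- sprintf("calibration unstable (TBG %.1f -> %.1f)",
                               tbg_start, tbg_end)
      next
    }
    zmap <- tbg_to_z(ifelse(is.na(tbg), fit$tbg_reference, tbg), fit)
    res <- data.frame(frame = tr$frame, t_ms = tr$t_ms, x_um = tr$x_um,
                      y_um = tr$y_um, z_um = ifelse(roi_ok, zmap$z_um, NA),
                      z_sigma_um = ifelse(roi_ok, zmap$z_sigma_um, NA),
                      tbg = tbg,
                      extrapolated = roi_ok & zmap$extrapolated,
                      roi_ok = roi_ok)
    attr(res, "particle_id") <- pid
    out_tracks[[pid]] <- res
    fits[[pid]] <- fit
  }
  report <- list(
    n_frames = length(video$frames),
    n_detections = sum(vapply(detections, nrow, integer(1))),
    n_tracks_2d = length(tracks2d),
    n_tracks_3d = length(out_tracks),
    n_excluded = length(excluded),
    excluded = excluded,
    flank_length_um = vapply(fits, `[[`, numeric(1), "flank_length_um"),
    slope_tbg_per_um = vapply(fits, `[[`, numeric(1), "slope"),
    inverse_slope_um_per_tbg =
      vapply(fits, `[[`, numeric(1), "inverse_slope_um_per_tbg"),
    config = unclass(cfg)
  )
  structure(list(tracks = out_tracks, tracks2d = tracks2d, fits = fits,
                 excluded = excluded, report = report),
            class = "track3d_result")
}

#' @export
print.track3d_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<track3d_result> %d frames, %d 2D tracks, %d with z (excluded: %d)\n",
              r$n_frames, r$n_tracks_2d, r$n_tracks_3d, r$n_excluded))
  if (length(r$excluded))
    for (p in names(r$excluded)) cat(sprintf("  - %s: %s\n", p, r$excluded[p]))
  if (length(r$slope_tbg_per_um))
    cat(sprintf("  flank %.2f-%.2f um, inverse slope %.4g-%.4g um/TBG\n",
                min(r$flank_length_um), max(r$flank_length_um),
                min(r$inverse_slope_um_per_tbg),
                max(r$inverse_slope_um_per_tbg)))
  invisible(x)
}
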