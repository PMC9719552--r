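# Frame containers and preprocessing: contrast enhancement, Fourier low-pass,
# mean-frame background estimation and subtraction.
#
# Frames are plain numeric matrices with intensities in [0, 1]
# (rows = y downward, columns = x rightward, origin at the top-left pixel
# centre). Physical scale is carried by an explicit pixel size argument where
# needed.

#' Video stack container
#'
#' @param frames List of same-sized numeric matrices in `[0, 1]`.
#' @param frame_rate_fps Acquisition frame rate (default 1000 fps, the rate
#'   used for the transport recordings).
#' @return An object of class `video_stack`.
#' @export
video_stack <- function(frames, frame_rate_fps = 1000) {
  if (!length(frames)) stop("empty frame list", call. = FALSE)
  d <- dim(frames[[1]])
  for (fr in frames) {
    .assert_image(fr)
    if (!identical(dim(fr), d))
      stop("all frames must have identical dimensions", call. = FALSE)
  }
  .assert_scalar_pos(frame_rate_fps, "frame_rate_fps")
  structure(list(frames = frames, frame_rate_fps = frame_rate_fps),
            class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<video_stack> %d frames of %dx%d px at %g fps\n",
              length(x$frames), d[2], d[1], x$frame_rate_fps))
  invisible(x)
}

#' Focus-sweep container
#'
#' A stack of reference frames taken while stepping the sample axially through
#' the focal plane with a piezo stage (typically 25 or 50 nm steps). The step
#' must be uniform within 1%.
#'
#' @param frames List of same-sized numeric matrices in `[0, 1]`.
#' @param z_set_um Strictly increasing piezo set positions, one per frame (um).
#' @return An object of class `focus_sweep` with the inferred `step_um`.
#' @export
focus_sweep <- function(frames, z_set_um) {
  if (length(frames) != length(z_set_um))
    stop("need one z set-point per frame", call. = FALSE)
  d <- dim(frames[[1]])
  for (fr in frames) {
    .assert_image(fr)
    if (!identical(dim(fr), d))
      stop("all frames must have identical dimensions", call. = FALSE)
  }
  dz <- diff(z_set_um)
  if (any(dz <= 0)) stop("'z_set_um' must be strictly increasing", call. = FALSE)
  step <- stats::median(dz)
  if (any(abs(dz - step) > 0.01 * step))
    stop("z step must be uniform within 1%", call. = FALSE)
  structure(list(frames = frames, z_set_um = as.numeric(z_set_um),
                 step_um = step),
            class = "focus_sweep")
}

#' @export
print.focus_sweep <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<focus_sweep> %d frames of %dx%d px, z %g..%g um in %g nm steps\n",
              length(x$frames), d[2], d[1], min(x$z_set_um), max(x$z_set_um),
              1000 * x$step_um))
  invisible(x)
}

# Hard circular low-pass mask in the 2D Fourier domain at radius
# cutoff * Nyquist; real part of the inverse transform.
.fourier_lowpass <- function(img, cutoff) {
  nr <- nrow(img); nc <- ncol(img)
  rho <- sqrt(outer(.fft_freq(nr)^2, .fft_freq(nc)^2, `+`))
  mask <- rho <= cutoff * 0.5
  Re(stats::fft(stats::fft(img) * mask, inverse = TRUE)) / (nr * nc)
}

#' Contrast enhancement and Fourier low-pass denoising
#'
#' Applies (1) global 256-level histogram equalization onto the full `[0, 1]`
#' output range and (2) an isotropic hard circular low-pass mask in the 2D
#' Fourier domain at radius `lowpass_cutoff` x Nyquist, taking the real part of
#' the inverse transform. A constant frame passes through unchanged.
#'
#' @param frame Numeric matrix in `[0, 1]`.
#' @param lowpass_cutoff Fraction of the Nyquist frequency kept, in `(0, 1]`
#'   (default 0.3).
#' @param equalize Apply the histogram equalization step (default TRUE).
#' @return The enhanced frame, clipped to `[0, 1]`.
#' @export
enhance_frame <- function(frame, lowpass_cutoff = 0.3, equalize = TRUE) {
  .assert_image(frame)
  if (!is.numeric(lowpass_cutoff) || length(lowpass_cutoff) != 1 ||
      lowpass_cutoff <= 0 || lowpass_cutoff > 1)
    stop("'lowpass_cutoff' must be in (0, 1]", call. = FALSE)
  out <- frame
  if (isTRUE(equalize)) {
    # constant images cannot be equalized; leave them untouched
    out <- suppressWarnings(
      EBImage::equalize(out, range = c(0, 1), levels = 256))
    out <- matrix(as.numeric(out), nrow(frame), ncol(frame))
  }
  if (lowpass_cutoff < 1) out <- .fourier_lowpass(out, lowpass_cutoff)
  .clip01(out)
}

#' Mean-frame background estimate
#'
#' Pixel-wise mean over all frames of a video. Moving particles are diluted by
#' 1/N per pixel dwell, so the mean approximates the static inhomogeneous
#' illumination background.
#'
#' @param video A [video_stack()] or a list of frames (>= 2).
#' @return A background frame (numeric matrix).
#' @export
estimate_background <- function(video) {
  frames <- if (inherits(video, "video_stack")) video$frames else video
  if (length(frames) < 2) stop("need at least 2 frames", call. = FALSE)
  Reduce(`+`, frames) / length(frames)
}

#' Robust per-pixel quantile background
#'
#' Per-pixel upper-quantile intensity over a strided subsample of frames.
#' Unlike the mean ([estimate_background()]), an upper quantile is insensitive
#' to dark particles that dwell at one position for up to `q` of the time, so
#' it estimates the illumination surface without particle "ghosts". Used for
#' detection; the TBG path keeps the mean background, which is what the
#' z-calibration is defined on.
#'
#' @param video A [video_stack()] or list of frames.
#' @param q Quantile in (0, 1) (default 0.75).
#' @param max_frames Subsample size (default 24; frames are taken evenly
#'   spaced).
#' @return A background frame (numeric matrix).
#' @export
quantile_background <- function(video, q = 0.75, max_frames = 24L) {
  frames <- if (inherits(video, "video_stack")) video$frames else video
  if (length(frames) < 2) stop("need at least 2 frames", call. = FALSE)
  if (q <= 0 || q >= 1) stop("'q' must be in (0, 1)", call. = FALSE)
  idx <- unique(round(seq(1, length(frames),
                          length.out = min(max_frames, length(frames)))))
  np <- length(frames[[1]])
  M <- vapply(frames[idx], as.vector, numeric(np))
  K <- ncol(M)
  # vectorized compare-exchange sort across the (few) sampled frames
  for (j in 2:K) {
    for (i in j:2) {
      a <- M[, i - 1L]; b <- M[, i]
      lo <- pmin(a, b)
      M[, i - 1L] <- lo
      M[, i] <- a + b - lo
    }
  }
  k <- max(1L, min(K, ceiling(q * K)))
  matrix(M[, k], nrow(frames[[1]]), ncol(frames[[1]]))
}

#' Subtract an illumination background from a frame
#'
#' Computes `frame - background`, re-centres the difference at the output
#' mid-range (0.5) and clips to `[0, 1]`. Re-centring keeps the result
#' displayable and TBG-comparable while preserving the sign of the bead
#' contrast. A frame equal to its background maps to a uniform 0.5 with zero
#' Tenenbaum gradient.
#'
#' @param frame,background Numeric matrices of identical dimensions.
#' @return The background-subtracted frame.
#' @export
subtract_background <- function(frame, background) {
  .assert_image(frame)
  if (!identical(dim(frame), dim(background)))
    stop("frame and background dimensions differ", call. = FALSE)
  .clip01(frame - background + 0.5)
}
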