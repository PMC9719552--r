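# Sharpness quantification and focus-sweep calibration for axial localization.

#' Optical model of the imaging setup
#'
#' Bundles the optical parameters needed for depth-of-field estimates and for
#' converting pixels to physical lengths. Defaults correspond to a high-NA
#' oil-immersion bright-field setup (white light, 100x objective) imaging at
#' 0.11 um per pixel.
#'
#' @param wavelength_nm Central illumination wavelength in nm.
#' @param numerical_aperture Objective numerical aperture (0 < NA <= 1.7).
#' @param pixel_size_um Physical size of one camera pixel in the sample plane,
#'   in micrometres per pixel.
#' @param magnification Objective magnification (informational).
#' @return An object of class `optics_model`.
#' @export
#' @examples
#' om <- optics_model()
#' compute_dof(om)      # 127.55 nm
#' dof_reported(om)     # 130 nm
optics_model <- function(wavelength_nm = 500, numerical_aperture = 1.4,
                         pixel_size_um = 0.11, magnification = 100) {
  .assert_scalar_pos(wavelength_nm, "wavelength_nm")
  .assert_scalar_pos(numerical_aperture, "numerical_aperture")
  if (numerical_aperture > 1.7)
    stop("'numerical_aperture' must be <= 1.7", call. = FALSE)
  .assert_scalar_pos(pixel_size_um, "pixel_size_um")
  structure(list(wavelength_nm = wavelength_nm,
                 numerical_aperture = numerical_aperture,
                 pixel_size_um = pixel_size_um,
                 magnification = magnification),
            class = "optics_model")
}

#' Diffraction-limited depth of field
#'
#' Computes the depth of field `DOF = lambda / (2 NA^2)`, the axial range over
#' which an object appears in focus. A thin DOF is what makes the sharpness
#' metric a sensitive probe of the axial coordinate.
#'
#' @param optics An [optics_model()].
#' @return Depth of field in nm.
#' @export
compute_dof <- function(optics) {
  stopifnot(inherits(optics, "optics_model"))
  optics$wavelength_nm / (2 * optics$numerical_aperture^2)
}

#' @rdname compute_dof
#' @details `dof_reported()` rounds the value to the nearest 10 nm for
#'   reporting.
#' @export
dof_reported <- function(optics) {
  round(compute_dof(optics) / 10) * 10
}

#' Tenenbaum (Tenengrad) gradient of an image
#'
#' Sums the squared responses of the horizontal and vertical 3x3 Sobel
#' operators over all interior pixels of the image:
#' `f_TBG = sum_ij Gx(i,j)^2 + Gy(i,j)^2`. The Sobel kernels are the
#' unnormalized `[[-1,0,1],[-2,0,2],[-1,0,1]]` form (applied as correlation;
#' the sign convention is immaterial under squaring). The one-pixel border is
#' excluded so the metric does not depend on a padding convention.
#'
#' The TBG is maximal when the imaged object is in focus and decreases towards
#' a noise-floor plateau with increasing defocus, which is what the focus-sweep
#' calibration exploits.
#'
#' @param image Numeric matrix of intensities, at least 3x3, all finite.
#' @return A single non-negative number (TBG units; quadratic in intensity).
#' @export
tenenbaum_gradient <- function(image) {
  .assert_image(image)
  nr <- nrow(image); nc <- ncol(image)
  i <- 2:(nr - 1L); j <- 2:(nc - 1L)
  gx <- (image[i - 1L, j + 1L] + 2 * image[i, j + 1L] + image[i + 1L, j + 1L]) -
        (image[i - 1L, j - 1L] + 2 * image[i, j - 1L] + image[i + 1L, j - 1L])
  gy <- (image[i + 1L, j - 1L] + 2 * image[i + 1L, j] + image[i + 1L, j + 1L]) -
        (image[i - 1L, j - 1L] + 2 * image[i - 1L, j] + image[i - 1L, j + 1L])
  sum(gx * gx + gy * gy)
}

#' Sharpness curve of a focus sweep
#'
#' Container for TBG values sampled against the piezo set position during a
#' focus sweep of a single particle.
#'
#' @param z_set_um Strictly increasing piezo positions in um.
#' @param tbg Finite, non-negative TBG values, one per position.
#' @param roi_size ROI side length in pixels used for the TBG computation.
#' @param particle_id Identifier of the particle the curve belongs to.
#' @param flags Optional character vector of quality flags.
#' @return An object of class `sharpness_curve`.
#' @export
sharpness_curve <- function(z_set_um, tbg, roi_size = NA_integer_,
                            particle_id = NA_character_, flags = character()) {
  if (length(z_set_um) != length(tbg))
    stop("'z_set_um' and 'tbg' must have the same length", call. = FALSE)
  if (any(diff(z_set_um) <= 0))
    stop("'z_set_um' must be strictly increasing", call. = FALSE)
  if (!all(is.finite(tbg)) || any(tbg < 0))
    stop("'tbg' values must be finite and >= 0", call. = FALSE)
  structure(list(z_set_um = as.numeric(z_set_um), tbg = as.numeric(tbg),
                 roi_size = roi_size, particle_id = particle_id, flags = flags),
            class = "sharpness_curve")
}

#' @export
print.sharpness_curve <- function(x, ...) {
  cat(sprintf("<sharpness_curve> particle %s: %d samples, z [%.3f, %.3f] um, peak TBG %.4g at %.3f um\n",
              x$particle_id, length(x$tbg), min(x$z_set_um), max(x$z_set_um),
              max(x$tbg), x$z_set_um[which.max(x$tbg)]))
  if (length(x$flags)) cat(" flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Compute a sharpness curve from a focus sweep
#'
#' Crops a fixed region of interest around `roi_center_px` out of every
#' (optionally background-subtracted) sweep frame and evaluates the Tenenbaum
#' gradient per frame. Well-formed sweeps yield a single-peaked curve; a flat
#' curve is flagged `"no focus found"` and curves with several comparable
#' maxima are flagged `"multiple peaks"`.
#'
#' @param sweep A [focus_sweep()].
#' @param roi_center_px Numeric length-2 `(x, y)` ROI centre in pixels
#'   (0-based, origin at the top-left pixel centre, x rightward, y downward).
#' @param roi_size ROI side length in pixels.
#' @param background Optional background frame (same size as the sweep frames)
#'   subtracted from every frame before the TBG computation.
#' @param particle_id Identifier stored with the curve.
#' @return A [sharpness_curve()].
#' @export
sweep_to_curve <- function(sweep, roi_center_px, roi_size,
                           background = NULL, particle_id = NA_character_) {
  stopifnot(inherits(sweep, "focus_sweep"))
  tbg <- vapply(sweep$frames, function(fr) {
    if (!is.null(background)) fr <- subtract_background(fr, background)
    roi <- .crop_roi_px(fr, roi_center_px, roi_size)
    tenenbaum_gradient(roi)
  }, numeric(1))
  flags <- character()
  rng <- max(tbg) - min(tbg)
  if (rng <= 1e-12 * max(max(tbg), 1e-300)) {
    flags <- c(flags, "no focus found")
    warning("sharpness curve is constant: no focus found", call. = FALSE)
  } else {
    # prominent local maxima of the lightly smoothed curve
    s <- stats::filter(tbg, rep(1 / 3, 3), sides = 2)
    s[is.na(s)] <- tbg[is.na(s)]
    n <- length(s)
    if (n >= 3) {
      loc <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] > s[3:n]) + 1L
      prom <- loc[s[loc] > min(tbg) + 0.5 * rng]
      if (length(prom) > 1L) {
        flags <- c(flags, "multiple peaks")
        warning("sharpness curve has multiple prominent maxima", call. = FALSE)
      }
    }
  }
  sharpness_curve(sweep$z_set_um, tbg, roi_size = roi_size,
                  particle_id = particle_id, flags = flags)
}

#' Fit the rising-flank calibration of a sharpness curve
#'
#' Selects the rising flank of the curve (samples strictly below the global
#' TBG maximum), trims it to the longest contiguous sub-interval whose linear
#' fit reaches `R^2 >= r2_min` with positive slope, and performs an ordinary
#' least-squares fit of TBG on z. The flank start is the calibration reference:
#' [tbg_to_z()] maps the TBG at the flank start to relative z = 0.
#'
#' The rising flank is used because it is the steepest, most sensitive branch
#' of the curve; with the optics used here it spans roughly 2-4 um and behaves
#' nearly linearly.
#'
#' @param curve A [sharpness_curve()].
#' @param r2_min Linearity criterion for the flank trimming (default 0.98).
#' @param min_len Minimum number of flank samples (default 4).
#' @return An object of class `calibration_fit` with elements `slope`
#'   (TBG units per um), `intercept`, `inverse_slope_um_per_tbg`, `covariance`
#'   (2x2, ordered intercept then slope), `residual_sd`, `r_squared`,
#'   `flank_range` (index interval into the curve), `flank_length_um`,
#'   `z_reference_um`, `tbg_reference` and `tbg_range` (observed TBG range on
#'   the flank, used for extrapolation flagging).
#' @export
fit_calibration <- function(curve, r2_min = 0.98, min_len = 4L) {
  stopifnot(inherits(curve, "sharpness_curve"))
  z <- curve$z_set_um; y <- curve$tbg
  m <- which.max(y)
  if (m - 1L < min_len)
    stop("calibration failure: fewer than ", min_len,
         " samples below the sharpness peak", call. = FALSE)
  nf <- m - 1L
  zf <- z[seq_len(nf)]; yf <- y[seq_len(nf)]
  # prefix sums for O(1) window statistics
  cz <- c(0, cumsum(zf));  cy <- c(0, cumsum(yf))
  czz <- c(0, cumsum(zf * zf)); cyy <- c(0, cumsum(yf * yf))
  czy <- c(0, cumsum(zf * yf))
  best <- NULL
  # longest contiguous window with linear R^2 >= r2_min and positive slope
  for (i in seq_len(nf - min_len + 1L)) {
    jj <- (i + min_len - 1L):nf
    n <- jj - i + 1L
    sz <- cz[jj + 1L] - cz[i];   sy <- cy[jj + 1L] - cy[i]
    szz <- czz[jj + 1L] - czz[i]; syy <- cyy[jj + 1L] - cyy[i]
    szy <- czy[jj + 1L] - czy[i]
    sxx <- szz - sz * sz / n
    syy2 <- syy - sy * sy / n
    sxy <- szy - sz * sy / n
    r2 <- ifelse(sxx > 0 & syy2 > 0, sxy * sxy / (sxx * syy2), 0)
    ok <- r2 >= r2_min & sxy > 0
    if (any(ok)) {
      kk <- which(ok)
      k <- kk[which.max(n[kk] + r2[kk])]  # longest, ties by higher R^2
      if (is.null(best) || n[k] > best$len ||
          (n[k] == best$len && r2[k] > best$r2)) {
        best <- list(i = i, j = jj[k], len = n[k], r2 = r2[k])
      }
    }
  }
  if (is.null(best))
    stop("calibration failure: no contiguous rising flank with R^2 >= ",
         r2_min, call. = FALSE)
  idx <- best$i:best$j
  fit <- stats::lm(y[idx] ~ z[idx])
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration failure: non-positive flank slope", call. = FALSE)
  structure(list(
    slope = slope,
    intercept = intercept,
    inverse_slope_um_per_tbg = 1 / slope,
    covariance = unname(stats::vcov(fit)),
    residual_sd = stats::sigma(fit),
    r_squared = best$r2,
    flank_range = c(best$i, best$j),
    flank_length_um = z[best$j] - z[best$i],
    z_reference_um = z[best$i],
    tbg_reference = intercept + slope * z[best$i],
    tbg_range = range(y[idx]),
    particle_id = curve$particle_id
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> particle %s\n", x$particle_id))
  cat(sprintf("  slope %.4g TBG/um (inverse %.4g um/TBG), intercept %.4g\n",
              x$slope, x$inverse_slope_um_per_tbg, x$intercept))
  cat(sprintf("  flank samples %d..%d (%.2f um), R^2 %.4f, residual sd %.4g\n",
              x$flank_range[1], x$flank_range[2], x$flank_length_um,
              x$r_squared, x$residual_sd))
  invisible(x)
}

#' Convert a TBG value to a relative axial position
#'
#' Inverts the linear flank calibration: `z = (tbg - intercept)/slope`,
#' reported relative to the flank start (`z_reference_um`), so that the TBG at
#' the flank start maps to z = 0. Larger piezo z corresponds to the particle
#' sitting closer to the objective, i.e. higher elevation.
#'
#' The uncertainty is first-order propagation of the (intercept, slope) fit
#' covariance plus the observation scatter `residual_sd/slope`, added in
#' quadrature. TBG values outside the fitted flank's observed TBG range are
#' still converted but flagged `extrapolated`.
#'
#' @param tbg_value Numeric vector of TBG values.
#' @param fit A [fit_calibration()] result.
#' @return A data.frame with columns `z_um`, `z_sigma_um`, `extrapolated`.
#' @export
tbg_to_z <- function(tbg_value, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (!is.numeric(tbg_value) || !all(is.finite(tbg_value)))
    stop("'tbg_value' must be finite numeric", call. = FALSE)
  if (fit$slope <= 0) stop("invalid fit: slope must be > 0", call. = FALSE)
  a <- fit$slope; b <- fit$intercept
  z_abs <- (tbg_value - b) / a
  z_rel <- z_abs - fit$z_reference_um
  # var of (t - b)/a from the fit covariance, gradient (-1/a, -(t-b)/a^2)
  g1 <- -1 / a
  g2 <- -(tbg_value - b) / a^2
  V <- fit$covariance
  var_fit <- g1^2 * V[1, 1] + 2 * g1 * g2 * V[1, 2] + g2^2 * V[2, 2]
  var_obs <- (fit$residual_sd / a)^2
  eps <- 1e-9 * max(diff(fit$tbg_range), 1)
  data.frame(
    z_um = z_rel,
    z_sigma_um = sqrt(pmax(var_fit + var_obs, 0)),
    extrapolated = tbg_value < fit$tbg_range[1] - eps |
      tbg_value > fit$tbg_range[2] + eps
  )
}

#' Check that a particle's calibration stayed valid during transport
#'
#' A per-particle calibration function is only trusted when the TBG measured
#' before and after the lateral movement is approximately equal (the particle
#' returned to its reference sharpness, hence to its reference elevation and
#' lighting). Returns `TRUE` iff
#' `|start - end| <= rel_tol * max(start, end)`.
#'
#' @param track_tbg_start,track_tbg_end Non-negative TBG values measured at
#'   the start and end of the lateral movement.
#' @param rel_tol Relative tolerance (default 0.10).
#' @return Logical.
#' @export
calibration_stable <- function(track_tbg_start, track_tbg_end, rel_tol = 0.10) {
  if (any(c(track_tbg_start, track_tbg_end) < 0))
    stop("TBG values must be >= 0", call. = FALSE)
  abs(track_tbg_start - track_tbg_end) <=
    rel_tol * pmax(track_tbg_start, track_tbg_end)
}
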