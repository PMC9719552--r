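# Lateral particle localization and frame-by-frame trajectory linking.
#
# Coordinates: image convention with the origin at the centre of the top-left
# pixel, x rightward (columns), y downward (rows); pixel positions are 0-based
# and converted to um by the pixel size. Beads may appear dark or bright
# against the background depending on the defocus side, so detection operates
# on absolute contrast.

#' Detect particles in a preprocessed frame
#'
#' Band-pass blob detection: the contrast image is the absolute
#' difference-of-Gaussians `|G(sigma) - G(bg_sigma)|`, which suppresses the
#' smooth illumination surface within each frame while responding to
#' bead-scale structure of either polarity. Candidates are local maxima of
#' this contrast above `threshold`; candidates closer than
#' `min_separation_um` are merged into the stronger one (and flagged).
#' Positions are refined to sub-pixel precision by an iterated
#' intensity-weighted centroid, which converges to the symmetric centre even
#' when a ring-shaped defocused bead seeds the search on its rim.
#'
#' @param frame Preprocessed (enhanced or background-subtracted) numeric
#'   matrix in `[0, 1]`.
#' @param pixel_size_um Pixel size in um/px.
#' @param min_separation_um Minimum particle separation in um; must correspond
#'   to at least 3 px. Should be at least the bead diameter, so that the
#'   ring-shaped appearance of defocused beads collapses to one candidate.
#' @param threshold Detection threshold on the band-pass contrast.
#' @param smooth_sigma_px Small (blob) scale of the band-pass in px
#'   (default 6: of the order of the bead radius, so a bead yields a single
#'   smooth blob).
#' @param bg_sigma_px Large (background) scale of the band-pass in px
#'   (default `4 * smooth_sigma_px`).
#' @return A data.frame with columns `x_um`, `y_um`, `x_px`, `y_px`,
#'   `peak_contrast`, `merged`. The `merged` flag is conservative: it marks
#'   detections whose support contained more than one contrast maximum within
#'   the minimum separation. Unresolved close pairs are always flagged, but a
#'   single strongly defocused (ring-shaped) bead flags itself too, so treat
#'   it as a resolution warning rather than proof of a pair.
#' @export
detect_particles <- function(frame, pixel_size_um = 0.11,
                             min_separation_um = 5, threshold = 0.04,
                             smooth_sigma_px = 6,
                             bg_sigma_px = 4 * smooth_sigma_px) {
  .assert_image(frame)
  .assert_scalar_pos(pixel_size_um, "pixel_size_um")
  sep_px <- min_separation_um / pixel_size_um
  if (sep_px < 3)
    stop("'min_separation_um' must be at least 3 pixels", call. = FALSE)
  s <- abs(.gauss_blur(frame, smooth_sigma_px) -
             .gauss_blur(frame, bg_sigma_px))
  nr <- nrow(s); nc <- ncol(s)
  if (nr < 3 || nc < 3) return(.empty_detections())
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  ctr <- s[i, j]
  ismax <- ctr >= threshold &
    ctr > s[i - 1, j] & ctr > s[i + 1, j] &
    ctr > s[i, j - 1] & ctr > s[i, j + 1] &
    ctr > s[i - 1, j - 1] & ctr > s[i - 1, j + 1] &
    ctr > s[i + 1, j - 1] & ctr > s[i + 1, j + 1]
  idx <- which(ismax, arr.ind = TRUE)
  if (!nrow(idx)) return(.empty_detections())
  rows <- idx[, 1] + 1L; cols <- idx[, 2] + 1L
  val <- s[cbind(rows, cols)]
  ord <- order(val, decreasing = TRUE)
  rows <- rows[ord]; cols <- cols[ord]; val <- val[ord]
  keep <- integer(0); merged <- logical(0)
  for (k in seq_along(val)) {
    if (length(keep)) {
      d2 <- (rows[k] - rows[keep])^2 + (cols[k] - cols[keep])^2
      hit <- which(d2 < sep_px^2)
      if (length(hit)) { merged[hit[1]] <- TRUE; next }
    }
    keep <- c(keep, k); merged <- c(merged, FALSE)
  }
  rows <- rows[keep]; cols <- cols[keep]; val <- val[keep]
  # sub-pixel refinement: median-thresholded intensity centroid over a
  # circular window, iterated (re-centred) so a seed on the rim of a
  # ring-shaped bead converges to the symmetric centre
  w <- max(2L, as.integer(round(sep_px / 2)))
  x_px <- y_px <- numeric(length(keep))
  for (k in seq_along(keep)) {
    cy <- rows[k] - 1; cx <- cols[k] - 1           # 0-based
    for (it in 1:6) {
      r0 <- max(1L, round(cy) + 1L - w); r1 <- min(nr, round(cy) + 1L + w)
      c0 <- max(1L, round(cx) + 1L - w); c1 <- min(nc, round(cx) + 1L + w)
      win <- s[r0:r1, c0:c1]
      ys <- (r0:r1) - 1; xs <- (c0:c1) - 1
      wgt <- pmax(win - stats::median(win), 0)
      wgt[outer((ys - cy)^2, (xs - cx)^2, `+`) > w^2] <- 0
      tot <- sum(wgt)
      if (tot <= 0) break
      cy <- sum(rowSums(wgt) * ys) / tot
      cx <- sum(colSums(wgt) * xs) / tot
    }
    y_px[k] <- cy; x_px[k] <- cx
  }
  # second suppression pass: centroids seeded on opposite rims of one object
  # converge to the same position and must be merged
  keep2 <- integer(0)
  for (k in order(val, decreasing = TRUE)) {
    if (length(keep2)) {
      d2 <- (y_px[k] - y_px[keep2])^2 + (x_px[k] - x_px[keep2])^2
      hit <- which(d2 < sep_px^2)
      if (length(hit)) { merged[keep2[hit[1]]] <- TRUE; next }
    }
    keep2 <- c(keep2, k)
  }
  out <- data.frame(x_um = x_px[keep2] * pixel_size_um,
                    y_um = y_px[keep2] * pixel_size_um,
                    x_px = x_px[keep2], y_px = y_px[keep2],
                    peak_contrast = val[keep2], merged = merged[keep2])
  out[order(out$x_um, out$y_um), , drop = FALSE]
}

.empty_detections <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0), x_px = numeric(0),
             y_px = numeric(0), peak_contrast = numeric(0),
             merged = logical(0))
}

#' Link per-frame detections into trajectories
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames under a
#' maximum displacement. Unmatched detections start new tracks; unmatched
#' tracks terminate (no gap closing). Ambiguous ties - two candidates whose
#' distances differ by less than 1e-6 um - terminate the track rather than
#' guess, since a false join would corrupt the per-particle calibration
#' downstream.
#'
#' @param detections List of per-frame detection data.frames (as returned by
#'   [detect_particles()]), ordered by frame; frame indices are 0-based.
#' @param max_displacement_um Maximum allowed frame-to-frame displacement (um).
#' @param frame_rate_fps Frame rate used to derive timestamps (default 1000).
#' @return A list of `track2d` data.frames with columns `frame`, `t_ms`,
#'   `x_um`, `y_um` and attribute `particle_id`.
#' @export
link_trajectories <- function(detections, max_displacement_um,
                              frame_rate_fps = 1000) {
  if (!length(detections)) return(list())
  tracks <- list()           # finished tracks
  active <- list()           # open tracks: list(rows = data.frame)
  tie_eps <- 1e-6
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    t_ms <- (f - 1) / frame_rate_fps * 1000
    nd <- if (is.null(det)) 0L else nrow(det)
    na <- length(active)
    if (na && nd) {
      px <- vapply(active, function(a) a$x_um[nrow(a)], numeric(1))
      py <- vapply(active, function(a) a$y_um[nrow(a)], numeric(1))
      D <- sqrt(outer(px, det$x_um, `-`)^2 + outer(py, det$y_um, `-`)^2)
      assign_a <- rep(NA_integer_, na)
      for (a in seq_len(na)) {
        d <- D[a, ]
        jmin <- which.min(d)
        if (d[jmin] > max_displacement_um) next
        # ambiguous tie: a second candidate at (almost) the same distance
        if (sum(d <= d[jmin] + tie_eps) > 1) next
        # mutual: this detection's nearest active track must be a, uniquely
        da <- D[, jmin]
        amin <- which.min(da)
        if (amin != a || sum(da <= da[amin] + tie_eps) > 1) next
        assign_a[a] <- jmin
      }
      taken <- assign_a[!is.na(assign_a)]
      for (a in seq_len(na)) {
        jj <- assign_a[a]
        if (!is.na(jj)) {
          active[[a]] <- rbind(active[[a]],
                               data.frame(frame = f - 1L, t_ms = t_ms,
                                          x_um = det$x_um[jj],
                                          y_um = det$y_um[jj]))
        }
      }
      ended <- which(is.na(assign_a))
      if (length(ended)) {
        tracks <- c(tracks, active[ended])
        active <- active[-ended]
      }
      new_j <- setdiff(seq_len(nd), taken)
      for (jj in new_j) {
        active <- c(active, list(data.frame(frame = f - 1L, t_ms = t_ms,
                                            x_um = det$x_um[jj],
                                            y_um = det$y_um[jj])))
      }
    } else if (nd) {
      for (jj in seq_len(nd)) {
        active <- c(active, list(data.frame(frame = f - 1L, t_ms = t_ms,
                                            x_um = det$x_um[jj],
                                            y_um = det$y_um[jj])))
      }
    } else if (na) {
      tracks <- c(tracks, active)
      active <- list()
    }
  }
  tracks <- c(tracks, active)
  # stable ordering: by first appearance, then x
  ord <- order(vapply(tracks, function(tr) tr$frame[1], numeric(1)),
               vapply(tracks, function(tr) tr$x_um[1], numeric(1)))
  tracks <- tracks[ord]
  for (k in seq_along(tracks)) {
    attr(tracks[[k]], "particle_id") <- sprintf("p%03d", k)
    class(tracks[[k]]) <- c("track2d", "data.frame")
  }
  tracks
}

# Crop a square ROI around a pixel-space centre (0-based x, y).
.crop_roi_px <- function(frame, center_px, roi_size) {
  L <- as.integer(roi_size)
  cx <- floor(center_px[1]) + 1L    # 1-based centre column
  cy <- floor(center_px[2]) + 1L
  lo <- ceiling(L / 2) - 1L
  hi <- floor(L / 2)
  rows <- (cy - lo):(cy + hi)
  cols <- (cx - lo):(cx + hi)
  if (rows[1] < 1L || cols[1] < 1L || rows[L] > nrow(frame) || cols[L] > ncol(frame))
    stop("ROI out of frame bounds", call. = FALSE)
  frame[rows, cols]
}

#' Crop a region of interest around a particle centre
#'
#' Extracts a square ROI of exactly `roi_size` x `roi_size` pixels placed
#' symmetrically around the (sub-pixel) particle centre; the centre pixel is
#' `floor(centre) + 1` along each axis, so an even-sized ROI is symmetric to
#' within half a pixel. Typical sizes are 50 px (5.5 um at 0.11 um/px) for
#' beads up to 3 um and 60 px (6.6 um) for 4 um beads.
#'
#' @param frame Numeric matrix.
#' @param center_um Length-2 `(x, y)` particle centre in um.
#' @param roi_size ROI side length in pixels.
#' @param pixel_size_um Pixel size in um/px.
#' @return A `roi_size` x `roi_size` numeric matrix. ROIs touching or
#'   exceeding the frame edge raise an error (such particles are excluded from
#'   the axial analysis).
#' @export
crop_roi <- function(frame, center_um, roi_size, pixel_size_um = 0.11) {
  .assert_image(frame)
  .assert_scalar_pos(pixel_size_um, "pixel_size_um")
  .crop_roi_px(frame, center_um / pixel_size_um, roi_size)
}

#' Bind a list of tracks into one data.frame
#'
#' @param tracks List of `track2d` objects from [link_trajectories()].
#' @return A data.frame with a `particle_id` column.
#' @export
tracks_to_df <- function(tracks) {
  if (!length(tracks)) {
    return(data.frame(particle_id = character(0), frame = integer(0),
                      t_ms = numeric(0), x_um = numeric(0), y_um = numeric(0)))
  }
  do.call(rbind, lapply(tracks, function(tr) {
    cbind(data.frame(particle_id = attr(tr, "particle_id")),
          as.data.frame(tr))
  }))
}
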