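# File formats: TIFF stacks in, CSV / YAML out.

#' Read an image stack
#'
#' Reads either a multi-page TIFF file or a directory of numbered TIFF/PNG
#' frames (8- or 16-bit grayscale; RGB frames are averaged to grayscale).
#' Intensities are returned in `[0, 1]`.
#'
#' @param path Path to a `.tif`/`.tiff` file or a directory of frames.
#' @return A list of numeric matrices.
#' @export
read_stack <- function(path) {
  to_gray <- function(a) {
    if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
    a
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no TIFF/PNG frames in ", path, call. = FALSE)
    lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) {
        if (!requireNamespace("png", quietly = TRUE))
          stop("package 'png' required for PNG frames", call. = FALSE)
        to_gray(png::readPNG(f))
      } else to_gray(tiff::readTIFF(f))
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, to_gray)
  }
}

#' Write an image stack as multi-page TIFF
#'
#' @param frames List of numeric matrices in `[0, 1]` (or a [video_stack()] /
#'   [focus_sweep()]).
#' @param path Output `.tif` path.
#' @param bits_per_sample 8 or 16 (default 16).
#' @param sidecar Optional named list written as a YAML sidecar next to the
#'   stack (e.g. preprocessing settings or z set-points).
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path, bits_per_sample = 16L, sidecar = NULL) {
  if (inherits(frames, "video_stack") || inherits(frames, "focus_sweep"))
    frames <- frames$frames
  tiff::writeTIFF(lapply(frames, .clip01), path,
                  bits.per.sample = as.integer(bits_per_sample))
  if (!is.null(sidecar))
    yaml::write_yaml(sidecar, paste0(tools::file_path_sans_ext(path), ".yaml"))
  invisible(path)
}

#' Write 3D tracks as CSV files
#'
#' One CSV per particle with columns `particle_id`, `frame` (0-based),
#' `t_ms`, `x_um`, `y_um`, `z_um`, `z_sigma_um`, `tbg`, `extrapolated`,
#' `roi_ok`; coordinates in image convention (origin at the top-left pixel
#' centre, y downward), lengths in um. A `report.yaml` with the run summary
#' and resolved configuration is written alongside.
#'
#' @param result A `track3d_result` from [track3d_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_tracks_csv <- function(result, dir) {
  stopifnot(inherits(result, "track3d_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (pid in names(result$tracks)) {
    df <- cbind(particle_id = pid, result$tracks[[pid]])
    p <- file.path(dir, sprintf("track3d_%s.csv", pid))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  rep <- result$report
  rep$excluded <- as.list(rep$excluded)
  rep$flank_length_um <- as.list(rep$flank_length_um)
  rep$slope_tbg_per_um <- as.list(rep$slope_tbg_per_um)
  rep$inverse_slope_um_per_tbg <- as.list(rep$inverse_slope_um_per_tbg)
  yaml::write_yaml(rep, file.path(dir, "report.yaml"))
  invisible(c(paths, file.path(dir, "report.yaml")))
}

#' Write a sharpness curve and its calibration fit
#'
#' The curve goes to CSV (columns `z_set_um`, `tbg`); the fit parameters
#' (slope, intercept, covariance, flank indices, residual sd) to a YAML
#' sidecar.
#'
#' @param curve A [sharpness_curve()].
#' @param path Output `.csv` path.
#' @param fit Optional [fit_calibration()] result for the sidecar.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path, fit = NULL) {
  utils::write.csv(data.frame(z_set_um = curve$z_set_um, tbg = curve$tbg),
                   path, row.names = FALSE)
  if (!is.null(fit)) {
    yaml::write_yaml(list(
      particle_id = fit$particle_id, slope = fit$slope,
      intercept = fit$intercept,
      inverse_slope_um_per_tbg = fit$inverse_slope_um_per_tbg,
      covariance = as.list(as.data.frame(fit$covariance)),
      residual_sd = fit$residual_sd, r_squared = fit$r_squared,
      flank_range = fit$flank_range, flank_length_um = fit$flank_length_um,
      z_reference_um = fit$z_reference_um, tbg_reference = fit$tbg_reference),
      paste0(tools::file_path_sans_ext(path), ".yaml"))
  }
  invisible(path)
}

#' Write an equilibrium profile as CSV
#'
#' @param profile An `equilibrium_profile` from
#'   [transport_elevation_profile()].
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile)[, c("t_ms", "x_um", "z_eq_um",
                                              "bracketed")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' Reads a nested configuration (paths, optics, preprocessing, tracking,
#' calibration, physical model blocks, seed) and instantiates the
#' corresponding model objects where present. Unknown keys are kept as-is.
#'
#' @param path YAML file path.
#' @return A named list with any of `optics` ([optics_model()]), `pipeline`
#'   ([pipeline_config()]), `pattern` ([stripe_pattern()]), `pulses`
#'   ([pulse_sequence()]), `particle` ([particle_model()]), `interactions`
#'   ([interaction_params()]) plus the raw remainder.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(block, ctor) {
    if (is.null(raw[[block]])) return(NULL)
    do.call(ctor, raw[[block]])
  }
  out <- raw
  out$optics <- build("optics", optics_model)
  out$pipeline <- build("pipeline", pipeline_config)
  out$pattern <- build("pattern", stripe_pattern)
  out$pulses <- build("pulses", pulse_sequence)
  out$particle <- build("particle", particle_model)
  out$interactions <- build("interactions", interaction_params)
  out
}
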