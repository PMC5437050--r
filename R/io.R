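#' Write a confocal image as float TIFF plus sidecar metadata
#'
#' Stores the intensity grid as a single-page 32-bit float TIFF (values
#' rescaled to [0, 1]; the affine scale is recorded in the sidecar so reading
#' restores intensity units) and the acquisition metadata (pixel size, laser
#' power, offset, noise SD) as a YAML sidecar next to it.
#'
#' @param image a [confocal_image()].
#' @param path TIFF output path; the sidecar is written to
#'   \code{paste0(path, ".yml")}.
#' @return invisibly, the sidecar path.
#' @export
write_confocal_tiff <- function(image, path) {
  stopifnot(inherits(image, "confocal_image"))
  lo <- min(image$data)
  hi <- max(image$data)
  rng <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((image$data - lo) / rng, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  meta <- list(pixel_size_um = image$pixel_size,
               laser_power_percent = image$laser_power,
               offset = image$offset, noise_sd = image$noise_sd,
               intensity_min = lo, intensity_range = rng)
  sidecar <- paste0(path, ".yml")
  yaml::write_yaml(meta, sidecar)
  invisible(sidecar)
}

#' Read a confocal image written by [write_confocal_tiff()]
#'
#' @param path TIFF path (sidecar expected at \code{paste0(path, ".yml")}).
#' @return a [confocal_image()].
#' @export
read_confocal_tiff <- function(path) {
  sidecar <- paste0(path, ".yml")
  if (!file.exists(sidecar)) stop("sidecar metadata not found: ", sidecar)
  meta <- yaml::read_yaml(sidecar)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m <- m * meta$intensity_range + meta$intensity_min
  confocal_image(m, pixel_size = meta$pixel_size_um,
                 laser_power = meta$laser_power_percent,
                 offset = meta$offset, noise_sd = meta$noise_sd)
}

#' Read a RoI table
#'
#' CSV with columns x0, y0, width, height in pixels (0-based, half-open, as
#' documented in the file header comment if present).
#'
#' @param path CSV path.
#' @return data.frame of RoIs.
#' @export
read_roi_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("x0", "y0", "width", "height") %in% names(df)))
  df
}

#' Write a per-RoI SpIDA fit table
#'
#' @param fits list of [spida()] fits.
#' @param path output CSV path.
#' @param roi_ids optional identifiers (default sequence).
#' @return invisibly, the written data.frame.
#' @export
write_fit_table <- function(fits, path, roi_ids = seq_along(fits)) {
  df <- data.frame(
    roi_id = roi_ids,
    qb = vapply(fits, function(f) f$qb, numeric(1L)),
    density = vapply(fits, function(f) f$density, numeric(1L)),
    chi2 = vapply(fits, function(f) ifelse(is.null(f$chi2), NA_real_, f$chi2), numeric(1L)),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1L)),
    degenerate = vapply(fits, function(f) isTRUE(f$degenerate), logical(1L)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a FRAP trace as CSV (time_s, Fs, Fb, Fc columns)
#' @param trace a \code{"frap_trace"}
#' @param path output CSV path
#' @return invisibly, the data.frame written
#' @export
write_frap_csv <- function(trace, path) {
  df <- data.frame(time_s = trace$times, Fs = trace$Fs, Fb = trace$Fb,
                   Fc = trace$Fc,
                   prebleach = seq_along(trace$times) <= trace$n_prebleach)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a FRAP trace CSV written by [write_frap_csv()]
#' @param path CSV path
#' @return a \code{"frap_trace"}
#' @export
read_frap_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "Fs", "Fb", "Fc", "prebleach") %in% names(df)))
  structure(list(times = df$time_s, Fs = df$Fs, Fb = df$Fb, Fc = df$Fc,
                 n_prebleach = sum(df$prebleach)),
            class = "frap_trace")
}
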