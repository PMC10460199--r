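#' Construct a phase-contrast velocity series
#'
#' Bundles one cardiac cycle of through-plane velocity maps with the matching
#' lumen masks and acquisition metadata. Velocities are signed (cm/s) and keep
#' the acquisition sign; `forward_sign` declares which sign is forward flow
#' for this region of interest (ascending and descending aorta have opposite
#' through-plane signs in a single acquisition plane).
#'
#' Pixel coordinates used throughout the package are 0-based, `x` along
#' columns and `y` along rows, with pixel centers at integer coordinates.
#' Frame indices are 1-based, following R convention.
#'
#' @param velocity numeric array `[rows, cols, frames]`, signed through-plane
#'   velocity in cm/s.
#' @param mask logical array of the same dimensions; `TRUE` marks lumen
#'   pixels. Every frame must contain at least one lumen pixel.
#' @param trigger_times_ms numeric vector, one trigger time per frame, in ms
#'   from the R-wave; strictly increasing and all `< rr_interval_ms`.
#' @param rr_interval_ms length of the cardiac cycle in ms.
#' @param pixel_spacing_mm length-2 numeric, mm per pixel as `(row, col)`;
#'   anisotropic spacing is allowed and areas always use their product.
#' @param roi_label `"ascending"` or `"descending"`.
#' @param forward_sign `+1` or `-1`; defaults to `+1` for the ascending and
#'   `-1` for the descending aorta.
#'
#' @return An object of class `velocity_series`.
#' @export
velocity_series <- function(velocity, mask, trigger_times_ms, rr_interval_ms,
                            pixel_spacing_mm, roi_label = "ascending",
                            forward_sign = NULL) {
  roi_label <- match.arg(roi_label, c("ascending", "descending"))
  forward_sign <- forward_sign %||% if (roi_label == "ascending") 1 else -1
  x <- structure(
    list(
      velocity = velocity,
      mask = mask,
      trigger_times_ms = as.numeric(trigger_times_ms),
      rr_interval_ms = as.numeric(rr_interval_ms),
      pixel_spacing_mm = as.numeric(pixel_spacing_mm),
      roi_label = roi_label,
      forward_sign = as.numeric(forward_sign)
    ),
    class = "velocity_series"
  )
  validate_velocity_series(x)
}

#' Validate a velocity series
#'
#' Checks every container invariant: matching velocity/mask geometry, at
#' least 8 frames, finite velocities, non-empty mask frames, strictly
#' increasing trigger times below the RR interval, and positive spacing.
#' Violations raise classed conditions (`aortaflow_error_shape`,
#' `aortaflow_error_value`, `aortaflow_error_timing`).
#'
#' @param x a `velocity_series`.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_velocity_series <- function(x) {
  dv <- dim(x$velocity)
  dm <- dim(x$mask)
  if (length(dv) != 3L) {
    abort("`velocity` must be a 3-D array [rows, cols, frames].",
          class = "aortaflow_error_shape")
  }
  if (!identical(dv, dm)) {
    abort(sprintf("velocity dims [%s] do not match mask dims [%s].",
                  paste(dv, collapse = "x"), paste(dm, collapse = "x")),
          class = "aortaflow_error_shape")
  }
  n <- dv[3L]
  if (n < 8L) {
    abort(sprintf("a velocity series needs >= 8 frames, got %d.", n),
          class = "aortaflow_error_shape")
  }
  if (length(x$trigger_times_ms) != n) {
    abort(sprintf("%d trigger times for %d frames.",
                  length(x$trigger_times_ms), n),
          class = "aortaflow_error_shape")
  }
  if (!all(is.finite(x$velocity))) {
    abort("non-finite velocity values.", class = "aortaflow_error_value")
  }
  if (!is.logical(x$mask)) {
    abort("`mask` must be logical.", class = "aortaflow_error_value")
  }
  npix <- apply(x$mask, 3L, sum)
  if (any(npix < 1L)) {
    abort(sprintf("mask frame %d has no lumen pixels.", which(npix < 1L)[1L]),
          class = "aortaflow_error_value")
  }
  tt <- x$trigger_times_ms
  if (any(diff(tt) <= 0)) {
    abort("trigger times must be strictly increasing.",
          class = "aortaflow_error_timing")
  }
  if (!is.finite(x$rr_interval_ms) || x$rr_interval_ms <= 0 ||
      any(tt < 0) || any(tt >= x$rr_interval_ms)) {
    abort("trigger times must lie in [0, rr_interval_ms).",
          class = "aortaflow_error_timing")
  }
  if (length(x$pixel_spacing_mm) != 2L || any(x$pixel_spacing_mm <= 0)) {
    abort("`pixel_spacing_mm` must be two positive values (row, col).",
          class = "aortaflow_error_value")
  }
  if (!x$forward_sign %in% c(-1, 1)) {
    abort("`forward_sign` must be +1 or -1.", class = "aortaflow_error_value")
  }
  invisible(x)
}

#' @export
print.velocity_series <- function(x, ...) {
  d <- dim(x$velocity)
  cat(sprintf(
    "<velocity_series> %s aorta, %d frames of %dx%d px (%.3g x %.3g mm), RR %.0f ms, forward sign %+d\n",
    x$roi_label, d[3], d[1], d[2], x$pixel_spacing_mm[1],
    x$pixel_spacing_mm[2], x$rr_interval_ms, x$forward_sign))
  invisible(x)
}

#' Number of frames in a velocity series
#' @param series a `velocity_series`.
#' @return integer frame count.
#' @export
n_frames <- function(series) dim(series$velocity)[3L]

#' Frame times in seconds
#' @param series a `velocity_series`.
#' @return numeric vector of trigger times converted to seconds.
#' @export
frame_times_s <- function(series) series$trigger_times_ms / 1000
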