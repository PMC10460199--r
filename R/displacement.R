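# Pixel coordinates are 0-based: x along columns, y along rows, centers at
# integer coordinates. Physical offsets use pixel_spacing_mm = (row, col).

mask_coords <- function(mask_frame) {
  idx <- which(mask_frame, arr.ind = TRUE)
  cbind(x = idx[, 2L] - 1, y = idx[, 1L] - 1)
}

#' Geometric center of a lumen mask frame
#'
#' Unweighted centroid of the mask pixels, in 0-based pixel coordinates
#' `(x, y)`.
#'
#' @param mask_frame logical matrix with at least one `TRUE` pixel.
#' @return named numeric vector `c(x, y)`.
#' @export
vessel_center <- function(mask_frame) {
  if (!any(mask_frame)) {
    abort("mask frame has no lumen pixels.", class = "aortaflow_error_value")
  }
  colMeans(mask_coords(mask_frame))
}

#' Center of velocity of the forward flow
#'
#' Forward-velocity-weighted centroid over the lumen:
#' `sum(v_i * p_i) / sum(v_i)` over pixels with `forward_sign * velocity > 0`.
#' Returns `NULL` when the frame has no forward pixels (the frame is then
#' treated as gated downstream).
#'
#' @param vel_frame numeric velocity matrix, cm/s, acquisition sign.
#' @param mask_frame logical lumen mask of the same shape.
#' @param forward_sign +1 or -1.
#' @return named numeric vector `c(x, y)` in 0-based pixel coordinates, or
#'   `NULL` when no pixel carries forward flow.
#' @export
center_of_velocity <- function(vel_frame, mask_frame, forward_sign = 1) {
  v <- forward_sign * vel_frame
  fwd <- mask_frame & v > 0
  if (!any(fwd)) return(NULL)
  w <- v[fwd]
  xy <- mask_coords(fwd)
  c(x = sum(w * xy[, "x"]) / sum(w), y = sum(w * xy[, "y"]) / sum(w))
}

# Rotational-angle convention: 0 deg at image "up" (-y, anterior on a
# standard axial display), increasing clockwise, range (-180, 180].
offset_angle_deg <- function(dx_mm, dy_mm) {
  wrap_angle(atan2(dx_mm, -dy_mm) * 180 / pi)
}

#' Map an angle (or angle difference) to (-180, 180]
#' @param a angle in degrees.
#' @return wrapped angle in degrees.
#' @export
wrap_angle <- function(a) {
  r <- (a + 180) %% 360 - 180
  r[r == -180] <- 180
  r
}

# Unit offset direction (x, y in pixel axes) for an angle in the package
# convention; used by the simulator so imposed and measured angles share one
# definition of zero.
angle_to_unit_xy <- function(angle_deg) {
  th <- angle_deg * pi / 180
  c(x = sin(th), y = -cos(th))
}

#' Flow displacement of a single frame
#'
#' Distance between the lumen geometric center and the forward-flow center of
#' velocity, in physical mm, normalized to the vessel size of the same frame:
#' by default the equivalent lumen diameter `D_eq = 2 sqrt(area / pi)`
#' (`normalization = "radius"` uses the equivalent radius instead). Also
#' returns the angular position of the jet around the lumen center.
#'
#' @param vel_frame,mask_frame one frame of velocity (cm/s) and mask.
#' @param pixel_spacing_mm mm per pixel, `(row, col)`.
#' @param forward_sign +1 or -1.
#' @param normalization `"diameter"` (default) or `"radius"`.
#' @return named numeric vector `c(fd_pct, ra_deg)`; both `NA` when the frame
#'   has no forward pixels.
#' @export
flow_displacement_frame <- function(vel_frame, mask_frame, pixel_spacing_mm,
                                    forward_sign = 1,
                                    normalization = c("diameter", "radius")) {
  normalization <- match.arg(normalization)
  cov <- center_of_velocity(vel_frame, mask_frame, forward_sign)
  if (is.null(cov)) return(c(fd_pct = NA_real_, ra_deg = NA_real_))
  ctr <- vessel_center(mask_frame)
  dx_mm <- (cov["x"] - ctr["x"]) * pixel_spacing_mm[2L]
  dy_mm <- (cov["y"] - ctr["y"]) * pixel_spacing_mm[1L]
  area_mm2 <- sum(mask_frame) * prod(pixel_spacing_mm)
  r_eq_mm <- sqrt(area_mm2 / pi)
  denom <- if (normalization == "diameter") 2 * r_eq_mm else r_eq_mm
  c(fd_pct = unname(100 * sqrt(dx_mm^2 + dy_mm^2) / denom),
    ra_deg = unname(offset_angle_deg(dx_mm, dy_mm)))
}

#' Flow displacement series
#'
#' Per-frame flow displacement and jet rotational angle for a whole velocity
#' series. Frames with no forward pixels get `NA` displacement and are marked
#' gated. The laminar-flow gate itself (RA = 0 when FD is at or below the
#' threshold) is applied by [apply_ra_gate()].
#'
#' @param series a [velocity_series()].
#' @inheritParams flow_displacement_frame
#' @return tibble of class `fd_series` with columns `frame`, `time_s`,
#'   `fd_pct`, `ra_deg`, `gated`.
#' @export
flow_displacement <- function(series,
                              normalization = c("diameter", "radius")) {
  normalization <- match.arg(normalization)
  validate_velocity_series(series)
  n <- n_frames(series)
  vals <- vapply(seq_len(n), function(k) {
    flow_displacement_frame(series$velocity[, , k], series$mask[, , k],
                            series$pixel_spacing_mm, series$forward_sign,
                            normalization)
  }, numeric(2))
  out <- tibble(
    frame = seq_len(n),
    time_s = frame_times_s(series),
    fd_pct = vals["fd_pct", ],
    ra_deg = vals["ra_deg", ],
    gated = is.na(vals["fd_pct", ])
  )
  class(out) <- c("fd_series", class(out))
  out
}

#' Apply the laminar-flow gate to a flow-displacement series
#'
#' Frames whose displacement is at or below the gate (default 12% — aortic
#' flow is mainly laminar in early systole, where the jet centroid is
#' unreliable) are marked gated: their rotational angle is set to `NA` for
#' analysis (plots draw them at 0) and they are excluded from the rotational
#' angle-change and rotational-speed computations. Frames with no forward
#' flow stay gated.
#'
#' @param fd an `fd_series` from [flow_displacement()].
#' @param gate_pct gate threshold, percent of the equivalent diameter
#'   (default 12).
#' @return the `fd_series` with `gated` and `ra_deg` updated.
#' @export
apply_ra_gate <- function(fd, gate_pct = 12) {
  gated <- is.na(fd$fd_pct) | fd$fd_pct <= gate_pct
  fd$gated <- gated
  fd$ra_deg[gated] <- NA_real_
  fd
}

#' Flow-displacement summary averages
#'
#' Arithmetic means of the per-frame displacement over systole, late systole
#' and diastole, plus the displacement at the peak-systolic frame. Frames
#' with undefined displacement (no forward flow) are excluded from the means.
#'
#' @param fd an `fd_series`.
#' @param landmarks landmarks from [phase_landmarks()] on the matching flow
#'   curve.
#' @return one-row tibble: `fds_avg_pct`, `fdls_avg_pct`, `fdd_avg_pct`,
#'   `fdps_pct`.
#' @export
fd_summaries <- function(fd, landmarks) {
  win_mean <- function(idx) {
    if (length(idx) == 0L) {
      abort("empty landmark window.", class = "aortaflow_error_value")
    }
    mean(fd$fd_pct[idx], na.rm = TRUE)
  }
  tibble(
    fds_avg_pct = win_mean(landmarks$systole),
    fdls_avg_pct = win_mean(landmarks$late_systole),
    fdd_avg_pct = if (length(landmarks$diastole)) win_mean(landmarks$diastole)
                  else NA_real_,
    fdps_pct = fd$fd_pct[landmarks$peak_systole_idx]
  )
}

#' Rotational angle change from post-peak stabilization to end systole
#'
#' The stabilization frame is the first ungated frame after peak systole
#' where the absolute frame-to-frame angle change stays below
#' `stab_deg_per_frame` for `stab_consecutive` consecutive ungated steps.
#' The result is the minimal-wrap difference `RA(end systole) - RA(stab)`.
#' Returns `NA` with a warning when no stabilization frame exists or either
#' endpoint is gated.
#'
#' @param fd a gated `fd_series` (see [apply_ra_gate()]).
#' @param landmarks landmarks from [phase_landmarks()].
#' @param stab_deg_per_frame stabilization threshold, degrees per frame
#'   (default 10).
#' @param stab_consecutive number of consecutive small steps required
#'   (default 2).
#' @return angle change in degrees, range (-180, 180].
#' @export
delta_ra <- function(fd, landmarks, stab_deg_per_frame = 10,
                     stab_consecutive = 2) {
  peak <- landmarks$peak_systole_idx
  end <- landmarks$end_systole_idx
  if (is.na(fd$ra_deg[end])) {
    warn("end-systolic frame is gated; delta RA is undefined.")
    return(NA_real_)
  }
  idx <- seq(peak, end)
  idx <- idx[!is.na(fd$ra_deg[idx])]
  if (length(idx) < stab_consecutive + 1L) {
    warn("too few ungated late-systolic frames; delta RA is undefined.")
    return(NA_real_)
  }
  steps <- abs(wrap_angle(diff(fd$ra_deg[idx])))
  stab <- NA_integer_
  for (j in seq_len(length(steps) - stab_consecutive + 1L)) {
    if (all(steps[j:(j + stab_consecutive - 1L)] < stab_deg_per_frame)) {
      stab <- idx[j + 1L]  # first frame after peak where the angle has settled
      break
    }
  }
  if (is.na(stab)) {
    warn("no stabilization frame after peak systole; delta RA is undefined.")
    return(NA_real_)
  }
  wrap_angle(fd$ra_deg[end] - fd$ra_deg[stab])
}

#' Rotational speed of the displaced jet
#'
#' Between consecutive ungated frames, the rotational speed is the wrapped
#' angle change divided by `360 * frame_dt` (revolutions per second). Gated
#' frames are excluded, not zero-filled. `rsls_avg_rev_s` averages the speeds
#' whose frame pairs lie inside late systole (peak to end systole); it is
#' `NA` when no eligible pair exists.
#'
#' @param fd a gated `fd_series`.
#' @param landmarks landmarks from [phase_landmarks()].
#' @param frame_dt_s uniform frame duration, s.
#' @return list of class `rotation_summary`: `rs` (tibble `frame_from`,
#'   `frame_to`, `rs_rev_s`), `rsls_avg_rev_s`.
#' @export
rotational_speed <- function(fd, landmarks, frame_dt_s) {
  if (frame_dt_s <= 0) {
    abort("frame_dt_s must be > 0.", class = "aortaflow_error_value")
  }
  ok <- which(!is.na(fd$ra_deg))
  pairs <- ok[c(diff(ok) == 1L, FALSE)]
  rs <- tibble(
    frame_from = pairs,
    frame_to = pairs + 1L,
    rs_rev_s = wrap_angle(fd$ra_deg[pairs + 1L] - fd$ra_deg[pairs]) /
      (360 * frame_dt_s)
  )
  ls <- landmarks$late_systole
  in_ls <- rs$frame_from %in% ls & rs$frame_to %in% ls
  rsls <- if (any(in_ls)) mean(rs$rs_rev_s[in_ls]) else NA_real_
  if (is.na(rsls)) warn("no ungated late-systolic frame pairs; RSls_avg is undefined.")
  structure(list(rs = rs, rsls_avg_rev_s = rsls), class = "rotation_summary")
}

#' @export
print.rotation_summary <- function(x, ...) {
  cat(sprintf("<rotation_summary> %d ungated pairs, RSls_avg = %s rev/s\n",
              nrow(x$rs),
              ifelse(is.na(x$rsls_avg_rev_s), "NA",
                     sprintf("%.3f", x$rsls_avg_rev_s))))
  invisible(x)
}
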