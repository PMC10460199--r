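#' Lumen cross-section area per frame
#'
#' Area of each mask frame as true-pixel count times the pixel area
#' (row spacing x column spacing), reported in cm^2.
#'
#' @param series a [velocity_series()] (its mask and spacing are used).
#' @return tibble with columns `frame`, `time_s`, `area_cm2`.
#' @export
area_series <- function(series) {
  validate_velocity_series(series)
  a_pix_cm2 <- prod(series$pixel_spacing_mm) / 100  # mm^2 -> cm^2
  tibble(
    frame = seq_len(n_frames(series)),
    time_s = frame_times_s(series),
    area_cm2 = apply(series$mask, 3L, sum) * a_pix_cm2
  )
}

#' Relative area change (RAC)
#'
#' `(max area - min area) / min area x 100`, the lumen distensibility
#' surrogate used for the ascending aorta.
#'
#' @param areas the tibble from [area_series()], or any data frame with an
#'   `area_cm2` column.
#' @return RAC in percent.
#' @export
relative_area_change <- function(areas) {
  a <- areas$area_cm2
  if (length(a) < 1L || any(!is.finite(a)) || any(a <= 0)) {
    abort("areas must be positive and finite.", class = "aortaflow_error_value")
  }
  100 * (max(a) - min(a)) / min(a)
}

#' Flow curve with pixelwise forward/retrograde decomposition
#'
#' For each frame, pixels inside the lumen are split by the sign of
#' `forward_sign * velocity`: the forward rate integrates the forward-signed
#' pixels, the retrograde rate the opposite-signed ones, so
#' `net = forward - retro` holds exactly. Rates are mL/s
#' (cm/s x pixel area in cm^2).
#'
#' @param series a [velocity_series()].
#' @return tibble of class `flow_curve` with columns `frame`, `time_s`,
#'   `net_ml_s`, `forward_ml_s`, `retro_ml_s` and attributes
#'   `rr_interval_ms`, `roi_label`.
#' @export
flow_curve <- function(series) {
  validate_velocity_series(series)
  a_pix_cm2 <- prod(series$pixel_spacing_mm) / 100
  s <- series$forward_sign
  n <- n_frames(series)
  fwd <- numeric(n)
  ret <- numeric(n)
  for (k in seq_len(n)) {
    v <- s * series$velocity[, , k][series$mask[, , k]]
    fwd[k] <- sum(pmax(v, 0)) * a_pix_cm2
    ret[k] <- sum(pmax(-v, 0)) * a_pix_cm2
  }
  out <- tibble(
    frame = seq_len(n),
    time_s = frame_times_s(series),
    net_ml_s = fwd - ret,
    forward_ml_s = fwd,
    retro_ml_s = ret
  )
  attr(out, "rr_interval_ms") <- series$rr_interval_ms
  attr(out, "roi_label") <- series$roi_label
  class(out) <- c("flow_curve", class(out))
  out
}

#' Build a flow curve from raw rate samples
#'
#' Convenience constructor for curves that do not come from a velocity
#' series (e.g. simulated or externally computed rates).
#'
#' @param time_s frame times, s.
#' @param forward_ml_s,retro_ml_s non-negative rates, mL/s; `retro_ml_s`
#'   defaults to zero.
#' @param rr_interval_ms cycle length, ms; defaults to the time span implied
#'   by uniform frame spacing.
#' @return a `flow_curve` tibble.
#' @export
as_flow_curve <- function(time_s, forward_ml_s, retro_ml_s = 0,
                          rr_interval_ms = NULL) {
  n <- length(time_s)
  retro_ml_s <- rep_len(retro_ml_s, n)
  if (any(forward_ml_s < 0) || any(retro_ml_s < 0)) {
    abort("forward and retro rates must be >= 0.",
          class = "aortaflow_error_value")
  }
  rr_interval_ms <- rr_interval_ms %||% (1000 * n * mean(diff(time_s)))
  out <- tibble(
    frame = seq_len(n),
    time_s = as.numeric(time_s),
    net_ml_s = forward_ml_s - retro_ml_s,
    forward_ml_s = as.numeric(forward_ml_s),
    retro_ml_s = as.numeric(retro_ml_s)
  )
  attr(out, "rr_interval_ms") <- rr_interval_ms
  class(out) <- c("flow_curve", class(out))
  out
}

#' Detect cardiac-phase landmarks on a flow curve
#'
#' Peak systole is the frame of maximum net flow rate. End systole is the
#' first linearly interpolated downward zero crossing of the net rate after
#' the peak (where the descending systolic limb meets the x-axis);
#' `end_systole_idx` is the last frame at or before that crossing. Systole
#' runs from frame 1 (acquisition is R-wave-triggered) to `end_systole_idx`,
#' late systole from the peak to end systole, diastole covers the remaining
#' frames.
#'
#' @param curve a `flow_curve`.
#' @param mode `"strict"` errors when the net rate never crosses zero after
#'   the peak; `"lenient"` falls back to the frame of minimum net rate after
#'   the peak as end systole, with a warning.
#' @return list of class `phase_landmarks` with `peak_systole_idx`,
#'   `end_systole_idx`, `end_systole_time_s`, and the index windows
#'   `systole`, `late_systole`, `diastole`.
#' @export
phase_landmarks <- function(curve, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  y <- curve$net_ml_s
  t <- curve$time_s
  n <- length(y)
  if (max(y) <= 0) {
    abort("flow curve has no positive maximum.",
          class = "aortaflow_error_value")
  }
  peak <- which.max(y)
  cross <- NA_integer_
  for (i in seq(peak, n - 1L)) {
    if (y[i] > 0 && y[i + 1L] <= 0) {
      cross <- i
      break
    }
  }
  if (is.na(cross)) {
    if (mode == "strict") {
      abort("net flow never crosses zero after the peak; no end systole.",
            class = "aortaflow_error_landmark")
    }
    warn("no zero crossing after peak; using post-peak minimum as end systole.")
    end_idx <- peak - 1L + which.min(y[peak:n])
    t_es <- t[end_idx]
  } else if (y[cross + 1L] == 0) {
    end_idx <- cross + 1L
    t_es <- t[cross + 1L]
  } else {
    # linear interpolation of the downward crossing
    t_es <- t[cross] + (t[cross + 1L] - t[cross]) * y[cross] /
      (y[cross] - y[cross + 1L])
    end_idx <- cross
  }
  structure(
    list(
      peak_systole_idx = peak,
      end_systole_idx = end_idx,
      end_systole_time_s = t_es,
      systole = seq_len(end_idx),
      late_systole = seq(peak, end_idx),
      diastole = if (end_idx < n) seq(end_idx + 1L, n) else integer(0)
    ),
    class = "phase_landmarks"
  )
}

#' @export
print.phase_landmarks <- function(x, ...) {
  cat(sprintf(
    "<phase_landmarks> peak systole frame %d, end systole frame %d (t = %.4f s)\n",
    x$peak_systole_idx, x$end_systole_idx, x$end_systole_time_s))
  invisible(x)
}

curve_frame_dt_s <- function(curve, rr_interval_ms = NULL) {
  rr <- rr_interval_ms %||% attr(curve, "rr_interval_ms")
  if (is.null(rr)) {
    abort("rr_interval_ms is needed and not attached to the curve.",
          class = "aortaflow_error_metadata")
  }
  rr / 1000 / nrow(curve)
}

integrate_rate <- function(rate, dt_s, idx = seq_along(rate),
                           rule = c("rectangle", "trapezoid")) {
  rule <- match.arg(rule)
  x <- rate[idx]
  if (rule == "rectangle") sum(x) * dt_s
  else sum((x[-1] + x[-length(x)]) / 2) * dt_s
}

#' Whole-cycle forward and backward flow volumes
#'
#' Integrates the forward and retrograde rates over the full cardiac cycle
#' with the rectangle rule (sample times uniform frame duration,
#' `rr / n_frames`, the frame-based phase-contrast convention; a trapezoid
#' rule is available via `rule`). Volumes are indexed to body surface area
#' when `bsa` is given.
#'
#' @param curve a `flow_curve`.
#' @param bsa body surface area, m^2 (`NA` to skip indexing).
#' @param rr_interval_ms cycle length, ms; taken from the curve attribute by
#'   default.
#' @param rule integration rule, `"rectangle"` (default) or `"trapezoid"`.
#' @return one-row tibble: `ff_ml`, `bf_ml`, `ffi_ml_m2`, `bfi_ml_m2`.
#' @export
cycle_volumes <- function(curve, bsa = NA_real_, rr_interval_ms = NULL,
                          rule = c("rectangle", "trapezoid")) {
  rule <- match.arg(rule)
  if (!is.na(bsa) && bsa <= 0) {
    abort("bsa must be > 0.", class = "aortaflow_error_value")
  }
  dt <- curve_frame_dt_s(curve, rr_interval_ms)
  ff <- integrate_rate(curve$forward_ml_s, dt, rule = rule)
  bf <- integrate_rate(curve$retro_ml_s, dt, rule = rule)
  tibble(ff_ml = ff, bf_ml = bf,
         ffi_ml_m2 = ff / bsa, bfi_ml_m2 = bf / bsa)
}

#' Systolic forward flow, retrograde flow, and flow-reversal ratio
#'
#' Integrates the forward and retrograde rates over the systolic window and
#' reports `sfrr_pct = 100 * srf / sff`. When the systolic forward volume is
#' zero the ratio is undefined and reported as `NA` with a warning.
#'
#' @param curve a `flow_curve`.
#' @param landmarks landmarks from [phase_landmarks()] computed on the same
#'   curve.
#' @param rr_interval_ms cycle length, ms (defaults to the curve attribute).
#' @param rule integration rule, as in [cycle_volumes()].
#' @return one-row tibble: `sff_ml`, `srf_ml`, `sfrr_pct`.
#' @export
systolic_flow_metrics <- function(curve, landmarks, rr_interval_ms = NULL,
                                  rule = c("rectangle", "trapezoid")) {
  rule <- match.arg(rule)
  dt <- curve_frame_dt_s(curve, rr_interval_ms)
  idx <- landmarks$systole
  sff <- integrate_rate(curve$forward_ml_s, dt, idx, rule)
  srf <- integrate_rate(curve$retro_ml_s, dt, idx, rule)
  if (sff > 0) {
    sfrr <- 100 * srf / sff
  } else {
    warn("systolic forward flow is zero; sFRR is undefined.")
    sfrr <- NA_real_
  }
  tibble(sff_ml = sff, srf_ml = srf, sfrr_pct = sfrr)
}
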