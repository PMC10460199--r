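#' Full single-plane flow quantification
#'
#' Runs the whole 2-D phase-contrast pipeline on one velocity series: flow
#' curve with pixelwise forward/retrograde decomposition, phase landmarks,
#' whole-cycle forward/backward volumes (BSA-indexed when `bsa` is given),
#' systolic forward/retrograde volumes and flow-reversal ratio, lumen areas
#' and relative area change, flow displacement with the laminar gate, its
#' phase averages, the rotational angle change and the late-systolic
#' rotational speed.
#'
#' @param series a [velocity_series()].
#' @param bsa body surface area, m^2 (`NA` skips indexing).
#' @param fd_gate laminar-flow gate for the rotational angle, percent
#'   (default 12).
#' @param landmark_mode `"strict"` or `"lenient"`, see [phase_landmarks()].
#' @param normalization vessel-size normalization for FD, see
#'   [flow_displacement()].
#' @return list of class `flow_metrics`: `metrics` (one-row tibble of all
#'   scalar outputs), `curve` (per-frame flow curve joined with area and FD
#'   columns), `landmarks`. `tidy()` returns the per-frame table, `glance()`
#'   the scalar row.
#' @export
compute_flow_metrics <- function(series, bsa = NA_real_, fd_gate = 12,
                                 landmark_mode = c("strict", "lenient"),
                                 normalization = c("diameter", "radius")) {
  landmark_mode <- match.arg(landmark_mode)
  normalization <- match.arg(normalization)
  curve <- flow_curve(series)
  lm_ <- phase_landmarks(curve, mode = landmark_mode)
  vols <- cycle_volumes(curve, bsa = bsa)
  sys <- systolic_flow_metrics(curve, lm_)
  areas <- area_series(series)
  fd <- apply_ra_gate(flow_displacement(series, normalization), fd_gate)
  fds <- fd_summaries(fd, lm_)
  dt <- curve_frame_dt_s(curve)
  dra <- suppressWarnings(delta_ra(fd, lm_))
  rot <- suppressWarnings(rotational_speed(fd, lm_, dt))

  metrics <- dplyr::bind_cols(
    vols, sys,
    tibble(
      area_max_cm2 = max(areas$area_cm2),
      area_min_cm2 = min(areas$area_cm2),
      rac_pct = relative_area_change(areas)
    ),
    fds,
    tibble(delta_ra_deg = dra, rsls_avg_rev_s = rot$rsls_avg_rev_s)
  )
  per_frame <- dplyr::left_join(
    dplyr::left_join(as_tibble(curve), areas[, c("frame", "area_cm2")],
                     by = "frame"),
    as_tibble(fd)[, c("frame", "fd_pct", "ra_deg", "gated")], by = "frame")
  structure(
    list(metrics = metrics, curve = per_frame, landmarks = lm_,
         fd_gate = fd_gate, bsa = bsa, roi_label = series$roi_label),
    class = "flow_metrics"
  )
}

#' @export
print.flow_metrics <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<flow_metrics> %s aorta\n", x$roi_label))
  cat(sprintf("  FF %.1f mL, BF %.2f mL%s\n", m$ff_ml, m$bf_ml,
              if (!is.na(m$ffi_ml_m2))
                sprintf(" (FFi %.1f, BFi %.2f mL/m^2)", m$ffi_ml_m2,
                        m$bfi_ml_m2) else ""))
  cat(sprintf("  SFF %.1f mL, SRF %.2f mL, sFRR %.2f%%\n",
              m$sff_ml, m$srf_ml, m$sfrr_pct))
  cat(sprintf("  area %.2f-%.2f cm^2, RAC %.1f%%\n",
              m$area_min_cm2, m$area_max_cm2, m$rac_pct))
  cat(sprintf("  FDs %.1f%%, FDls %.1f%%, FDd %.1f%%, FDps %.1f%%\n",
              m$fds_avg_pct, m$fdls_avg_pct, m$fdd_avg_pct, m$fdps_pct))
  cat(sprintf("  deltaRA %s deg, RSls_avg %s rev/s\n",
              ifelse(is.na(m$delta_ra_deg), "NA",
                     sprintf("%.1f", m$delta_ra_deg)),
              ifelse(is.na(m$rsls_avg_rev_s), "NA",
                     sprintf("%.3f", m$rsls_avg_rev_s))))
  invisible(x)
}

#' @rdname compute_flow_metrics
#' @param x a `flow_metrics` object.
#' @param ... unused.
#' @method tidy flow_metrics
#' @export
tidy.flow_metrics <- function(x, ...) x$curve

#' @rdname compute_flow_metrics
#' @method glance flow_metrics
#' @export
glance.flow_metrics <- function(x, ...) x$metrics

#' Write the per-frame curves of a flow-metrics result to CSV
#'
#' Columns `time_s`, `net`, `forward`, `retro` (mL/s), `area_cm2`, `fd_pct`,
#' `ra_deg` (gated frames drawn as 0, flagged by `gated`).
#'
#' @param x a `flow_metrics` object.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_curves_csv <- function(x, path) {
  out <- tibble(
    time_s = x$curve$time_s,
    net = x$curve$net_ml_s,
    forward = x$curve$forward_ml_s,
    retro = x$curve$retro_ml_s,
    area_cm2 = x$curve$area_cm2,
    fd_pct = x$curve$fd_pct,
    ra_deg = ifelse(x$curve$gated, 0, x$curve$ra_deg),
    gated = x$curve$gated
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
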