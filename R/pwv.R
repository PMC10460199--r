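#' Half-maximum arrival time of a flow curve
#'
#' Time at which the systolic upslope first reaches 50% of the curve maximum,
#' linearly interpolated between the bracketing frames. The crossing is
#' searched from the start of the curve forward and the last crossing before
#' the peak is used, which is robust to small noise-induced blips on the
#' baseline. By default the forward rate is used (robust to small retrograde
#' components); `on = "net"` switches to the net rate.
#'
#' The curve maximum is refined by quadratic interpolation through the peak
#' sample and its two neighbours before halving (`refine_peak = FALSE` uses
#' the raw sample maximum): the sampled maximum systematically undershoots
#' the true peak by up to `O((dt/Ts)^2)`, and the undershoot differs between
#' two curves sampled at different phases, which would bias the transit time.
#'
#' @param curve a `flow_curve`.
#' @param on `"forward"` (default) or `"net"`.
#' @param refine_peak refine the maximum by a three-point parabola (default
#'   `TRUE`).
#' @return arrival time in seconds.
#' @export
half_max_time <- function(curve, on = c("forward", "net"),
                          refine_peak = TRUE) {
  on <- match.arg(on)
  y <- if (on == "forward") curve$forward_ml_s else curve$net_ml_s
  t <- curve$time_s
  if (max(y) <= 0) {
    abort("curve has no positive peak.", class = "aortaflow_error_value")
  }
  peak <- which.max(y)
  y_max <- y[peak]
  if (refine_peak && peak > 1L && peak < length(y)) {
    y0 <- y[peak - 1L]; y1 <- y[peak]; y2 <- y[peak + 1L]
    denom <- y0 - 2 * y1 + y2
    if (denom < 0) {  # strictly concave triple: parabola has a maximum
      y_max <- y1 - (y2 - y0)^2 / (8 * denom)
    }
  }
  h <- y_max / 2
  if (y[1L] >= h) {
    abort("curve starts at or above half-maximum; no upslope crossing.",
          class = "aortaflow_error_landmark")
  }
  cross <- NA_integer_
  if (peak > 1L) {
    for (i in seq_len(peak - 1L)) {
      if (y[i] < h && y[i + 1L] >= h) cross <- i  # keep the LAST one
    }
  }
  if (is.na(cross)) {
    abort("no upslope half-maximum crossing before the peak.",
          class = "aortaflow_error_landmark")
  }
  t[cross] + (t[cross + 1L] - t[cross]) * (h - y[cross]) /
    (y[cross + 1L] - y[cross])
}

#' Three-dimensional arch length of a centerline polyline
#'
#' Sum of consecutive Euclidean segment lengths of the aortic-arch centerline
#' between the ascending and descending measurement planes, converted from mm
#' to m.
#'
#' @param centerline tibble/data frame with columns `x_mm`, `y_mm`, `z_mm`.
#' @return path length in meters.
#' @export
arch_length <- function(centerline) {
  validate_centerline(centerline)
  p <- as.matrix(centerline[, c("x_mm", "y_mm", "z_mm")])
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] -
                    p[-nrow(p), , drop = FALSE])^2))) / 1000
}

#' Transit-time pulse wave velocity by the half-maximum method
#'
#' The transit time is the difference between the half-maximum arrival times
#' of the descending and ascending flow curves (each curve measured with its
#' own forward-sign convention, so both are positive-forward); the pulse wave
#' velocity is the arch path length divided by the transit time. A
#' non-positive transit time (non-physiological ordering) raises an error.
#'
#' @param asc,desc `flow_curve`s for the ascending and descending planes.
#' @param path_length_m arch length in meters (see [arch_length()]).
#' @param on rate used for the half-maximum, as in [half_max_time()].
#' @return one-row tibble of class `pwv_result`: `t_half_asc_s`,
#'   `t_half_desc_s`, `transit_time_s`, `path_length_m`, `pwv_m_s`.
#' @export
compute_pwv <- function(asc, desc, path_length_m,
                        on = c("forward", "net")) {
  on <- match.arg(on)
  if (path_length_m <= 0) {
    abort("path_length_m must be > 0.", class = "aortaflow_error_value")
  }
  t_asc <- half_max_time(asc, on)
  t_desc <- half_max_time(desc, on)
  transit <- t_desc - t_asc
  if (transit <= 0) {
    abort(sprintf(
      "transit time %.4f s is not positive (descending wave must arrive later).",
      transit), class = "aortaflow_error_value")
  }
  out <- tibble(
    t_half_asc_s = t_asc,
    t_half_desc_s = t_desc,
    transit_time_s = transit,
    path_length_m = path_length_m,
    pwv_m_s = path_length_m / transit
  )
  class(out) <- c("pwv_result", class(out))
  out
}
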