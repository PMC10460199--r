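# Ground-truth simulators. Every generator is a pure function of its
# parameters and seed: stochastic terms run inside withr::with_seed(), so
# global RNG state is never consumed or disturbed.

#' Parameters for the velocity-cine simulator
#'
#' Describes one synthetic phase-contrast acquisition of an aortic cross
#' section: a systolic-pulse flow waveform carried by an eccentric (optionally
#' rotating) forward jet with a truncated-Gaussian profile, a late-systolic
#' retrograde crescent at the lumen edge opposite the jet, a pulsatile
#' circular lumen, and additive Gaussian velocity noise inside the lumen.
#'
#' Defaults emulate a typical healthy ascending aorta: 30 frames over an RR of
#' 1000 ms on a 96 x 96 grid at 1.25 mm pixels; peak flow 420 mL/s with a 35%
#' systolic fraction (systolic forward volume ~73 mL), a small dicrotic notch
#' and a low diastolic baseline; lumen radius 13 mm in diastole pulsing to
#' 14.5 mm at peak systole; jet offset 17% of the equivalent diameter in
#' systole and 29% in diastole; 4.4 mL of systolic retrograde volume.
#'
#' @param grid_px image size in pixels (square grid).
#' @param pixel_spacing_mm mm per pixel, `(row, col)`.
#' @param n_frames frames per cardiac cycle.
#' @param rr_ms RR interval, ms.
#' @param peak_ml_s peak of the systolic flow pulse, mL/s. The systolic limb
#'   is `peak * sin^2(pi t / Ts)` for `t < Ts`.
#' @param sff_ml optional systolic forward volume target, mL; when given,
#'   `peak_ml_s` is solved so the frame-sampled (rectangle-rule) systolic
#'   forward volume equals it exactly.
#' @param systolic_fraction systolic duration as a fraction of the RR.
#' @param baseline_ml_s diastolic forward baseline, mL/s.
#' @param notch_ml_s depth of the brief retrograde dicrotic notch after end
#'   systole, mL/s (0 disables it; the notch gives the net curve its
#'   end-systolic zero crossing).
#' @param notch_ms notch duration, ms.
#' @param radius_dias_mm,radius_sys_mm lumen radius in diastole and at peak
#'   systole; the radius follows the systolic waveform shape.
#' @param offset_frac jet-center offset as a fraction of the equivalent lumen
#'   diameter: a scalar, a length-2 vector `(systole, diastole)`, or one
#'   value per frame. Must stay below 0.5 so the jet center stays inside the
#'   lumen.
#' @param jet_angle_deg angular position of the jet at (and before) peak
#'   systole, package RA convention.
#' @param rotation_rev_s jet rotation rate from peak systole onward, rev/s.
#' @param jet_sigma_frac Gaussian jet width as a fraction of the lumen
#'   radius.
#' @param retro_target_ml systolic retrograde volume carried by the crescent,
#'   mL (0 disables it).
#' @param retro_band radial band of the crescent, fractions of the lumen
#'   radius.
#' @param retro_half_angle_deg angular half-width of the crescent, placed
#'   opposite the jet.
#' @param noise_sd_cm_s additive Gaussian velocity noise inside the lumen,
#'   cm/s.
#' @param roi_label,forward_sign as in [velocity_series()].
#' @param seed RNG seed; mandatory when `noise_sd_cm_s > 0`.
#' @return a list of class `jet_params`.
#' @export
jet_params <- function(grid_px = 96,
                       pixel_spacing_mm = c(1.25, 1.25),
                       n_frames = 30,
                       rr_ms = 1000,
                       peak_ml_s = 420,
                       sff_ml = NULL,
                       systolic_fraction = 0.35,
                       baseline_ml_s = 3,
                       notch_ml_s = 15,
                       notch_ms = 60,
                       radius_dias_mm = 13,
                       radius_sys_mm = 14.5,
                       offset_frac = c(0.17, 0.29),
                       jet_angle_deg = 0,
                       rotation_rev_s = 0,
                       jet_sigma_frac = 0.18,
                       retro_target_ml = 4.4,
                       retro_band = c(0.75, 0.95),
                       retro_half_angle_deg = 60,
                       noise_sd_cm_s = 0,
                       roi_label = "ascending",
                       forward_sign = NULL,
                       seed = NULL) {
  p <- as.list(environment())
  if (any(p$offset_frac >= 0.5)) {
    abort("offset_frac must stay below 0.5.", class = "aortaflow_error_value")
  }
  max_r <- max(radius_dias_mm, radius_sys_mm)
  if (max_r >= grid_px / 2 * min(pixel_spacing_mm)) {
    abort("lumen radius does not fit the grid.",
          class = "aortaflow_error_value")
  }
  if (noise_sd_cm_s > 0 && is.null(seed)) {
    abort("a seed is mandatory when noise_sd_cm_s > 0.",
          class = "aortaflow_error_value")
  }
  class(p) <- "jet_params"
  p
}

#' Preset simulator configurations
#'
#' `laminar`: centered axisymmetric jet, no retrograde flow, no noise.
#' `eccentric-static`: the [jet_params()] defaults.
#' `eccentric-rotating`: eccentric jet rotating at 0.5 rev/s from peak
#' systole, with noise. `retro-heavy`: doubled retrograde volume.
#'
#' @param name preset name.
#' @param seed RNG seed for the stochastic presets.
#' @param ... overrides passed to [jet_params()].
#' @return a `jet_params` object.
#' @export
jet_preset <- function(name = c("laminar", "eccentric-static",
                                "eccentric-rotating", "retro-heavy"),
                       seed = NULL, ...) {
  name <- match.arg(name)
  args <- switch(name,
    "laminar" = list(offset_frac = 0, retro_target_ml = 0),
    "eccentric-static" = list(),
    "eccentric-rotating" = list(rotation_rev_s = 0.5, noise_sd_cm_s = 2,
                                seed = seed %||% 1L),
    "retro-heavy" = list(retro_target_ml = 8.8)
  )
  do.call(jet_params, utils::modifyList(args, list(seed = seed, ...),
                                        keep.null = TRUE))
}

# Waveform of the net flow rate, mL/s, at time t (s). Systole: sin^2 pulse of
# length Ts; then a sin^2 dicrotic notch of length Tn; then the baseline.
waveform_rate <- function(t, peak, ts, baseline, notch, tn) {
  out <- numeric(length(t))
  sys <- t >= 0 & t < ts
  out[sys] <- peak * sin(pi * t[sys] / ts)^2
  ntc <- t >= ts & t < ts + tn & tn > 0
  out[ntc] <- -notch * sin(pi * (t[ntc] - ts) / tn)^2
  dia <- t >= ts + tn
  out[dia] <- baseline
  out[t < 0] <- 0
  out
}

# Shared rasterizer: one frame of velocity + mask for given jet state.
# Coordinates: pixel centers at 0-based integers; lumen centered on the grid.
rasterize_frame <- function(p, q_ml_s, r_mm, offset_frac, angle_deg,
                            retro_rate_unit) {
  g <- p$grid_px
  sp <- p$pixel_spacing_mm
  cx <- (g - 1) / 2
  cy <- (g - 1) / 2
  xs <- matrix(rep(0:(g - 1), each = g), g, g)   # x = column index
  ys <- matrix(rep(0:(g - 1), times = g), g, g)  # y = row index
  dx_mm <- (xs - cx) * sp[2L]
  dy_mm <- (ys - cy) * sp[1L]
  rad_mm <- sqrt(dx_mm^2 + dy_mm^2)
  mask <- rad_mm <= r_mm
  a_pix_cm2 <- prod(sp) / 100

  area_mm2 <- sum(mask) * prod(sp)
  d_eq_mm <- 2 * sqrt(area_mm2 / pi)

  # crescent opposite the jet
  crescent <- mask & FALSE
  if (retro_rate_unit > 0) {
    pix_ang <- offset_angle_deg(dx_mm, dy_mm)
    crescent <- mask &
      rad_mm >= p$retro_band[1L] * r_mm & rad_mm <= p$retro_band[2L] * r_mm &
      abs(wrap_angle(pix_ang - (angle_deg + 180))) <= p$retro_half_angle_deg
  }

  v <- matrix(0, g, g)
  if (q_ml_s != 0) {
    u <- angle_to_unit_xy(angle_deg)
    jc_x_mm <- offset_frac * d_eq_mm * u[["x"]]
    jc_y_mm <- offset_frac * d_eq_mm * u[["y"]]
    sigma_mm <- p$jet_sigma_frac * r_mm
    prof <- exp(-((dx_mm - jc_x_mm)^2 + (dy_mm - jc_y_mm)^2) /
                  (2 * sigma_mm^2))
    support <- mask & !crescent
    norm <- sum(prof[support]) * a_pix_cm2
    v[support] <- q_ml_s * prof[support] / norm
  }
  if (any(crescent)) v[crescent] <- -retro_rate_unit
  list(velocity = v, mask = mask, crescent_px = sum(crescent),
       d_eq_mm = d_eq_mm)
}

# Core generator shared by the single-series and paired simulators.
# delay_s shifts the waveform and radius trajectory (descending plane);
# amp_scale scales the waveform.
simulate_series_core <- function(p, delay_s = 0, amp_scale = 1) {
  n <- p$n_frames
  rr_s <- p$rr_ms / 1000
  dt <- rr_s / n
  t <- (0:(n - 1)) * dt
  ts <- p$systolic_fraction * rr_s
  tn <- p$notch_ms / 1000
  tl <- t - delay_s

  peak <- p$peak_ml_s
  if (!is.null(p$sff_ml)) {
    s_sys <- sum(sin(pi * tl[tl >= 0 & tl < ts] / ts)^2) * dt
    peak <- p$sff_ml / s_sys
  }
  q <- amp_scale * waveform_rate(tl, peak, ts, p$baseline_ml_s,
                                 p$notch_ml_s, tn)

  # lumen radius follows the systolic waveform shape
  wave01 <- waveform_rate(tl, 1, ts, 0, 0, 0)
  r_mm <- p$radius_dias_mm + (p$radius_sys_mm - p$radius_dias_mm) *
    pmax(wave01, 0)

  # per-frame jet offset (fraction of D_eq) and angle
  off <- p$offset_frac
  if (length(off) == 1L) off <- rep(off, n)
  else if (length(off) == 2L) off <- ifelse(tl >= 0 & tl < ts, off[1L], off[2L])
  else if (length(off) != n) {
    abort("offset_frac must have length 1, 2 or n_frames.",
          class = "aortaflow_error_value")
  }
  # rotation is anchored at the sampled peak frame (the frame the pipeline
  # registers as peak systole), so each post-peak frame pair carries exactly
  # rotation_rev_s * dt of angle change
  k_peak <- which.max(q)
  ang <- p$jet_angle_deg + 360 * p$rotation_rev_s * pmax(0, t - t[k_peak])

  # retrograde temporal shape: sin^2 from peak systole to end systole
  gshape <- numeric(n)
  if (p$retro_target_ml > 0) {
    w <- tl >= ts / 2 & tl < ts
    gshape[w] <- sin(pi * (tl[w] - ts / 2) / (ts / 2))^2
  }

  g <- p$grid_px
  vel <- array(0, c(g, g, n))
  msk <- array(FALSE, c(g, g, n))
  crescent_px <- integer(n)
  d_eq <- numeric(n)
  for (k in seq_len(n)) {
    fr <- rasterize_frame(p, q[k], r_mm[k], off[k], ang[k], gshape[k])
    vel[, , k] <- fr$velocity
    msk[, , k] <- fr$mask
    crescent_px[k] <- fr$crescent_px
    d_eq[k] <- fr$d_eq_mm
  }

  a_pix_cm2 <- prod(p$pixel_spacing_mm) / 100
  retro_rate <- numeric(n)
  if (p$retro_target_ml > 0) {
    denom <- sum(gshape * crescent_px) * a_pix_cm2 * dt
    if (denom <= 0) {
      abort("retrograde target is unreachable: crescent is empty in the window.",
            class = "aortaflow_error_value")
    }
    scale <- p$retro_target_ml / denom
    for (k in which(gshape > 0)) {
      neg <- vel[, , k] < 0 & msk[, , k]
      vk <- vel[, , k]
      vk[neg] <- vk[neg] * scale
      vel[, , k] <- vk
    }
    retro_rate <- scale * gshape * crescent_px * a_pix_cm2
  }

  if (p$noise_sd_cm_s > 0) {
    vel <- withr::with_seed(p$seed, {
      noise <- array(rnorm(length(vel), sd = p$noise_sd_cm_s), dim(vel))
      vel + noise * msk
    })
  }

  fs <- p$forward_sign %||% if (p$roi_label == "ascending") 1 else -1
  series <- velocity_series(
    velocity = fs * vel, mask = msk,
    trigger_times_ms = t * 1000, rr_interval_ms = p$rr_ms,
    pixel_spacing_mm = p$pixel_spacing_mm,
    roi_label = p$roi_label, forward_sign = fs
  )

  sys_frames <- which(tl >= 0 & tl < ts)
  truth <- list(
    per_frame = tibble(
      frame = seq_len(n), time_s = t, q_ml_s = q, radius_mm = r_mm,
      offset_frac = off, jet_angle_deg = wrap_angle(ang),
      retro_rate_ml_s = retro_rate, d_eq_mm = d_eq
    ),
    frame_dt_s = dt,
    peak_ml_s = peak * amp_scale,
    sff_ml = sum(pmax(q[sys_frames], 0)) * dt,
    srf_ml = p$retro_target_ml,
    sfrr_pct = if (p$retro_target_ml > 0) {
      100 * p$retro_target_ml / (sum(pmax(q[sys_frames], 0)) * dt)
    } else 0,
    peak_frame = k_peak,
    t_peak_s = t[k_peak],
    t_end_systole_s = delay_s + ts,
    t_half_s = delay_s + ts / 4,  # sin^2 reaches half-max at Ts/4
    rac_pct = 100 * (p$radius_sys_mm^2 - p$radius_dias_mm^2) /
      p$radius_dias_mm^2,
    rotation_rev_s = p$rotation_rev_s,
    delay_s = delay_s
  )
  list(series = series, truth = truth)
}

#' Simulate a phase-contrast velocity cine with known ground truth
#'
#' Generates one cardiac cycle of through-plane velocity maps and lumen masks
#' from [jet_params()]: per frame, a truncated-Gaussian forward jet whose
#' integrated rate equals the flow waveform exactly, displaced from the lumen
#' center by the requested fraction of the equivalent diameter and rotated
#' along the requested trajectory; a retrograde crescent at the lumen edge
#' opposite the jet, active from peak to end systole and scaled in closed
#' form so the systolic retrograde volume (rectangle rule) equals the target
#' exactly; a circular lumen whose radius follows the systolic waveform; and
#' optional Gaussian noise inside the lumen. The jet and the crescent are
#' spatially disjoint, so the imposed forward and retrograde volumes are both
#' exact before noise.
#'
#' @param p a [jet_params()] object.
#' @return list with `series` (a [velocity_series()]) and `truth` (every
#'   imposed quantity: per-frame waveform, radius, offset, angle, retrograde
#'   rate; scalar SFF/SRF/sFRR, analytic peak/end-systole/half-maximum times,
#'   RAC, rotation rate, frame duration).
#' @export
simulate_velocity_series <- function(p) {
  stopifnot(inherits(p, "jet_params"))
  simulate_series_core(p)
}

#' Simulate an ascending/descending flow-curve pair for PWV testing
#'
#' The descending series carries the ascending waveform delayed by
#' `delay_ms` and scaled by `desc_scale`, rasterized into a smaller lumen
#' with the descending sign convention (`forward_sign = -1`).
#'
#' @param p a [jet_params()] for the ascending plane.
#' @param delay_ms transit delay of the descending wave, ms; must be shorter
#'   than the systolic duration.
#' @param desc_scale amplitude scale of the descending waveform.
#' @param desc_radius_scale lumen radius scale of the descending plane.
#' @return list with `asc`, `desc` (each a `series` + `truth` list) and
#'   `transit_time_s`, the imposed transit time.
#' @export
simulate_flow_pair <- function(p, delay_ms = 20, desc_scale = 0.7,
                               desc_radius_scale = 0.8) {
  stopifnot(inherits(p, "jet_params"))
  ts_ms <- p$systolic_fraction * p$rr_ms
  if (delay_ms < 0 || delay_ms >= ts_ms) {
    abort("delay_ms must be non-negative and shorter than systole.",
          class = "aortaflow_error_value")
  }
  asc <- simulate_series_core(p)
  pd <- p
  pd$roi_label <- "descending"
  pd$forward_sign <- -1
  pd$radius_dias_mm <- p$radius_dias_mm * desc_radius_scale
  pd$radius_sys_mm <- p$radius_sys_mm * desc_radius_scale
  desc <- simulate_series_core(pd, delay_s = delay_ms / 1000,
                               amp_scale = desc_scale)
  list(asc = asc, desc = desc, transit_time_s = delay_ms / 1000)
}

#' Published composite model coefficients for CMR-derived peak oxygen uptake
#'
#' The printed linear combination of the aortic forward flow index (mL/m^2),
#' average systolic flow displacement (%), and LVEF (%):
#' `20.729 + 0.443 * ffi - 0.261 * fds_avg - 0.172 * lvef`.
#'
#' @format named numeric vector with elements `intercept`, `ffi`, `fds_avg`,
#'   `lvef`.
#' @export
pvo2_composite_coefs <- c(intercept = 20.729, ffi = 0.443,
                          fds_avg = -0.261, lvef = -0.172)

#' Simulate a cohort table with the composite-model structure
#'
#' Covariates are drawn independently normal with the requested means and
#' SDs (defaults: the healthy-cohort values — FFi 42.7 +/- 6.5 mL/m^2,
#' FDs_avg 17 +/- 6%, LVEF 63 +/- 7%); peak oxygen uptake is the composite
#' linear combination plus Gaussian noise. Decoy covariates for stepwise
#' testing are included: `age` (correlated with FDs_avg, as jet eccentricity
#' rises with age) and `bsa` (pure noise). METs and the boundary-inclusive
#' high-risk label (PVO2 <= 14 mL/kg/min) are derived columns.
#'
#' @param n subjects (>= 20; default 169).
#' @param seed RNG seed (mandatory).
#' @param means,sds named vectors for `ffi`, `fds_avg`, `lvef`.
#' @param coefs named generating coefficients `intercept`, `ffi`, `fds_avg`,
#'   `lvef`; default the published composite model.
#' @param noise_sd residual SD of PVO2, mL/kg/min (default 6).
#' @param age_fd_cor correlation between the age decoy and FDs_avg.
#' @return tibble with columns `id`, `age`, `sex`, `bsa`, `lvef`, `ffi`,
#'   `fds_avg`, `pvo2`, `mets`, `high_risk`; the generating model is attached
#'   as attribute `generator`.
#' @export
simulate_cohort <- function(n = 169, seed,
                            means = c(ffi = 42.7, fds_avg = 17, lvef = 63),
                            sds = c(ffi = 6.5, fds_avg = 6, lvef = 7),
                            coefs = pvo2_composite_coefs,
                            noise_sd = 6,
                            age_fd_cor = 0.5) {
  if (n < 20) abort("n must be >= 20.", class = "aortaflow_error_value")
  if (any(sds <= 0) || noise_sd < 0) {
    abort("SDs must be positive.", class = "aortaflow_error_value")
  }
  tab <- withr::with_seed(seed, {
    ffi <- rnorm(n, means[["ffi"]], sds[["ffi"]])
    fds <- rnorm(n, means[["fds_avg"]], sds[["fds_avg"]])
    lvef <- rnorm(n, means[["lvef"]], sds[["lvef"]])
    z_fd <- (fds - means[["fds_avg"]]) / sds[["fds_avg"]]
    age <- 44 + 13 * (age_fd_cor * z_fd +
                        sqrt(1 - age_fd_cor^2) * rnorm(n))
    bsa <- rnorm(n, 1.72, 0.19)
    sex <- ifelse(rbinom(n, 1, 0.43) == 1, "F", "M")
    pvo2 <- coefs[["intercept"]] + coefs[["ffi"]] * ffi +
      coefs[["fds_avg"]] * fds + coefs[["lvef"]] * lvef +
      rnorm(n, 0, noise_sd)
    tibble(
      id = sprintf("S%03d", seq_len(n)),
      age = age, sex = sex, bsa = bsa, lvef = lvef,
      ffi = ffi, fds_avg = fds, pvo2 = pmax(pvo2, 0)
    )
  })
  tab$mets <- mets_from_pvo2(tab$pvo2)
  tab$high_risk <- as.integer(risk_class(tab$pvo2) == "high")
  attr(tab, "generator") <- list(coefs = coefs, noise_sd = noise_sd,
                                 means = means, sds = sds, seed = seed)
  tab
}

#' Simulate paired repeated measurements for agreement statistics
#'
#' Subject true values are `N(mu, sigma_between^2)`; each of the two
#' measurements adds independent `N(0, sigma_error^2)` error — the classical
#' two-way model behind the consistency ICC.
#'
#' @param n number of subjects.
#' @param sigma_between between-subject SD.
#' @param sigma_error within-subject measurement SD.
#' @param mu grand mean.
#' @param seed RNG seed (mandatory).
#' @return tibble with columns `subject`, `m1`, `m2`.
#' @export
simulate_repeated_pairs <- function(n, sigma_between, sigma_error, mu = 10,
                                    seed) {
  if (sigma_between < 0 || sigma_error < 0) {
    abort("sigmas must be >= 0.", class = "aortaflow_error_value")
  }
  withr::with_seed(seed, {
    truth <- rnorm(n, mu, sigma_between)
    tibble(
      subject = seq_len(n),
      m1 = truth + rnorm(n, 0, sigma_error),
      m2 = truth + rnorm(n, 0, sigma_error)
    )
  })
}
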