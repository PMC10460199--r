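test_that("lumen area is pixel count times pixel area", {
  g <- 20
  msk <- array(FALSE, c(g, g, 8))
  vel <- array(0, c(g, g, 8))
  msk[1:10, 1:10, ] <- TRUE  # 100 pixels per frame
  s <- make_series(vel, msk, spacing = c(1, 1))
  a <- area_series(s)
  expect_equal(a$area_cm2, rep(1, 8))  # 100 mm^2 = 1.00 cm^2

  # rasterized disc against the brute-force pixel count, anisotropy-safe
  m2 <- array(FALSE, c(64, 64, 8))
  for (k in 1:8) m2[, , k] <- disc_mask(64, 15)
  s2 <- make_series(array(0, c(64, 64, 8)), m2, spacing = c(0.5, 0.5))
  npix <- sum(disc_mask(64, 15))
  expect_equal(area_series(s2)$area_cm2, rep(npix * 0.25 / 100, 8))
})

test_that("relative area change follows (max-min)/min and is 0 for constant areas", {
  expect_equal(relative_area_change(tibble::tibble(area_cm2 = c(6, 7, 8, 6.5))),
               100 * (8 - 6) / 6)
  expect_equal(relative_area_change(tibble::tibble(area_cm2 = rep(5.5, 10))), 0)
  expect_error(relative_area_change(tibble::tibble(area_cm2 = c(1, 0))),
               class = "aortaflow_error_value")
})

test_that("rasterized pulsatile lumen reproduces the closed-form area change", {
  # lattice error in a rasterized disc count is ~0.5% at r ~ 20 px and is
  # amplified ~5x in RAC, so the closed-form comparison uses the finer grid
  p <- jet_params(grid_px = 192, pixel_spacing_mm = c(0.625, 0.625),
                  offset_frac = 0, retro_target_ml = 0)
  sim <- simulate_velocity_series(p)
  rac <- relative_area_change(area_series(sim$series))
  expect_lt(abs(rac - sim$truth$rac_pct), 1)  # within 1 percentage point
})

test_that("flow curve decomposes pixels by through-plane sign", {
  g <- 20
  n <- 8
  msk <- array(FALSE, c(g, g, n))
  msk[1:20, 1:20, ] <- TRUE
  vel <- array(10, c(g, g, n))
  s <- make_series(vel, msk, spacing = c(1, 1))  # 400 px = 4 cm^2
  fc <- flow_curve(s)
  expect_equal(fc$net_ml_s, rep(40, n))
  expect_equal(fc$retro_ml_s, rep(0, n))

  # half positive, half negative, equal areas: net 0, forward = retro
  vel2 <- vel
  vel2[, 1:10, ] <- -10
  fc2 <- flow_curve(make_series(vel2, msk, spacing = c(1, 1)))
  expect_equal(fc2$net_ml_s, rep(0, n))
  expect_equal(fc2$forward_ml_s, fc2$retro_ml_s)

  # descending sign convention flips the roles
  fc3 <- flow_curve(make_series(vel2, msk, spacing = c(1, 1),
                                forward_sign = -1, roi = "descending"))
  expect_equal(fc3$forward_ml_s, fc2$retro_ml_s)
})

test_that("parabolic profile integrates to v_max * A / 2 within 1%", {
  g <- 96
  n <- 8
  r_px <- 40
  m <- disc_mask(g, r_px)
  c0 <- (g - 1) / 2
  xs <- matrix(rep(0:(g - 1), each = g), g, g)
  ys <- matrix(rep(0:(g - 1), times = g), g, g)
  v_max <- 80
  prof <- v_max * matrix(pmax(0, 1 - ((xs - c0)^2 + (ys - c0)^2) / r_px^2),
                         g, g)
  vel <- array(rep(prof * m, n), c(g, g, n))
  msk <- array(rep(m, n), c(g, g, n))
  s <- make_series(vel, msk, spacing = c(0.5, 0.5))
  fc <- flow_curve(s)

  # brute-force pixel sum oracle
  ssum <- 0
  for (i in 1:g) for (j in 1:g) if (m[i, j]) ssum <- ssum + prof[i, j]
  expect_equal(fc$net_ml_s[1], ssum * 0.25 / 100, tolerance = 1e-12)

  a_cm2 <- sum(m) * 0.25 / 100
  expect_lt(abs(fc$net_ml_s[1] - v_max * a_cm2 / 2) / (v_max * a_cm2 / 2),
            0.01)
})

test_that("flow outputs are invariant to a consistent pixel relabeling", {
  sim <- simulate_velocity_series(jet_params(noise_sd_cm_s = 2, seed = 5))
  s <- sim$series
  perm_r <- sample(dim(s$velocity)[1])
  perm_c <- sample(dim(s$velocity)[2])
  s2 <- s
  s2$velocity <- s$velocity[perm_r, perm_c, , drop = FALSE]
  s2$mask <- s$mask[perm_r, perm_c, , drop = FALSE]
  expect_equal(flow_curve(s2)$net_ml_s, flow_curve(s)$net_ml_s)
  expect_equal(area_series(s2)$area_cm2, area_series(s)$area_cm2)
})

test_that("phase landmarks find peak and the interpolated zero crossing", {
  # triangular pulse peaking at frame 9, crossing zero between frames 14/15
  y <- c(seq(0, 80, length.out = 9), seq(80, 0, length.out = 11)[-1])
  y <- y - 14  # shift so the downward limb crosses zero between frames
  y[y < -20] <- -20
  t <- (0:18) / 19
  curve <- as_flow_curve(t, pmax(y, 0), pmax(-y, 0), rr_interval_ms = 1000)
  lm_ <- phase_landmarks(curve)
  expect_equal(lm_$peak_systole_idx, 9)
  expect_true(y[lm_$end_systole_idx] > 0 && y[lm_$end_systole_idx + 1] <= 0)
  expect_gt(lm_$end_systole_time_s, t[lm_$end_systole_idx])
  expect_lt(lm_$end_systole_time_s, t[lm_$end_systole_idx + 1])
  expect_equal(lm_$late_systole,
               seq(lm_$peak_systole_idx, lm_$end_systole_idx))
  expect_equal(union(lm_$systole, lm_$diastole), 1:19)
  expect_length(intersect(lm_$systole, lm_$diastole), 0)

  # all-positive decay: strict errors, lenient falls back with a warning
  y2 <- 100 * exp(-(0:18) / 4) + 5
  c2 <- as_flow_curve(t, y2, 0, rr_interval_ms = 1000)
  expect_error(phase_landmarks(c2, "strict"),
               class = "aortaflow_error_landmark")
  expect_warning(lm2 <- phase_landmarks(c2, "lenient"), "minimum")
  expect_equal(lm2$end_systole_idx, 19)
})

test_that("end-systole time from the simulator is within one frame of truth", {
  sim <- simulate_velocity_series(jet_params())
  curve <- flow_curve(sim$series)
  lm_ <- phase_landmarks(curve)
  dt <- sim$truth$frame_dt_s
  expect_lt(abs(lm_$end_systole_time_s - sim$truth$t_end_systole_s), dt)
  expect_equal(lm_$peak_systole_idx, sim$truth$peak_frame)
})

test_that("landmarks are stable under temporal refinement", {
  p <- jet_params()
  ts <- p$systolic_fraction * p$rr_ms / 1000
  rate <- function(t) {
    ifelse(t < ts, 400 * sin(pi * t / ts)^2,
           ifelse(t < ts + 0.06, -15 * sin(pi * (t - ts) / 0.06)^2, 3))
  }
  t1 <- (0:29) / 30
  t2 <- (0:59) / 60
  c1 <- as_flow_curve(t1, pmax(rate(t1), 0), pmax(-rate(t1), 0), 1000)
  c2 <- as_flow_curve(t2, pmax(rate(t2), 0), pmax(-rate(t2), 0), 1000)
  e1 <- phase_landmarks(c1)$end_systole_time_s
  e2 <- phase_landmarks(c2)$end_systole_time_s
  expect_lt(abs(e1 - e2), 1 / 30)
})

test_that("cycle volumes integrate with the rectangle rule and index to BSA", {
  n <- 10
  t <- (0:(n - 1)) / n
  curve <- as_flow_curve(t, rep(50, n), 0, rr_interval_ms = 1000)
  v <- cycle_volumes(curve, bsa = 2)
  expect_equal(v$ff_ml, 50)
  expect_equal(v$bf_ml, 0)
  expect_equal(v$ffi_ml_m2, 25)
  expect_error(cycle_volumes(curve, bsa = 0), class = "aortaflow_error_value")

  # analytic integral of the simulator waveform (rectangle rule is exact on
  # the frame samples by construction of the ground truth)
  sim <- simulate_velocity_series(jet_params(retro_target_ml = 0))
  fc <- flow_curve(sim$series)
  vv <- cycle_volumes(fc, bsa = 1.72)
  q <- sim$truth$per_frame$q_ml_s
  dt <- sim$truth$frame_dt_s
  expect_equal(vv$ff_ml, sum(pmax(q, 0)) * dt, tolerance = 1e-9)
  # against the analytic integral peak*Ts/2 + baseline terms, within 1%
  p <- jet_params(retro_target_ml = 0)
  ts <- p$systolic_fraction
  analytic_ff <- p$peak_ml_s * ts / 2 +
    p$baseline_ml_s * (1 - ts - p$notch_ms / 1000)
  expect_lt(abs(vv$ff_ml - analytic_ff) / analytic_ff, 0.01)
})

test_that("conservation: ff - bf equals the integral of the net rate", {
  for (seed in 1:5) {
    sim <- simulate_velocity_series(jet_params(noise_sd_cm_s = 3, seed = seed))
    fc <- flow_curve(sim$series)
    v <- cycle_volumes(fc)
    dt <- curve_frame_dt_s <- attr(fc, "rr_interval_ms") / 1000 / nrow(fc)
    expect_equal(v$ff_ml - v$bf_ml, sum(fc$net_ml_s) * dt, tolerance = 1e-9)
  }
})

test_that("systolic metrics follow the printed ratio definition", {
  n <- 10
  t <- (0:(n - 1)) / n
  fwd <- c(rep(200, 5), rep(0, 5))
  ret <- c(rep(10, 5), rep(0, 5))
  curve <- as_flow_curve(t, fwd, ret, rr_interval_ms = 1000)
  lm_ <- make_landmarks(peak = 1, end = 5, n = n)
  m <- systolic_flow_metrics(curve, lm_)
  expect_equal(m$sff_ml, 100)
  expect_equal(m$srf_ml, 5)
  expect_equal(m$sfrr_pct, 5)

  # no retrograde pixels in systole -> srf 0, sfrr 0
  c2 <- as_flow_curve(t, fwd, 0, rr_interval_ms = 1000)
  expect_equal(systolic_flow_metrics(c2, lm_)$sfrr_pct, 0)

  # zero systolic forward flow -> sFRR missing with a warning
  c3 <- as_flow_curve(t, c(rep(0, 5), rep(10, 5)), ret, rr_interval_ms = 1000)
  expect_warning(m3 <- systolic_flow_metrics(c3, lm_), "undefined")
  expect_true(is.na(m3$sfrr_pct))
})

test_that("velocity scaling scales volumes but not sFRR", {
  sim <- simulate_velocity_series(jet_params())
  s <- sim$series
  s2 <- s
  s2$velocity <- 3 * s$velocity
  f1 <- flow_curve(s)
  f2 <- flow_curve(s2)
  lm1 <- phase_landmarks(f1)
  lm2 <- phase_landmarks(f2)
  v1 <- cycle_volumes(f1)
  v2 <- cycle_volumes(f2)
  expect_equal(v2$ff_ml, 3 * v1$ff_ml, tolerance = 1e-9)
  expect_equal(v2$bf_ml, 3 * v1$bf_ml, tolerance = 1e-9)
  m1 <- systolic_flow_metrics(f1, lm1)
  m2 <- systolic_flow_metrics(f2, lm2)
  expect_equal(m2$sff_ml, 3 * m1$sff_ml, tolerance = 1e-9)
  expect_equal(m2$sfrr_pct, m1$sfrr_pct, tolerance = 1e-9)
})
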