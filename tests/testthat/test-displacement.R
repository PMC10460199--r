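test_that("vessel center is the unweighted mask centroid", {
  m <- disc_mask(65, 20)  # odd grid: center exactly at (32, 32)
  expect_equal(vessel_center(m), c(x = 32, y = 32))

  m1 <- matrix(FALSE, 16, 16)
  m1[8, 6] <- TRUE  # 0-based (x = 5, y = 7)
  expect_equal(vessel_center(m1), c(x = 5, y = 7))

  withr::with_seed(42, {
    for (rep in 1:10) {
      m2 <- matrix(stats::runif(400) < 0.3, 20, 20)
      if (!any(m2)) next
      idx <- which(m2, arr.ind = TRUE)
      expect_equal(vessel_center(m2),
                   c(x = mean(idx[, 2] - 1), y = mean(idx[, 1] - 1)))
    }
  })
  expect_error(vessel_center(matrix(FALSE, 4, 4)),
               class = "aortaflow_error_value")
})

test_that("center of velocity weights forward pixels only", {
  m <- disc_mask(33, 10)
  v <- matrix(0, 33, 33)
  v[m] <- 7  # uniform forward
  expect_equal(center_of_velocity(v, m), vessel_center(m))

  v2 <- matrix(0, 33, 33)
  v2[10, 20] <- 5  # all forward flow in one pixel: 0-based (19, 9)
  expect_equal(center_of_velocity(v2, m | TRUE), c(x = 19, y = 9))

  # retrograde pixels are ignored
  v3 <- v
  v3[1:16, ] <- -3
  v3[17:33, ][m[17:33, ]] <- 7
  expect_equal(center_of_velocity(v3, m),
               center_of_velocity(pmax(v3, 0) * 1, m))

  # no forward pixels -> NULL (propagates as a gated frame)
  expect_null(center_of_velocity(-v, m))
  expect_equal(center_of_velocity(-v, m, forward_sign = -1), vessel_center(m))
})

test_that("a Gaussian jet centroid lands within 0.1 px of the imposed center", {
  p <- jet_params(offset_frac = 0.2, retro_target_ml = 0)
  sim <- simulate_velocity_series(p)
  k <- sim$truth$peak_frame
  cov <- center_of_velocity(sim$series$velocity[, , k],
                            sim$series$mask[, , k])
  ctr <- vessel_center(sim$series$mask[, , k])
  d_eq_mm <- sim$truth$per_frame$d_eq_mm[k]
  u <- c(sin(sim$truth$per_frame$jet_angle_deg[k] * pi / 180),
         -cos(sim$truth$per_frame$jet_angle_deg[k] * pi / 180))
  expected <- ctr + 0.2 * d_eq_mm * u / rev(p$pixel_spacing_mm)
  expect_lt(sqrt(sum((cov - expected)^2)), 0.1)
})

test_that("flow displacement matches its definition and the brute-force oracle", {
  # axisymmetric profile on a symmetric grid: FD ~ 0
  g <- 96
  m <- disc_mask(g, 30)
  c0 <- (g - 1) / 2
  xs <- matrix(rep(0:(g - 1), each = g), g, g)
  ys <- matrix(rep(0:(g - 1), times = g), g, g)
  v <- pmax(0, 1 - ((xs - c0)^2 + (ys - c0)^2) / 30^2) * 50
  fd0 <- flow_displacement_frame(v, m, c(1, 1))
  expect_lt(fd0[["fd_pct"]], 1e-9)

  # jet centroid at 0.25 D_eq -> FD 25% by definition
  d_eq_px <- 2 * sqrt(sum(m) / pi)
  v2 <- matrix(0, g, g)
  target_x <- round(c0 + 0.25 * d_eq_px)
  target_y <- round(c0)
  v2[target_y + 1, target_x + 1] <- 10
  fd2 <- flow_displacement_frame(v2, m, c(1, 1))
  ctr <- vessel_center(m)
  offset_px <- sqrt((target_x - ctr[["x"]])^2 + (target_y - ctr[["y"]])^2)
  expect_equal(fd2[["fd_pct"]], 100 * offset_px / d_eq_px, tolerance = 1e-12)
  expect_equal(fd2[["fd_pct"]], 25, tolerance = 0.05)  # rounded to a pixel

  # random fields equal the brute-force weighted-centroid oracle
  withr::with_seed(7, {
    for (rep in 1:10) {
      vr <- matrix(stats::rnorm(g * g, sd = 20), g, g)
      fd <- flow_displacement_frame(vr, m, c(1.1, 0.8))
      expect_equal(fd[["fd_pct"]], oracle_fd_frame(vr, m, c(1.1, 0.8)),
                   tolerance = 1e-12)
    }
  })

  # radius normalization doubles the percentage
  fd_r <- flow_displacement_frame(v2, m, c(1, 1), normalization = "radius")
  expect_equal(fd_r[["fd_pct"]], 2 * fd2[["fd_pct"]], tolerance = 1e-12)
})

test_that("fd is invariant to velocity scaling and rigid translation", {
  withr::with_seed(21, {
    g <- 64
    m0 <- disc_mask(g, 14)
    v0 <- matrix(stats::rnorm(g * g, 5, 10), g, g)
    base <- flow_displacement_frame(v0, m0, c(1, 1))
    scaled <- flow_displacement_frame(4.2 * v0, m0, c(1, 1))
    expect_equal(scaled, base, tolerance = 1e-12)

    shift <- function(mat, dr, dc) {
      out <- matrix(0, nrow(mat), ncol(mat))
      out[(1 + dr):nrow(mat), (1 + dc):ncol(mat)] <-
        mat[1:(nrow(mat) - dr), 1:(ncol(mat) - dc)]
      out
    }
    moved <- flow_displacement_frame(shift(v0, 5, 3), shift(m0, 5, 3) > 0,
                                     c(1, 1))
    expect_equal(moved, base, tolerance = 1e-9)
  })
})

test_that("fd is bounded by the mask extent", {
  withr::with_seed(9, {
    for (rep in 1:20) {
      g <- 48
      m <- matrix(stats::runif(g * g) < 0.2, g, g)
      if (sum(m) < 3) next
      v <- matrix(stats::rexp(g * g), g, g)
      fd <- flow_displacement_frame(v, m, c(1, 1))
      ctr <- vessel_center(m)
      idx <- which(m, arr.ind = TRUE)
      r_max <- sqrt(max((idx[, 2] - 1 - ctr[["x"]])^2 +
                          (idx[, 1] - 1 - ctr[["y"]])^2))
      d_eq <- 2 * sqrt(sum(m) / pi)
      expect_lte(fd[["fd_pct"]], 100 * r_max / d_eq + 1e-9)
    }
  })
})

test_that("the laminar gate zeroes RA at or below threshold and is monotone", {
  fd <- tibble::tibble(frame = 1:6, time_s = (0:5) / 10,
                       fd_pct = c(10, 11.9, 12, 12.1, 20, NA),
                       ra_deg = c(5, 10, 15, 20, 25, NA),
                       gated = is.na(fd_pct))
  g <- apply_ra_gate(fd, gate_pct = 12)
  expect_identical(g$gated, c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_true(all(is.na(g$ra_deg[g$gated])))
  expect_identical(g$ra_deg[4:5], c(20, 25))

  # raising the gate never ungates a frame
  n_gated <- vapply(seq(0, 40, by = 2),
                    function(th) sum(apply_ra_gate(fd, th)$gated), numeric(1))
  expect_true(all(diff(n_gated) >= 0))
})

test_that("fd summaries average the landmark windows", {
  fd <- tibble::tibble(frame = 1:8, time_s = (0:7) / 10,
                       fd_pct = c(NA, 10, 10, 30, 30, 40, 20, 20),
                       ra_deg = NA_real_, gated = TRUE)
  lm_ <- make_landmarks(peak = 3, end = 5, n = 8)
  s <- fd_summaries(fd, lm_)
  expect_equal(s$fds_avg_pct, mean(c(10, 10, 30, 30)))  # NA frame excluded
  expect_equal(s$fdls_avg_pct, mean(c(10, 30, 30)))
  expect_equal(s$fdd_avg_pct, mean(c(40, 20, 20)))
  expect_equal(s$fdps_pct, 10)

  fd2 <- tibble::tibble(frame = 1:8, time_s = (0:7) / 10, fd_pct = 20,
                        ra_deg = 0, gated = FALSE)
  s2 <- fd_summaries(fd2, lm_)
  expect_true(all(unlist(s2) == 20))
})

test_that("delta RA measures stabilization-to-end-systole rotation", {
  mk <- function(ra) tibble::tibble(frame = seq_along(ra),
                                    time_s = (seq_along(ra) - 1) / 10,
                                    fd_pct = 20, ra_deg = ra,
                                    gated = is.na(ra))
  lm_ <- make_landmarks(peak = 2, end = 9, n = 10)

  # constant after peak -> 0
  expect_equal(delta_ra(mk(rep(10, 10)), lm_), 0)

  # settles at 10 deg then ramps to 40 at end systole -> 30
  ra <- c(NA, 10, 10, 10, 18, 26, 34, 40, 40, NA)
  expect_equal(delta_ra(mk(ra), lm_), 30)

  # angle-wrap: the same trajectory +360 gives the same answer
  expect_equal(delta_ra(mk(ra + 360), lm_), 30)

  # no stabilization (always fast) -> NA with warning
  ra2 <- c(NA, 0, 40, 80, 120, 160, -160, -120, -80, NA)
  expect_warning(out <- delta_ra(mk(ra2), lm_), "stabilization")
  expect_true(is.na(out))
})

test_that("rotational speed converts wrapped angle steps to rev/s", {
  mk <- function(ra, fdv = 20) {
    tibble::tibble(frame = seq_along(ra), time_s = (seq_along(ra) - 1) / 10,
                   fd_pct = fdv, ra_deg = ra, gated = is.na(ra))
  }
  lm_ <- make_landmarks(peak = 2, end = 6, n = 8)

  # 36 deg per 0.1 s step -> 1 rev/s
  rs <- rotational_speed(mk(seq(0, by = 36, length.out = 8)), lm_, 0.1)
  expect_equal(rs$rs$rs_rev_s, rep(1, 7))
  expect_equal(rs$rsls_avg_rev_s, 1)

  # constant angle -> 0 everywhere
  expect_equal(rotational_speed(mk(rep(45, 8)), lm_, 0.1)$rsls_avg_rev_s, 0)

  # gated frames break pairs and are excluded, not zero-filled
  ra <- c(0, 36, NA, 108, 144, 180, 216, 252)
  rs2 <- rotational_speed(mk(ra), lm_, 0.1)
  expect_false(any(rs2$rs$frame_from %in% c(2, 3)))
  expect_equal(rs2$rsls_avg_rev_s, 1)  # pairs (4,5), (5,6)

  # wrap: a trajectory crossing the +/-180 seam still reads as steady rotation
  ra3 <- wrap_angle(seq(120, by = 36, length.out = 8))
  rs3 <- rotational_speed(mk(ra3), lm_, 0.1)
  expect_equal(rs3$rsls_avg_rev_s, 1)

  expect_error(rotational_speed(mk(ra3), lm_, 0),
               class = "aortaflow_error_value")
  expect_warning(
    out <- rotational_speed(mk(c(NA, 10, NA, 20, NA, 30, NA, 40)), lm_, 0.1),
    "no ungated")
  expect_true(is.na(out$rsls_avg_rev_s))
})

test_that("imposed rotating jet is recovered frame by frame", {
  p <- jet_params(offset_frac = 0.2, rotation_rev_s = 0.5,
                  retro_target_ml = 0)
  sim <- simulate_velocity_series(p)
  fd <- apply_ra_gate(flow_displacement(sim$series), 12)
  k <- !fd$gated
  expect_equal(fd$ra_deg[k], sim$truth$per_frame$jet_angle_deg[k],
               tolerance = 2 / 360)  # within 2 degrees (relative to 360)
})
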