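# Independent brute-force oracles used across the suite. These deliberately
# use naive loops / direct formulas, never the package's vectorized paths.

# Forward-velocity-weighted centroid and FD by explicit pixel loops,
# 0-based coordinates (x = column, y = row).
oracle_fd_frame <- function(vel, mask, spacing, forward_sign = 1) {
  sx <- sy <- sw <- 0
  cx <- cy <- npix <- 0
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j]) next
      npix <- npix + 1
      cx <- cx + (j - 1)
      cy <- cy + (i - 1)
      v <- forward_sign * vel[i, j]
      if (v > 0) {
        sw <- sw + v
        sx <- sx + v * (j - 1)
        sy <- sy + v * (i - 1)
      }
    }
  }
  if (sw == 0) return(NA_real_)
  dx_mm <- (sx / sw - cx / npix) * spacing[2]
  dy_mm <- (sy / sw - cy / npix) * spacing[1]
  d_eq_mm <- 2 * sqrt(npix * prod(spacing) / pi)
  100 * sqrt(dx_mm^2 + dy_mm^2) / d_eq_mm
}

# AUC as the exhaustive pairwise concordance count (ties = 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Binomial log-likelihood evaluated directly at given probabilities.
oracle_logistic_deviance <- function(y, prob) {
  -2 * sum(y * log(prob) + (1 - y) * log(1 - prob))
}

# A small series wrapper for hand-built frames (pads timing metadata).
make_series <- function(velocity, mask, spacing = c(1, 1), rr_ms = 1000,
                        forward_sign = 1, roi = "ascending") {
  n <- dim(velocity)[3]
  velocity_series(
    velocity = velocity, mask = mask,
    trigger_times_ms = (0:(n - 1)) * rr_ms / n,
    rr_interval_ms = rr_ms, pixel_spacing_mm = spacing,
    roi_label = roi, forward_sign = forward_sign
  )
}

# Hand-made landmark windows for unit tests of the displacement summaries.
make_landmarks <- function(peak, end, n) {
  structure(list(
    peak_systole_idx = peak, end_systole_idx = end,
    end_systole_time_s = NA_real_,
    systole = seq_len(end), late_systole = seq(peak, end),
    diastole = if (end < n) seq(end + 1, n) else integer(0)
  ), class = "phase_landmarks")
}

# Disc mask on a g x g grid, radius in pixels, center at the grid center.
disc_mask <- function(g, r_px) {
  c0 <- (g - 1) / 2
  xs <- matrix(rep(0:(g - 1), each = g), g, g)
  ys <- matrix(rep(0:(g - 1), times = g), g, g)
  sqrt((xs - c0)^2 + (ys - c0)^2) <= r_px
}
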