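#' Intraclass correlation, two-way mixed model, consistency, average measures
#'
#' ICC for the average of k = 2 measurements under the two-way mixed-effects
#' model with the consistency definition (fixed rater offsets are ignored),
#' computed from the two-way ANOVA mean squares as
#' `(MS_between - MS_error) / MS_between` (ICC(3,k) in the
#' Shrout-Fleiss taxonomy). The confidence interval uses the F-distribution
#' bounds on `F = MS_between / MS_error` with `(n-1, (n-1)(k-1))` degrees of
#' freedom.
#'
#' @param m1,m2 paired measurement vectors, length >= 5.
#' @param conf_level confidence level (default 0.95).
#' @return one-row tibble: `icc`, `ci_low`, `ci_high`, `n`.
#' @export
icc_consistency_average <- function(m1, m2, conf_level = 0.95) {
  n <- length(m1)
  if (length(m2) != n || n < 5L) {
    abort("m1 and m2 must be paired with n >= 5.",
          class = "aortaflow_error_value")
  }
  x <- cbind(m1, m2)
  k <- 2L
  grand <- mean(x)
  subj_means <- rowMeans(x)
  rater_means <- colMeans(x)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_rater <- n * sum((rater_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_subj - ss_rater
  ms_subj <- ss_subj / (n - 1)
  ms_err <- max(0, ss_err) / ((n - 1) * (k - 1))
  if (ms_subj <= 0) {
    abort("zero between-subject variance; ICC undefined.",
          class = "aortaflow_error_value")
  }
  if (ms_err == 0) {
    return(tibble(icc = 1, ci_low = 1, ci_high = 1, n = n))
  }
  f <- ms_subj / ms_err
  alpha <- 1 - conf_level
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  fl <- f / qf(1 - alpha / 2, df1, df2)
  fu <- f * qf(1 - alpha / 2, df2, df1)
  tibble(icc = 1 - 1 / f, ci_low = 1 - 1 / fl, ci_high = 1 - 1 / fu, n = n)
}

#' Coefficient of variation between paired repeated measurements
#'
#' `CV = 100 * SD / mean` with the paired-difference definitions
#' `SD = sqrt(sum((m1 - m2)^2) / (2n))` and
#' `mean = sum(m1 + m2) / (2n)`, n the number of pairs. When the mean is
#' near zero the CV is not meaningful and `NA` is returned with a warning.
#'
#' @param m1,m2 paired measurement vectors.
#' @return CV in percent (scale-invariant), or `NA` when the mean is near 0.
#' @export
cv_pairs <- function(m1, m2) {
  n <- length(m1)
  if (length(m2) != n || n < 1L) {
    abort("m1 and m2 must be paired.", class = "aortaflow_error_value")
  }
  sd_within <- sqrt(sum((m1 - m2)^2) / (2 * n))
  mean_pair <- sum(m1 + m2) / (2 * n)
  if (abs(mean_pair) <= 1e-8 * max(abs(c(m1, m2, 1)))) {
    warn("mean of the measurements is near 0; CV not calculated.")
    return(NA_real_)
  }
  100 * sd_within / mean_pair
}

#' Bland-Altman agreement statistics
#'
#' Mean difference `m1 - m2`, SD of the differences, and the limits of
#' agreement `mean +/- 1.96 SD`.
#'
#' @param m1,m2 paired measurement vectors, length >= 3.
#' @return object of class `bland_altman`: `stats` (one-row tibble:
#'   `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `n`) and `data` (per-pair
#'   means and differences, for plotting). `tidy()` returns `stats`.
#' @export
bland_altman <- function(m1, m2) {
  n <- length(m1)
  if (length(m2) != n || n < 3L) {
    abort("m1 and m2 must be paired with n >= 3.",
          class = "aortaflow_error_value")
  }
  d <- m1 - m2
  md <- mean(d)
  sdd <- sd(d)
  structure(
    list(
      stats = tibble(mean_diff = md, sd_diff = sdd,
                     loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
                     n = n),
      data = tibble(mean = (m1 + m2) / 2, diff = d)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<bland_altman> mean diff %.4g, LoA [%.4g, %.4g], n = %d\n",
    s$mean_diff, s$loa_low, s$loa_high, s$n))
  invisible(x)
}

#' @rdname bland_altman
#' @param x a `bland_altman` object.
#' @param ... unused.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) x$stats

#' Full agreement summary for a measurement pair
#'
#' Convenience wrapper combining [icc_consistency_average()], [cv_pairs()]
#' and [bland_altman()] into one row, the layout of a reproducibility table.
#'
#' @param m1,m2 paired measurement vectors, length >= 5.
#' @return one-row tibble: `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `icc`, `icc_ci_low`, `icc_ci_high`, `cv_pct`, `n`.
#' @export
agreement_stats <- function(m1, m2) {
  ba <- tidy(bland_altman(m1, m2))
  ic <- icc_consistency_average(m1, m2)
  cv <- suppressWarnings(cv_pairs(m1, m2))
  tibble(
    mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    icc = ic$icc, icc_ci_low = ic$ci_low, icc_ci_high = ic$ci_high,
    cv_pct = cv, n = ba$n
  )
}
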