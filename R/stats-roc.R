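#' Empirical ROC curve, AUC, and Youden-optimal threshold
#'
#' Builds the empirical ROC of `scores` against binary `labels`. The AUC is
#' the trapezoidal area, which equals the pairwise concordance U-statistic
#' (ties counted one half). Its 95% CI is the normal approximation
#' `AUC +/- 1.96 SE` with the Hanley-McNeil standard error. The operating
#' threshold maximizes the Youden index `sensitivity + specificity - 1`; ties
#' are broken toward the higher specificity. Thresholds are midpoints between
#' consecutive distinct score values, so a perfectly separating threshold
#' falls between the classes.
#'
#' @param scores numeric marker values.
#' @param labels binary outcome (0/1, logical, or two-level factor); both
#'   classes must be present.
#' @param direction `"greater"` when larger scores indicate the positive
#'   class, `"less"` for the opposite, `"auto"` to pick the orientation with
#'   AUC >= 0.5.
#' @return object of class `roc_result`: `curve` (tibble of `threshold`,
#'   `sensitivity`, `specificity`, `youden`), `auc`, `auc_ci_low`,
#'   `auc_ci_high`, `youden_threshold`, `direction`, `n_pos`, `n_neg`.
#'   `tidy()` returns the curve, `glance()` the scalar summary.
#' @export
roc_auc_youden <- function(scores, labels,
                           direction = c("greater", "less", "auto")) {
  direction <- match.arg(direction)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels) | labels > 0)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("both classes must be present.", class = "aortaflow_error_value")
  }

  if (direction == "auto") {
    direction <- if (auc_concordance(scores, labels) >= 0.5) "greater" else "less"
  }
  s <- if (direction == "less") -scores else scores

  auc <- auc_concordance(s, labels)
  se <- hanley_mcneil_se(auc, n_pos, n_neg)

  # thresholds: midpoints between distinct scores, plus sentinels
  u <- sort(unique(s))
  thr <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
  sens <- vapply(thr, function(th) mean(s[labels == 1L] >= th), numeric(1))
  spec <- vapply(thr, function(th) mean(s[labels == 0L] < th), numeric(1))
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  best <- best[which.max(spec[best])]  # ties -> higher specificity

  thr_out <- if (direction == "less") -thr else thr
  curve <- tibble(threshold = thr_out, sensitivity = sens,
                  specificity = spec, youden = youden)
  structure(
    list(curve = curve,
         auc = auc,
         auc_se = se,
         auc_ci_low = max(0, auc - 1.96 * se),
         auc_ci_high = min(1, auc + 1.96 * se),
         youden_threshold = thr_out[best],
         youden_max = youden[best],
         direction = direction, n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

# AUC as the pairwise concordance U-statistic (ties count 1/2), computed via
# the rank-sum identity.
auc_concordance <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f (95%% CI %.3f-%.3f), Youden threshold %.4g (direction %s)\n",
    x$auc, x$auc_ci_low, x$auc_ci_high, x$youden_threshold, x$direction))
  invisible(x)
}

#' @rdname roc_auc_youden
#' @param x a `roc_result`.
#' @param ... unused.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname roc_auc_youden
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, auc_ci_low = x$auc_ci_low, auc_ci_high = x$auc_ci_high,
         youden_threshold = x$youden_threshold, youden_max = x$youden_max,
         n_pos = x$n_pos, n_neg = x$n_neg)
}
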