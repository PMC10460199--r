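#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_vline geom_abline geom_area labs theme_minimal annotate
NULL

#' @export
ggplot2::autoplot

#' Plot a flow curve
#'
#' Net, forward and retrograde rates against time.
#'
#' @param object a `flow_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.flow_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("time_s", "net_ml_s", "forward_ml_s", "retro_ml_s")],
    -"time_s", names_to = "component", values_to = "rate")
  long$component <- sub("_ml_s$", "", long$component)
  ggplot(long, aes(x = .data$time_s, y = .data$rate,
                   colour = .data$component)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_line() +
    labs(x = "time (s)", y = "flow rate (mL/s)", colour = NULL) +
    theme_minimal()
}

#' Plot a flow-displacement series
#'
#' Displacement against frame with the laminar gate marked; gated frames are
#' drawn at RA = 0, as in the conventional display, but carry no angle in the
#' analysis.
#'
#' @param object an `fd_series`.
#' @param gate_pct gate threshold drawn as a reference line.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fd_series <- function(object, gate_pct = 12, ...) {
  d <- as_tibble(object)
  ggplot(d, aes(x = .data$frame, y = .data$fd_pct)) +
    geom_hline(yintercept = gate_pct, linetype = 2, colour = "grey50") +
    geom_line(na.rm = TRUE) +
    geom_point(aes(colour = .data$gated), na.rm = TRUE) +
    labs(x = "frame", y = "flow displacement (%)", colour = "gated") +
    theme_minimal()
}

#' Plot an ROC curve with the Youden-optimal point
#'
#' @param object a `roc_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  d <- object$curve[order(1 - object$curve$specificity,
                          object$curve$sensitivity), ]
  best <- object$curve[which(object$curve$youden == object$youden_max)[1L], ]
  ggplot(d, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey70", linetype = 2) +
    geom_line() +
    annotate("point", x = 1 - best$specificity, y = best$sensitivity,
             colour = "red") +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("AUC %.3f (%.3f-%.3f)", object$auc,
                         object$auc_ci_low, object$auc_ci_high)) +
    theme_minimal()
}

#' Bland-Altman plot
#'
#' Differences against pair means with the bias and the 95% limits of
#' agreement.
#'
#' @param object a `bland_altman` result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  s <- object$stats
  ggplot(object$data, aes(x = .data$mean, y = .data$diff)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = s$mean_diff, colour = "blue") +
    geom_hline(yintercept = c(s$loa_low, s$loa_high),
               colour = "blue", linetype = 2) +
    labs(x = "mean of measurements", y = "difference") +
    theme_minimal()
}
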