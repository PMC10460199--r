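#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation and its two-sided p-value from the t transform
#' `t = r sqrt((n-2)/(1-r^2))` (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3, finite, each with
#'   positive variance.
#' @return one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("x and y must have equal length >= 3.",
          class = "aortaflow_error_value")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("x and y must be finite.", class = "aortaflow_error_value")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in x or y.", class = "aortaflow_error_value")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Least-squares slope of minute ventilation on carbon-dioxide output
#'
#' The ventilatory-efficiency slope: OLS slope of VE on VCO2
#' (`y = m x + b`, `m` returned).
#'
#' @param ve minute ventilation samples.
#' @param vco2 carbon-dioxide output samples.
#' @return the slope, dimensionless.
#' @export
ve_vco2_slope <- function(ve, vco2) {
  if (length(ve) != length(vco2) || length(ve) < 3L) {
    abort("ve and vco2 must have equal length >= 3.",
          class = "aortaflow_error_value")
  }
  if (var(vco2) == 0) {
    abort("vco2 has zero variance.", class = "aortaflow_error_value")
  }
  unname(coef(lm(ve ~ vco2))[2L])
}

#' Metabolic equivalents from peak oxygen uptake
#'
#' One MET is 3.5 mL of oxygen per kg body weight per minute (resting
#' consumption), so `METs = pvo2 / 3.5`.
#'
#' @param pvo2 peak oxygen uptake, mL/kg/min (>= 0).
#' @return METs, dimensionless.
#' @export
mets_from_pvo2 <- function(pvo2) {
  if (any(pvo2 < 0, na.rm = TRUE)) {
    abort("pvo2 must be >= 0.", class = "aortaflow_error_value")
  }
  pvo2 / 3.5
}

#' Exercise-capacity risk strata from peak oxygen uptake
#'
#' Boundary-inclusive classification: `high` when PVO2 <= 14 mL/kg/min,
#' `low_intermediate` when 14 < PVO2 <= 20, `normal` when PVO2 > 20.
#'
#' @param pvo2 peak oxygen uptake, mL/kg/min (>= 0).
#' @return factor with levels `normal`, `low_intermediate`, `high`.
#' @export
risk_class <- function(pvo2) {
  if (any(pvo2 < 0, na.rm = TRUE)) {
    abort("pvo2 must be >= 0.", class = "aortaflow_error_value")
  }
  out <- ifelse(pvo2 <= 14, "high",
                ifelse(pvo2 <= 20, "low_intermediate", "normal"))
  factor(out, levels = c("normal", "low_intermediate", "high"))
}

#' Peak oxygen uptake predicted by the published composite model
#'
#' The exact printed linear combination
#' `20.729 + 0.443 * ffi - 0.261 * fds_avg - 0.172 * lvef`
#' (see [pvo2_composite_coefs]). Vectorized.
#'
#' @param ffi aortic forward flow index, mL/m^2.
#' @param fds_avg average systolic flow displacement, %.
#' @param lvef left-ventricular ejection fraction, %.
#' @return predicted PVO2, mL/kg/min.
#' @export
predict_pvo2_published <- function(ffi, fds_avg, lvef) {
  b <- pvo2_composite_coefs
  b[["intercept"]] + b[["ffi"]] * ffi + b[["fds_avg"]] * fds_avg +
    b[["lvef"]] * lvef
}

term_p_values <- function(fit) {
  s <- summary(fit)$coefficients
  p <- s[, 4L]
  p[setdiff(rownames(s), "(Intercept)")]
}

#' Stepwise ordinary least squares (forward selection, backward elimination)
#'
#' Candidates are first screened univariately: only terms with univariate
#' p < `p_screen` enter the candidate pool (set `p_screen = 1` to disable).
#' Then forward steps add the candidate with the smallest partial-t p-value
#' while it is below `p_enter` (ties broken toward the smaller p, then
#' alphabetical term name), and after every addition backward steps drop any
#' included term whose p-value exceeds `p_remove` (largest first). The
#' procedure is fully deterministic. Candidates that would make the design
#' matrix numerically rank-deficient are skipped with a warning.
#'
#' @param data a data frame (e.g. from [simulate_cohort()] or
#'   [load_cohort_table()]).
#' @param response name of the response column.
#' @param candidates character vector of candidate predictor columns.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @param p_screen univariate screening threshold (default 0.05).
#' @return object of class `stepwise_lm`: the final [stats::lm] fit plus the
#'   selection history. `tidy()` gives coefficients with 95% CIs, `glance()`
#'   the model-level summary.
#' @export
stepwise_ols <- function(data, response, candidates,
                         p_enter = 0.05, p_remove = 0.10, p_screen = 0.05) {
  if (nrow(data) <= length(candidates) + 2L) {
    abort("need n > number of candidates + 2.",
          class = "aortaflow_error_value")
  }
  cc <- stats::complete.cases(data[, c(response, candidates)])
  data <- data[cc, , drop = FALSE]

  screened <- candidates[vapply(candidates, function(v) {
    f <- stats::reformulate(v, response)
    term_p_values(lm(f, data))[[v]] < p_screen
  }, logical(1))]

  selected <- character(0)
  history <- list()
  pool <- sort(screened)
  repeat {
    # forward step
    best <- NULL
    if (length(pool)) {
      ps <- vapply(pool, function(v) {
        f <- stats::reformulate(c(selected, v), response)
        X <- stats::model.matrix(f, data)
        if (qr(X)$rank < ncol(X)) return(NA_real_)  # collinear: skip
        term_p_values(lm(f, data))[[v]]
      }, numeric(1))
      if (any(is.na(ps))) {
        warn(paste0("skipping collinear candidate(s): ",
                    paste(pool[is.na(ps)], collapse = ", ")))
      }
      ok <- which(!is.na(ps) & ps < p_enter)
      if (length(ok)) {
        best <- pool[ok][order(ps[ok], pool[ok])][1L]
      }
    }
    if (is.null(best)) break
    selected <- c(selected, best)
    pool <- setdiff(pool, best)
    history[[length(history) + 1L]] <-
      tibble(step = length(history) + 1L, action = "add", term = best)

    # backward elimination
    repeat {
      f <- stats::reformulate(selected, response)
      ps <- term_p_values(lm(f, data))[selected]
      worst <- names(ps)[order(-ps, names(ps))][1L]
      if (ps[[worst]] <= p_remove) break
      selected <- setdiff(selected, worst)
      pool <- sort(c(pool, worst))
      history[[length(history) + 1L]] <-
        tibble(step = length(history) + 1L, action = "drop", term = worst)
      if (!length(selected)) break
    }
  }

  f <- if (length(selected)) stats::reformulate(selected, response)
       else stats::reformulate("1", response)
  fit <- lm(f, data)
  structure(
    list(fit = fit, selected = selected, screened = screened,
         candidates = candidates, response = response,
         history = dplyr::bind_rows(history),
         p_enter = p_enter, p_remove = p_remove, p_screen = p_screen),
    class = "stepwise_lm"
  )
}

#' @export
print.stepwise_lm <- function(x, ...) {
  cat(sprintf("<stepwise_lm> %s ~ %s (R^2 = %.3f)\n", x$response,
              if (length(x$selected)) paste(x$selected, collapse = " + ")
              else "1",
              summary(x$fit)$r.squared))
  invisible(x)
}

#' @rdname stepwise_ols
#' @param x a `stepwise_lm` object.
#' @param ... unused.
#' @method tidy stepwise_lm
#' @export
tidy.stepwise_lm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  ci <- confint(x$fit, level = 0.95)
  tibble(
    term = rownames(s),
    estimate = s[, 1L],
    std_error = s[, 2L],
    statistic = s[, 3L],
    p_value = s[, 4L],
    conf_low = ci[, 1L],
    conf_high = ci[, 2L]
  )
}

#' @rdname stepwise_ols
#' @method glance stepwise_lm
#' @export
glance.stepwise_lm <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared,
    sigma = s$sigma,
    n = length(s$residuals),
    n_selected = length(x$selected)
  )
}

#' Incremental value of a term by nested logistic likelihood-ratio test
#'
#' Fits two nested binomial-logit models — `outcome ~ base_terms` and
#' `outcome ~ base_terms + added_term` — and compares them by the
#' likelihood-ratio chi-square with 1 degree of freedom. Non-convergence
#' (e.g. complete separation) raises a distinct error. An added term that is
#' aliased with the base terms yields chi-square 0, p = 1.
#'
#' @param data data frame.
#' @param outcome name of the binary outcome column (0/1 or logical); both
#'   classes must be present.
#' @param base_terms character vector of base model terms.
#' @param added_term single term whose increment is tested.
#' @return one-row tibble: `chi2`, `df`, `p_value`, `deviance_base`,
#'   `deviance_full`.
#' @export
nested_logistic_lrt <- function(data, outcome, base_terms, added_term) {
  y <- data[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2L) {
    abort("outcome must contain both classes.",
          class = "aortaflow_error_value")
  }
  fit_one <- function(terms) {
    f <- stats::reformulate(terms, outcome)
    fit <- withCallingHandlers(
      glm(f, family = binomial(), data = data),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          abort("logistic fit did not converge (separation).",
                class = "aortaflow_error_separation")
        }
        invokeRestart("muffleWarning")
      }
    )
    # complete separation can also "converge" with fitted probabilities at
    # the machine boundary and deviance ~ 0; reject that fit too
    mu <- stats::fitted(fit)
    if (!fit$converged || any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
      abort("logistic fit did not converge (separation).",
            class = "aortaflow_error_separation")
    }
    fit
  }
  base <- fit_one(base_terms)
  full <- fit_one(c(base_terms, added_term))
  chi2 <- max(0, base$deviance - full$deviance)
  tibble(
    chi2 = chi2,
    df = 1L,
    p_value = pchisq(chi2, df = 1L, lower.tail = FALSE),
    deviance_base = base$deviance,
    deviance_full = full$deviance
  )
}

#' Group-comparison convenience wrappers
#'
#' Thin, clearly-labelled wrappers over [stats::aov()] /
#' [stats::kruskal.test()] / [stats::chisq.test()] for descriptive
#' group-difference tables. Routing between ANOVA and Kruskal-Wallis is the
#' caller's choice (`normal`), not an inference made here.
#'
#' @param x values (numeric for `anova`/`kruskal`, categorical for `chisq`).
#' @param group grouping factor.
#' @param method `"anova"`, `"kruskal"`, or `"chisq"`.
#' @return one-row tibble: `method`, `statistic`, `p_value`.
#' @export
compare_groups <- function(x, group, method = c("anova", "kruskal", "chisq")) {
  method <- match.arg(method)
  group <- factor(group)
  if (method == "anova") {
    fit <- stats::aov(x ~ group)
    s <- summary(fit)[[1L]]
    tibble(method = "anova", statistic = s$`F value`[1L],
           p_value = s$`Pr(>F)`[1L])
  } else if (method == "kruskal") {
    k <- stats::kruskal.test(x, group)
    tibble(method = "kruskal", statistic = unname(k$statistic),
           p_value = k$p.value)
  } else {
    ct <- stats::chisq.test(table(x, group))
    tibble(method = "chisq", statistic = unname(ct$statistic),
           p_value = ct$p.value)
  }
}
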