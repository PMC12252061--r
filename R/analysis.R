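#' Fisher-z confidence interval for a correlation coefficient
#'
#' Closed-form confidence interval for a Pearson correlation via the Fisher
#' transform: `tanh(atanh(r) +/- z_{(1+c)/2} / sqrt(n - 3))`.
#'
#' @param r Correlation coefficient, `|r| < 1`.
#' @param n Number of paired observations (> 3).
#' @param confidence Confidence level (default 0.95).
#' @return Tibble with `r`, `ci_low`, `ci_high`, `n`, `confidence`.
#' @examples
#' fisher_ci(0.977, 80)   # [0.964, 0.985] to three decimals
#' @export
fisher_ci <- function(r, n, confidence = 0.95) {
  stopifnot(abs(r) < 1, n > 3, confidence > 0, confidence < 1)
  zq <- stats::qnorm((1 + confidence) / 2)
  half <- zq / sqrt(n - 3)
  tibble::tibble(
    r = r,
    ci_low = tanh(atanh(r) - half),
    ci_high = tanh(atanh(r) + half),
    n = n,
    confidence = confidence
  )
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Equal-length numeric vectors (n >= 4, finite, non-constant).
#' @param confidence Confidence level (default 0.95).
#' @return Tibble as [fisher_ci()].
#' @export
pearson_with_ci <- function(x, y, confidence = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 4,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: an input has zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    # exact linear relation: the interval collapses
    return(tibble::tibble(r = r, ci_low = r, ci_high = r,
                          n = length(x), confidence = confidence))
  }
  fisher_ci(r, length(x), confidence)
}

#' Compare two independent correlations (Fisher Z-test)
#'
#' Two-sided z-test of `H0: rho1 = rho2` for correlations from independent
#' samples: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`.
#'
#' @param r1,r2 Correlation coefficients (`|r| < 1`).
#' @param n1,n2 Sample sizes (> 3).
#' @return Tibble with `z_statistic` and `p_value` (two-sided).
#' @examples
#' compare_correlations_fisher(0.977, 80, 0.926, 80)   # p ~ 2e-4
#' @export
compare_correlations_fisher <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z_statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Linear calibration of predictions against observations
#'
#' Ordinary least squares of `observed ~ predicted`; the corrected
#' predictions `slope * predicted + intercept` have zero mean signed error
#' against the observations by the OLS normal equations. Mirrors the
#' in-practice calibration a deployed torque-limiting instrument would
#' carry.
#'
#' @param predicted,observed Equal-length numeric vectors (n >= 2).
#' @return List with `slope`, `intercept`, `corrected` (numeric vector) and
#'   `model` (the underlying [stats::lm()] fit).
#' @export
linear_calibration <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(predicted) >= 2)
  fit <- stats::lm(observed ~ predicted)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       corrected = unname(stats::fitted(fit)), model = fit)
}

#' Bland-Altman agreement analysis
#'
#' Differences `a - b` (absolute mode) or `100 * (a - b) / pairmean`
#' (relative mode, pair mean per convention), with bias (mean difference)
#' and 95% limits of agreement `bias +/- 1.96 SD`. The mean absolute
#' relative error `mean(|a - b| / b) * 100` is reported in both modes, with
#' the reference measurement `b` as denominator.
#'
#' @param a Predicted/estimated values.
#' @param b Reference (true) values; must be positive in relative mode and
#'   for the relative-error summary.
#' @param relative Use relative (percent of pair mean) differences.
#' @return Object of class `bland_altman`: list with `data` (tibble of pair
#'   `mean` and `diff`) and `summary` (one-row tibble: `bias`, `loa_low`,
#'   `loa_high`, `mean_abs_relative_error_pct`, `relative`, `n`).
#' @export
bland_altman <- function(a, b, relative = FALSE) {
  stopifnot(length(a) == length(b), length(a) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  if (any(b <= 0)) {
    stop("bland_altman requires positive reference values b", call. = FALSE)
  }
  m <- (a + b) / 2
  d <- if (relative) 100 * (a - b) / m else a - b
  bias <- mean(d)
  s <- stats::sd(d)
  out <- structure(
    list(
      data = tibble::tibble(mean = m, diff = d),
      summary = tibble::tibble(
        bias = bias,
        loa_low = bias - 1.96 * s,
        loa_high = bias + 1.96 * s,
        mean_abs_relative_error_pct = mean(abs(a - b) / b) * 100,
        relative = relative,
        n = length(a)
      )
    ),
    class = "bland_altman"
  )
  out
}

#' @export
print.bland_altman <- function(x, ...) {
  s <- x$summary
  unit <- if (s$relative) "%" else ""
  cat(sprintf(
    "<bland_altman> n=%d  bias %.4g%s  LoA [%.4g, %.4g]%s  MARE %.3g%%\n",
    s$n, s$bias, unit, s$loa_low, s$loa_high, unit,
    s$mean_abs_relative_error_pct))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
glance.bland_altman <- function(x, ...) x$summary

#' @rdname bland_altman
#' @export
tidy.bland_altman <- function(x, ...) x$data

#' Statistical evaluation of a processed cohort
#'
#' Reproduces the standard evaluation of predicted versus measured stripping
#' torques over a cohort of insertions: Pearson correlation with Fisher-z
#' confidence interval; an in-sample linear calibration of the predictions;
#' absolute and relative Bland-Altman summaries of the calibrated
#' predictions; and the mean absolute relative error (reference torque as
#' denominator). When the records carry a `sigma_ref` column (data-sheet
#' strengths), the strength-identification correlation is also computed and
#' compared with the torque correlation by a two-sided Fisher Z-test.
#'
#' @param records Tibble with at least `tau_pred` and `tau_true` (N mm);
#'   optionally `material`, `sigma_hat` and `sigma_ref`.
#' @param confidence Confidence level for the Fisher-z intervals.
#' @return Object of class `cohort_analysis`: list with `records` (input
#'   plus `tau_corrected`), `summary` (one-row tibble), `ba_absolute`,
#'   `ba_relative` (the two [bland_altman()] objects) and `calibration`.
#'   `glance()` returns the summary; `tidy()` the augmented records.
#' @export
analyze_cohort <- function(records, confidence = 0.95) {
  stopifnot(all(c("tau_pred", "tau_true") %in% names(records)))
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  torque_ci <- pearson_with_ci(records$tau_pred, records$tau_true,
                               confidence)
  cal <- linear_calibration(records$tau_pred, records$tau_true)
  records$tau_corrected <- cal$corrected
  ba_abs <- bland_altman(records$tau_corrected, records$tau_true,
                         relative = FALSE)
  ba_rel <- bland_altman(records$tau_corrected, records$tau_true,
                         relative = TRUE)

  summary <- tibble::tibble(
    n = n,
    r_torque = torque_ci$r,
    r_torque_ci_low = torque_ci$ci_low,
    r_torque_ci_high = torque_ci$ci_high,
    calibration_slope = cal$slope,
    calibration_intercept = cal$intercept,
    ba_bias = ba_abs$summary$bias,
    ba_loa_low = ba_abs$summary$loa_low,
    ba_loa_high = ba_abs$summary$loa_high,
    ba_rel_bias_pct = ba_rel$summary$bias,
    ba_rel_loa_low_pct = ba_rel$summary$loa_low,
    ba_rel_loa_high_pct = ba_rel$summary$loa_high,
    mean_abs_relative_error_pct =
      ba_abs$summary$mean_abs_relative_error_pct
  )

  if (all(c("sigma_hat", "sigma_ref") %in% names(records))) {
    strength_ci <- pearson_with_ci(records$sigma_hat, records$sigma_ref,
                                   confidence)
    cmp <- compare_correlations_fisher(strength_ci$r, n, torque_ci$r, n)
    summary$r_strength <- strength_ci$r
    summary$r_strength_ci_low <- strength_ci$ci_low
    summary$r_strength_ci_high <- strength_ci$ci_high
    summary$fisher_z <- cmp$z_statistic
    summary$fisher_p <- cmp$p_value
  }

  structure(
    list(records = records, summary = summary, ba_absolute = ba_abs,
         ba_relative = ba_rel, calibration = cal, confidence = confidence),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  s <- x$summary
  cat("<cohort_analysis>\n")
  cat(sprintf("  n = %d insertions\n", s$n))
  cat(sprintf("  r(pred, true stripping torque) = %.3f  %d%% CI [%.3f, %.3f]\n",
              s$r_torque, round(100 * x$confidence), s$r_torque_ci_low,
              s$r_torque_ci_high))
  if ("r_strength" %in% names(s)) {
    cat(sprintf("  r(identified, reference strength) = %.3f  CI [%.3f, %.3f]\n",
                s$r_strength, s$r_strength_ci_low, s$r_strength_ci_high))
    cat(sprintf("  Fisher Z-test (strength vs torque r): p = %.2g\n",
                s$fisher_p))
  }
  cat(sprintf("  calibration: slope %.3f, intercept %.1f N mm\n",
              s$calibration_slope, s$calibration_intercept))
  cat(sprintf("  calibrated mean |relative error| = %.1f%%\n",
              s$mean_abs_relative_error_pct))
  invisible(x)
}

#' @rdname analyze_cohort
#' @param x A `cohort_analysis` object.
#' @param ... Unused.
#' @export
glance.cohort_analysis <- function(x, ...) x$summary

#' @rdname analyze_cohort
#' @export
tidy.cohort_analysis <- function(x, ...) x$records
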