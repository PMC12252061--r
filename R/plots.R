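#' Plot a torque trace
#'
#' Torque, rotation and position against time, facetted; optional segment
#' bounds from [segment_trace()] are drawn as vertical lines.
#'
#' @param object A [torque_trace()].
#' @param bounds Optional one-row bounds tibble from [segment_trace()]
#'   (indices into this trace).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.torque_trace <- function(object, bounds = NULL, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("torque", "rotation", "position"),
    names_to = "channel", values_to = "value"
  )
  long$channel <- factor(long$channel,
                         levels = c("torque", "rotation", "position"),
                         labels = c("torque (N mm)", "rotation (rad)",
                                    "position (mm)"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel),
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
  if (!is.null(bounds)) {
    marks <- object$time[unlist(bounds[, c("start_idx", "tightening_idx",
                                           "stripping_idx", "end_idx")])]
    p <- p + ggplot2::geom_vline(xintercept = marks, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Plot predicted versus measured stripping torques
#'
#' Scatter of the cohort's predictions against the measured stripping
#' torques (N m), coloured by material where available, with the 1:1 line.
#'
#' @param object A `cohort_analysis` from [analyze_cohort()].
#' @param corrected Plot the calibrated predictions instead of the raw ones.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_analysis <- function(object, corrected = FALSE, ...) {
  rec <- object$records
  rec$pred <- if (corrected) rec$tau_corrected else rec$tau_pred
  aes <- if ("material" %in% names(rec)) {
    ggplot2::aes(x = .data$pred / 1000, y = .data$tau_true / 1000,
                 colour = .data$material)
  } else {
    ggplot2::aes(x = .data$pred / 1000, y = .data$tau_true / 1000)
  }
  ggplot2::ggplot(rec, aes) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("%s stripping torque (N m)",
                  if (corrected) "calibrated predicted" else "predicted"),
      y = "measured stripping torque (N m)"
    )
}

#' Bland-Altman plot
#'
#' @param object A [bland_altman()] object.
#' @param ... Unused.
#' @return A ggplot object with bias and limits of agreement.
#' @export
autoplot.bland_altman <- function(object, ...) {
  s <- object$summary
  ylab <- if (s$relative) "difference (% of pair mean)" else
    "difference (N mm)"
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = s$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(s$loa_low, s$loa_high),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = "pair mean", y = ylab)
}
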