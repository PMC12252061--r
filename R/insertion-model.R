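#' Forward insertion-torque model
#'
#' Evaluates the physical insertion model
#' `tau(phi) = sigma_ucs * G1 + mu_T * sigma_ucs * (phi - alpha/2) * G2`:
#' a constant cutting torque from the tapered tip plus a friction torque
#' that grows linearly with rotation as formed thread accumulates behind the
#' tip. For rotations before the engagement offset (`phi < alpha/2`) the
#' friction contribution would be negative and is clamped to zero; the
#' cutting term is retained.
#'
#' @param rotation Numeric vector of rotations (rad, >= 0).
#' @param sigma_ucs Ultimate compressive strength of the host material (MPa).
#' @param coeffs An [insertion_coefficients()] object.
#' @param mu_thread Thread friction coefficient; defaults to the value used
#'   in typical foam benches (0.2) if not supplied.
#' @return Torque vector (N mm), same length as `rotation`.
#' @examples
#' co <- insertion_coefficients(screw_geometry())
#' predict_insertion_torque(c(10, 20, 30), sigma_ucs = 2, co, mu_thread = 0.2)
#' @export
predict_insertion_torque <- function(rotation, sigma_ucs, coeffs,
                                     mu_thread = 0.2) {
  stopifnot(is.numeric(rotation), all(rotation >= 0, na.rm = TRUE),
            is.numeric(sigma_ucs), length(sigma_ucs) == 1L, sigma_ucs >= 0,
            inherits(coeffs, "insertion_coefficients"),
            mu_thread >= 0)
  friction <- pmax(0, mu_thread * (rotation - coeffs$alpha / 2) * coeffs$G2)
  sigma_ucs * (coeffs$G1 + friction)
}

#' Identify material strength from an insertion segment
#'
#' Fits the insertion model to a measured torque--rotation segment by
#' single-parameter linear least squares. With the regressor
#' `x_i = G1 + mu_T * G2 * (phi_i - alpha/2)`, the through-origin minimizer
#' of `sum((tau_i - sigma * x_i)^2)` is the closed form
#' `sigma_hat = sum(tau_i x_i) / sum(x_i^2)` -- deterministic, no iteration.
#' Samples with `phi < alpha/2` (the cutting-only regime, which the clamped
#' forward model describes poorly) are excluded from the fit; the rotation
#' range actually used is reported in `fit_range`.
#'
#' The model has no intercept: strength is the only free parameter, and
#' torque is strictly proportional to it. A negative estimate (possible on
#' pathological data) is returned with `negative = TRUE` rather than an
#' error.
#'
#' @param rotation Rotation samples (rad), ideally the equivalent rotation
#'   derived from the draw-wire position (see [position_to_rotation()]),
#'   which is immune to early engagement slip.
#' @param torque Torque samples (N mm), same length.
#' @param coeffs An [insertion_coefficients()] object.
#' @param mu_thread Thread friction coefficient.
#' @return Object of class `strength_fit`: list with `sigma_ucs` (MPa),
#'   `n_samples`, `sse` (N^2 mm^2), `fit_range` (rad, length 2) and
#'   `negative` (logical quality flag).
#' @examples
#' co <- insertion_coefficients(screw_geometry())
#' phi <- seq(2, 60, by = 0.1)
#' tau <- predict_insertion_torque(phi, 4, co)
#' identify_strength(phi, tau, co)$sigma_ucs   # 4, to machine precision
#' @export
identify_strength <- function(rotation, torque, coeffs, mu_thread = 0.2) {
  stopifnot(is.numeric(rotation), is.numeric(torque),
            inherits(coeffs, "insertion_coefficients"), mu_thread >= 0)
  if (length(rotation) != length(torque)) {
    stop("rotation and torque must have equal length", call. = FALSE)
  }
  keep <- is.finite(rotation) & is.finite(torque) &
    rotation >= coeffs$alpha / 2
  phi <- rotation[keep]
  tau <- torque[keep]
  if (length(phi) == 0L) {
    stop("empty fit segment: no samples at or beyond alpha/2", call. = FALSE)
  }
  x <- coeffs$G1 + mu_thread * coeffs$G2 * (phi - coeffs$alpha / 2)
  sxx <- sum(x * x)
  if (sxx == 0) {
    stop("degenerate fit segment: regressor identically zero", call. = FALSE)
  }
  sigma_hat <- sum(tau * x) / sxx
  resid <- tau - sigma_hat * x
  structure(
    list(sigma_ucs = sigma_hat,
         n_samples = length(phi),
         sse = sum(resid^2),
         fit_range = range(phi),
         negative = sigma_hat < 0,
         mu_thread = mu_thread,
         alpha = coeffs$alpha),
    class = "strength_fit"
  )
}

#' @export
print.strength_fit <- function(x, ...) {
  cat("<strength_fit>\n")
  cat(sprintf("  sigma_ucs %.5g MPa%s\n", x$sigma_ucs,
              if (x$negative) "  [WARNING: negative estimate]" else ""))
  cat(sprintf("  n %d  SSE %.4g  fit range [%.3f, %.3f] rad\n",
              x$n_samples, x$sse, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' @rdname identify_strength
#' @param x A `strength_fit` object.
#' @param ... Unused.
#' @export
tidy.strength_fit <- function(x, ...) {
  tibble::tibble(term = "sigma_ucs", estimate = x$sigma_ucs)
}

#' @rdname identify_strength
#' @export
glance.strength_fit <- function(x, ...) {
  tibble::tibble(
    sigma_ucs = x$sigma_ucs,
    n_samples = x$n_samples,
    sse = x$sse,
    fit_min = x$fit_range[1],
    fit_max = x$fit_range[2],
    negative = x$negative
  )
}
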