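#' Predict the thread-stripping torque from material strength
#'
#' Converts an identified ultimate compressive strength into the torque at
#' which the formed threads shear off along the cylindrical envelope of the
#' screw:
#'
#' `tau_fail = (sigma/sqrt(3)) * A_C * ((1/3) * (Dhead^3 - Dshaft^3) /
#'   (Dhead^2 - Dshaft^2) * mu_H * sin(theta_tau) - (Ds/2) * cos(theta_tau))`
#'
#' The first bracket term is the head--plate friction contribution, the
#' second the shear resistance of the material cylinder at the thread tips;
#' with `theta_tau` in the second quadrant both contributions are positive.
#' The prediction is exactly linear in `sigma_ucs`.
#'
#' A stress concentration factor `kt >= 1` accounts for locally elevated
#' stress at sharp thread tips and is applied by *dividing* the failure
#' torque. It matters most for brittle materials, where tip stresses drive
#' crack formation; ductile materials redistribute the local overload, so
#' the uncorrected torque is the better estimate for them. Accordingly
#' `kt_mode = "none"` is the default, and both bounds are always reported so
#' a cohort can be judged against the two 1:1 scales.
#'
#' @param sigma_ucs Strength value(s), MPa; vectorized.
#' @param geom A [screw_geometry()].
#' @param coeffs Optional [stripping_coefficients()] (recomputed from `geom`
#'   when `NULL`).
#' @param kt_mode `"none"` (report the uncorrected torque as the
#'   prediction), `"full"` (divide by the geometric `kt`; requires it to be
#'   defined, i.e. `gamma > 0`), or `"value"` (divide by `kt_value`).
#' @param kt_value User-supplied concentration factor for
#'   `kt_mode = "value"`.
#' @param ductility_exponent Optional exponent `d` in `[0, 1]` for the
#'   experimental ductility-interpolated prediction `tau_fail / kt^d`
#'   (0 = fully ductile, 1 = fully brittle). Requires a defined or supplied
#'   `kt`. Excluded from default reports.
#' @return A tibble with one row per strength: `sigma_ucs`, `tau_no_kt`,
#'   `tau_kt` (NA when no `kt` is available), `kt_used`, `tau_pred` (the
#'   column selected by `kt_mode`), and `tau_interp` when
#'   `ductility_exponent` is given. Torques in N mm.
#' @examples
#' predict_stripping_torque(4, screw_geometry())   # ~3.06e3 N mm
#' @export
predict_stripping_torque <- function(sigma_ucs, geom, coeffs = NULL,
                                     kt_mode = c("none", "full", "value"),
                                     kt_value = NULL,
                                     ductility_exponent = NULL) {
  kt_mode <- match.arg(kt_mode)
  stopifnot(is.numeric(sigma_ucs), all(sigma_ucs >= 0, na.rm = TRUE))
  validate_geometry(geom)
  if (is.null(coeffs)) coeffs <- stripping_coefficients(geom)
  stopifnot(inherits(coeffs, "stripping_coefficients"))

  Dhead <- geom$head_diameter
  Dshaft <- geom$shank_diameter
  Ds <- geom$major_diameter
  bracket <- (1 / 3) * (Dhead^3 - Dshaft^3) / (Dhead^2 - Dshaft^2) *
    geom$mu_head * sin(coeffs$theta_tau) -
    (Ds / 2) * cos(coeffs$theta_tau)
  tau_no_kt <- sigma_ucs / sqrt(3) * coeffs$A_C * bracket

  kt_avail <- if (!is.null(kt_value)) {
    stopifnot(is.numeric(kt_value), length(kt_value) == 1L, kt_value > 0)
    kt_value
  } else if (coeffs$kt_defined) {
    coeffs$kt
  } else {
    NA_real_
  }

  if (kt_mode == "full" && !coeffs$kt_defined && is.null(kt_value)) {
    stop("kt_mode = \"full\" but the geometric stress concentration factor ",
         "is undefined (gamma = ", signif(coeffs$gamma, 4),
         " <= 0); supply kt_mode = \"value\" with an explicit kt_value",
         call. = FALSE)
  }
  if (kt_mode == "value" && is.null(kt_value)) {
    stop("kt_mode = \"value\" requires kt_value", call. = FALSE)
  }

  tau_kt <- tau_no_kt / kt_avail
  out <- tibble::tibble(
    sigma_ucs = sigma_ucs,
    tau_no_kt = tau_no_kt,
    tau_kt = tau_kt,
    kt_used = kt_avail,
    tau_pred = switch(kt_mode,
                      none = tau_no_kt,
                      full = tau_no_kt / if (!is.null(kt_value)) kt_value
                             else coeffs$kt,
                      value = tau_no_kt / kt_value)
  )
  if (!is.null(ductility_exponent)) {
    d <- ductility_exponent
    stopifnot(is.numeric(d), all(d >= 0 & d <= 1))
    if (!is.finite(kt_avail)) {
      stop("ductility_exponent requires a defined or supplied kt",
           call. = FALSE)
    }
    out$tau_interp <- tau_no_kt / kt_avail^d
  }
  out
}
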