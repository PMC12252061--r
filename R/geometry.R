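#' Screw and hole geometry
#'
#' Bundle the dimensional and frictional parameters of a bone screw and its
#' pilot hole. All lengths are millimetres and all angles are stored in
#' radians; the constructor and the config reader accept degrees for the two
#' angular inputs because that is how data sheets print them. The defaults
#' describe an ISO 5835 HB 6.5 cancellous screw (2.75 mm pitch, 30 mm thread
#' length) inserted into a 3.2 mm pilot hole in polyurethane foam, with
#' literature friction coefficients for foam-on-titanium threads (0.2) and a
#' titanium plate under the head (0.45).
#'
#' @param hole_diameter Pilot-hole diameter Dh (mm).
#' @param major_diameter Screw major (outer thread) diameter Ds (mm).
#' @param shank_diameter Shank diameter at the head, Dshaft (mm).
#' @param head_diameter Head contact-surface diameter Dhead (mm).
#' @param minor_diameter Thread minor (root) diameter Dminor (mm).
#' @param half_angle_deg Thread-profile half angle beta (degrees).
#' @param pitch Thread pitch p (mm per revolution).
#' @param thread_length Threaded length L (mm).
#' @param mu_thread Thread--host friction coefficient (dimensionless).
#' @param mu_head Head--plate friction coefficient (dimensionless).
#' @param end_taper_deg Taper angle of the screw tip (degrees).
#' @param alpha Optional explicit engagement-offset rotation (rad); when
#'   `NULL` it is derived from the tip taper by
#'   [insertion_coefficients()] under the default policy.
#'
#' @return An object of class `screw_geometry`: a named list with all
#'   lengths in mm and angles in radians (`half_angle`, `end_taper`).
#' @examples
#' geom <- screw_geometry()          # HB 6.5 defaults
#' insertion_coefficients(geom)
#' @export
screw_geometry <- function(hole_diameter = 3.2,
                           major_diameter = 6.5,
                           shank_diameter = 2.8,
                           head_diameter = 7.0,
                           minor_diameter = 3.0,
                           half_angle_deg = 15,
                           pitch = 2.75,
                           thread_length = 30,
                           mu_thread = 0.2,
                           mu_head = 0.45,
                           end_taper_deg = 60,
                           alpha = NULL) {
  geom <- structure(
    list(
      hole_diameter = hole_diameter,
      major_diameter = major_diameter,
      shank_diameter = shank_diameter,
      head_diameter = head_diameter,
      minor_diameter = minor_diameter,
      half_angle = half_angle_deg * pi / 180,
      pitch = pitch,
      thread_length = thread_length,
      mu_thread = mu_thread,
      mu_head = mu_head,
      end_taper = end_taper_deg * pi / 180,
      alpha = alpha
    ),
    class = "screw_geometry"
  )
  validate_geometry(geom)
  geom
}

validate_geometry <- function(geom) {
  chk <- function(ok, field, rule) {
    if (!isTRUE(ok)) {
      stop("invalid screw geometry: field `", field, "` violates ", rule,
           call. = FALSE)
    }
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in setdiff(names(geom), "alpha")) {
    chk(num1(geom[[f]]), f, "numeric scalar requirement")
  }
  chk(geom$hole_diameter > 0, "hole_diameter", "Dh > 0")
  chk(geom$major_diameter > geom$hole_diameter, "major_diameter", "Ds > Dh")
  chk(geom$pitch > 0, "pitch", "p > 0")
  chk(geom$half_angle > 0 && geom$half_angle < pi / 2, "half_angle",
      "0 < beta < pi/2")
  chk(geom$thread_length > 0, "thread_length", "L > 0")
  chk(geom$mu_thread >= 0, "mu_thread", "mu_T >= 0")
  chk(geom$mu_head >= 0, "mu_head", "mu_H >= 0")
  chk(geom$shank_diameter > 0, "shank_diameter", "Dshaft > 0")
  chk(geom$head_diameter > geom$shank_diameter, "head_diameter",
      "Dhead > Dshaft")
  chk(geom$minor_diameter > 0, "minor_diameter", "Dminor > 0")
  chk(geom$end_taper > 0 && geom$end_taper < pi / 2, "end_taper",
      "0 < theta_t < pi/2")
  if (!is.null(geom$alpha)) {
    chk(num1(geom$alpha) && geom$alpha >= 0, "alpha", "alpha >= 0")
  }
  invisible(geom)
}

#' @export
print.screw_geometry <- function(x, ...) {
  cat("<screw_geometry>\n")
  cat(sprintf("  Dh %.3g  Ds %.3g  Dshaft %.3g  Dhead %.3g  Dminor %.3g mm\n",
              x$hole_diameter, x$major_diameter, x$shank_diameter,
              x$head_diameter, x$minor_diameter))
  cat(sprintf("  pitch %.3g mm  L %.3g mm  beta %.3g deg  taper %.3g deg\n",
              x$pitch, x$thread_length, x$half_angle * 180 / pi,
              x$end_taper * 180 / pi))
  cat(sprintf("  mu_thread %.3g  mu_head %.3g  alpha %s\n",
              x$mu_thread, x$mu_head,
              if (is.null(x$alpha)) "<from taper>" else format(x$alpha)))
  invisible(x)
}

#' Closed-form coefficients of the insertion-torque model
#'
#' Collapses the screw/hole geometry into the two lumped coefficients of the
#' torque--rotation model: `G1` (mm^3), which scales the cutting torque of
#' the tapered tip, and `G2` (mm^3), which scales the friction torque that
#' grows as formed thread accumulates. Intermediate quantities are exposed
#' for inspection: the pitch angle `theta = atan(p / (pi Ds))`, the
#' effective friction and cutting radii `rf = (Dh + Ds)/4` and
#' `rs = (2 Dh + 2 Ds)/6`, the intersected thread cross-section `Ac`, and
#' the friction-geometry factor `Kf0`.
#'
#' The engagement offset `alpha` is the rotation consumed by the tapered tip
#' before full-profile thread is being formed; the model's friction term is
#' proportional to `phi - alpha/2`. Because the offset is not directly
#' measurable it is governed by a policy:
#' * `"from-taper-geometry"` (default): `alpha = 2 pi Ltaper / p` with
#'   `Ltaper = (Ds - Dh) / (2 tan theta_t)`, i.e. the rotation needed for
#'   the taper to open the hole from Dh to Ds.
#' * `"explicit-value"`: take `alpha` from the `alpha` argument or the
#'   geometry's `alpha` field.
#'
#' @param geom A [screw_geometry()].
#' @param alpha_policy `"from-taper-geometry"` or `"explicit-value"`.
#' @param alpha Explicit offset (rad), used by the `"explicit-value"` policy;
#'   overrides `geom$alpha`.
#' @return Object of class `insertion_coefficients`: list with `theta`,
#'   `rf`, `rs`, `Kf0`, `Ac`, `G1`, `G2`, `alpha`, `alpha_policy`.
#' @examples
#' co <- insertion_coefficients(screw_geometry())
#' co$G1; co$G2
#' @export
insertion_coefficients <- function(geom,
                                   alpha_policy = c("from-taper-geometry",
                                                    "explicit-value"),
                                   alpha = NULL) {
  validate_geometry(geom)
  alpha_policy <- match.arg(alpha_policy)
  Dh <- geom$hole_diameter
  Ds <- geom$major_diameter
  p <- geom$pitch
  beta <- geom$half_angle

  theta <- atan(p / (pi * Ds))
  rf <- (Dh + Ds) / 4
  rs <- (2 * Dh + 2 * Ds) / 6
  Kf0 <- 0.5 * (Ds - Dh) * (1 + tan(beta)^2) *
    sqrt(((Ds + Dh) / 4)^2 + (p / (2 * pi))^2)
  Ac <- tan(beta) * ((Ds - Dh) / 2)^2
  G1 <- rs * Ac / cos(theta)
  G2 <- 2 * rf * Kf0 / cos(theta)

  alpha_val <- switch(
    alpha_policy,
    "from-taper-geometry" = {
      l_taper <- (Ds - Dh) / (2 * tan(geom$end_taper))
      2 * pi * l_taper / p
    },
    "explicit-value" = {
      a <- if (!is.null(alpha)) alpha else geom$alpha
      if (is.null(a)) {
        stop("alpha_policy = \"explicit-value\" requires an `alpha` ",
             "argument or an `alpha` field in the geometry", call. = FALSE)
      }
      a
    }
  )

  out <- structure(
    list(theta = theta, rf = rf, rs = rs, Kf0 = Kf0, Ac = Ac,
         G1 = G1, G2 = G2, alpha = alpha_val, alpha_policy = alpha_policy),
    class = "insertion_coefficients"
  )
  stopifnot(theta > 0, theta < pi / 2, rf > 0, rs > 0, Kf0 > 0, Ac > 0,
            G1 > 0, G2 > 0, alpha_val >= 0)
  out
}

#' @export
print.insertion_coefficients <- function(x, ...) {
  cat("<insertion_coefficients>\n")
  cat(sprintf("  theta %.5f rad  rf %.4f mm  rs %.4f mm\n",
              x$theta, x$rf, x$rs))
  cat(sprintf("  Kf0 %.4f mm^2  Ac %.4f mm^2\n", x$Kf0, x$Ac))
  cat(sprintf("  G1 %.4f mm^3  G2 %.4f mm^3  alpha %.4f rad (%s)\n",
              x$G1, x$G2, x$alpha, x$alpha_policy))
  invisible(x)
}

#' Coefficients of the thread-stripping model
#'
#' Derives the quantities entering the stripping-torque prediction: the
#' shear-stress angle on the cylindrical failure envelope
#' `theta_tau = atan2(p, pi Ds) + atan2(1, -mu_T)` (second quadrant for any
#' positive thread friction), the envelope area `A_C = pi Ds L`, the
#' normalized tip-sharpness ratio `gamma = (Dshaft - Dminor)/p`, and the
#' stress concentration factor
#' `kt = 1 + (1 + 1.5 tanh(0.3 ln gamma + 0.7)) gamma`.
#'
#' `kt` is only defined for `gamma > 0`. The default HB 6.5 geometry has a
#' shank slightly narrower than the thread root (`gamma < 0`), so `kt` is
#' returned as `NA` and flagged; downstream consumers must then either skip
#' the concentration correction or supply a value explicitly. This is a
#' reportable state, not an error.
#'
#' @param geom A [screw_geometry()].
#' @return Object of class `stripping_coefficients`: list with `theta_tau`
#'   (rad), `A_C` (mm^2), `gamma`, `kt` (`NA_real_` when undefined) and
#'   `kt_defined` (logical).
#' @examples
#' stripping_coefficients(screw_geometry())
#' @export
stripping_coefficients <- function(geom) {
  validate_geometry(geom)
  p <- geom$pitch
  Ds <- geom$major_diameter
  theta_tau <- atan2(p, pi * Ds) + atan2(1, -geom$mu_thread)
  A_C <- pi * Ds * geom$thread_length
  gamma <- (geom$shank_diameter - geom$minor_diameter) / p
  kt <- if (gamma > 0) {
    1 + (1 + 1.5 * tanh(0.3 * log(gamma) + 0.7)) * gamma
  } else {
    NA_real_
  }
  structure(
    list(theta_tau = theta_tau, A_C = A_C, gamma = gamma, kt = kt,
         kt_defined = is.finite(kt)),
    class = "stripping_coefficients"
  )
}

#' @export
print.stripping_coefficients <- function(x, ...) {
  cat("<stripping_coefficients>\n")
  cat(sprintf("  theta_tau %.5f rad (%.2f deg)  A_C %.2f mm^2\n",
              x$theta_tau, x$theta_tau * 180 / pi, x$A_C))
  cat(sprintf("  gamma %.4f  kt %s\n", x$gamma,
              if (x$kt_defined) sprintf("%.4f", x$kt) else
                "undefined (gamma <= 0)"))
  invisible(x)
}

# Config keys accepted in geometry YAML/JSON files, in boundary units.
geometry_config_keys <- c(
  "hole_diameter_mm", "major_diameter_mm", "shank_diameter_mm",
  "head_diameter_mm", "minor_diameter_mm", "half_angle_deg", "pitch_mm",
  "thread_length_mm", "mu_thread", "mu_head", "end_taper_deg"
)

#' Read a screw-geometry config file
#'
#' Reads a YAML or JSON file (decided by extension) holding the geometry in
#' boundary units: millimetres for lengths, degrees for the thread half
#' angle and end taper. Required keys are `hole_diameter_mm,
#' major_diameter_mm, shank_diameter_mm, head_diameter_mm,
#' minor_diameter_mm, half_angle_deg, pitch_mm, thread_length_mm, mu_thread,
#' mu_head, end_taper_deg`; `alpha_rad` is optional. A bundled example is
#' `system.file("extdata", "hb65_geometry.yaml", package = "screwstrip")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [screw_geometry()].
#' @export
read_geometry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    "yaml" = ,
    "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported geometry config extension: `.", ext,
         "` (use .yaml/.yml/.json)", call. = FALSE)
  )
  missing <- setdiff(geometry_config_keys, names(cfg))
  if (length(missing) > 0) {
    stop("geometry config ", path, " is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(cfg), c(geometry_config_keys, "alpha_rad"))
  if (length(unknown) > 0) {
    warning("geometry config has unrecognized key(s), ignored: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  screw_geometry(
    hole_diameter = cfg$hole_diameter_mm,
    major_diameter = cfg$major_diameter_mm,
    shank_diameter = cfg$shank_diameter_mm,
    head_diameter = cfg$head_diameter_mm,
    minor_diameter = cfg$minor_diameter_mm,
    half_angle_deg = cfg$half_angle_deg,
    pitch = cfg$pitch_mm,
    thread_length = cfg$thread_length_mm,
    mu_thread = cfg$mu_thread,
    mu_head = cfg$mu_head,
    end_taper_deg = cfg$end_taper_deg,
    alpha = cfg$alpha_rad
  )
}
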