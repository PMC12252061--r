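#' Material specification for the simulator
#'
#' @param name Material label.
#' @param sigma_ucs Nominal ultimate compressive strength (MPa, > 0).
#' @param ductility_weight Brittleness weight `d` in `[0, 1]` controlling
#'   where the programmed stripping torque falls between the two model
#'   bounds: `tau* = tau_fail_no_kt / kt^d` (0 = fully ductile, no
#'   concentration; 1 = fully brittle, full concentration).
#' @param strength_cv Relative standard deviation of lot-to-lot strength
#'   variation (lognormal, mean-preserving; default 5%).
#' @return One-row tibble.
#' @export
material_spec <- function(name, sigma_ucs, ductility_weight = 0,
                          strength_cv = 0.05) {
  stopifnot(sigma_ucs > 0, ductility_weight >= 0, ductility_weight <= 1,
            strength_cv >= 0)
  tibble::tibble(name = as.character(name), sigma_ucs = sigma_ucs,
                 ductility_weight = ductility_weight,
                 strength_cv = strength_cv)
}

#' Default simulated material cohort
#'
#' Eight rigid polyurethane foam grades spanning the strength range of
#' cancellous bone, with nominal strengths at the data-sheet values
#' (midpoints of printed ranges): M80 0.8, M150 1.6, M330 4, M450 10,
#' M600 17, 15 PCF 3, 20 PCF 10 and 30 PCF 12.5 MPa. All default to fully
#' ductile behaviour (`ductility_weight = 0`), consistent with foam sitting
#' near the no-concentration prediction, and 5% lot-to-lot strength CV.
#'
#' @return Tibble with 8 rows (columns as [material_spec()]).
#' @export
default_materials <- function() {
  dplyr::bind_rows(
    material_spec("M80", 0.8),
    material_spec("M150", 1.6),
    material_spec("M330", 4),
    material_spec("M450", 10),
    material_spec("M600", 17),
    material_spec("15PCF", 3),
    material_spec("20PCF", 10),
    material_spec("30PCF", 12.5)
  )
}

#' Test-rig specification for the simulator
#'
#' Emulates a motorized insertion bench: constant-speed insertion at
#' `rpm` until the threads strip, a +/-5 N m torque sensor with 0.5%
#' accuracy (Gaussian noise, SD 25 N mm), a 360 CPR quadrature encoder
#' (0.25 degree steps) and a 0.025 mm draw-wire encoder, sampled at 1 kHz.
#' Phase durations are expressed in screw revolutions. `tightening_
#' revolutions` and the stripping decay shape are simulator choices, with
#' defaults that put the final-insertion-to-stripping torque ratio near the
#' 0.2--0.5 band seen on real foam benches.
#'
#' @param rpm Insertion speed (rev/min).
#' @param sample_rate Sampling rate (Hz).
#' @param torque_noise_sd Torque sensor noise SD (N mm); 25 = 0.5% of a
#'   5 N m range. Set 0 for an ideal sensor.
#' @param encoder_resolution_deg Rotation quantization step (degrees);
#'   0 disables quantization.
#' @param drawwire_resolution_mm Position quantization step (mm); 0
#'   disables quantization.
#' @param engagement_revolutions Revolutions of the engagement phase, during
#'   which the screw slips axially (advance ramps from zero to full pitch
#'   per revolution after an initial bite delay).
#' @param insertion_revolutions Revolutions of steady insertion.
#' @param tightening_revolutions Revolutions over which torque ramps from
#'   the final insertion value to the stripping peak once the head seats.
#' @param peak_hold_s Seconds the stripping plateau holds at the peak.
#' @param decay_revolutions Revolutions of post-stripping torque decay.
#' @param plateau_fraction Fraction of the peak that the decayed,
#'   fully-stripped torque approaches.
#' @param settle_s Seconds of pre-motion recording.
#' @param bite_fraction Fraction of the engagement phase before the tip
#'   bites and axial advance begins.
#' @return List of class `rig_spec`.
#' @export
rig_spec <- function(rpm = 30, sample_rate = 1000, torque_noise_sd = 25,
                     encoder_resolution_deg = 0.25,
                     drawwire_resolution_mm = 0.025,
                     engagement_revolutions = 2, insertion_revolutions = 10,
                     tightening_revolutions = 0.5, peak_hold_s = 0.05,
                     decay_revolutions = 2, plateau_fraction = 0.3,
                     settle_s = 0.5, bite_fraction = 0.1) {
  rig <- structure(
    list(rpm = rpm, sample_rate = sample_rate,
         torque_noise_sd = torque_noise_sd,
         encoder_resolution_deg = encoder_resolution_deg,
         drawwire_resolution_mm = drawwire_resolution_mm,
         engagement_revolutions = engagement_revolutions,
         insertion_revolutions = insertion_revolutions,
         tightening_revolutions = tightening_revolutions,
         peak_hold_s = peak_hold_s, decay_revolutions = decay_revolutions,
         plateau_fraction = plateau_fraction, settle_s = settle_s,
         bite_fraction = bite_fraction),
    class = "rig_spec"
  )
  with(rig, stopifnot(
    rpm > 0, sample_rate > 0, torque_noise_sd >= 0,
    encoder_resolution_deg >= 0, drawwire_resolution_mm >= 0,
    engagement_revolutions > 0, insertion_revolutions > 0,
    tightening_revolutions > 0, peak_hold_s > 0, decay_revolutions > 0,
    plateau_fraction > 0, plateau_fraction < 1, settle_s >= 0,
    bite_fraction >= 0, bite_fraction < 1
  ))
  rig
}

quantize <- function(x, step) {
  if (step <= 0) return(x)
  round(x / step) * step
}

# Mean-preserving lognormal multiplier with relative SD cv.
lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate a single screw-insertion recording
#'
#' Generates a physically plausible torque/rotation/position recording with
#' known ground truth. The trace follows the canonical phase structure of a
#' strip-to-failure test: settle (no motion), engagement (rotation advances
#' at full speed while axial advance slips, torque ramping up to the model
#' value), insertion (torque follows the insertion model exactly at the
#' drawn true strength), tightening (linear torque rise once the head
#' seats), and stripping (peak at the programmed stripping torque, short
#' hold, then decay towards a residual plateau). Sensor quantization and
#' Gaussian torque noise are applied last, so regenerating with an ideal
#' rig recovers the model exactly. Fully reproducible from `seed`.
#'
#' The true strength is drawn as `sigma_ucs * lognormal(strength_cv)`; the
#' programmed stripping torque is `tau_fail_no_kt(sigma_true) / kt^d` times
#' an independent lognormal factor with the same CV. When `d > 0` a defined
#' (or explicitly supplied) stress concentration factor is required.
#'
#' @param material One-row tibble or list as from [material_spec()].
#' @param geom A [screw_geometry()].
#' @param rig A [rig_spec()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param kt_value Optional explicit stress concentration factor used for
#'   the ductility interpolation when the geometric one is undefined.
#' @return List with `trace` (a [torque_trace()]) and `truth`, a list with
#'   `sigma_ucs_true` (MPa), `tau_strip_true` (N mm), `onset_time` and
#'   `strip_time` (s, absolute trace time), `seed`, and
#'   `sensor_range_exceeded` (TRUE when the programmed peak exceeds the
#'   5 N m sensor range; the trace itself is not clipped).
#' @export
simulate_insertion_trace <- function(material, geom = screw_geometry(),
                                     rig = rig_spec(), seed = NULL,
                                     kt_value = NULL) {
  stopifnot(inherits(rig, "rig_spec"))
  validate_geometry(geom)
  mat <- as.list(material)
  stopifnot(mat$sigma_ucs > 0,
            mat$ductility_weight >= 0, mat$ductility_weight <= 1,
            mat$strength_cv >= 0)
  if (!is.null(seed)) set.seed(seed)

  ico <- insertion_coefficients(geom)
  sco <- stripping_coefficients(geom)
  fs <- rig$sample_rate
  omega <- 2 * pi * rig$rpm / 60          # rad/s
  rev_s <- 60 / rig$rpm                   # s per revolution
  p <- geom$pitch

  sigma_true <- mat$sigma_ucs * lognormal_factor(1, mat$strength_cv)
  tau_no_kt <- predict_stripping_torque(sigma_true, geom, sco)$tau_no_kt
  d <- mat$ductility_weight
  kt_eff <- 1
  if (d > 0) {
    kt_eff <- if (!is.null(kt_value)) kt_value else if (sco$kt_defined) {
      sco$kt
    } else {
      stop("material has ductility_weight > 0 but the geometric kt is ",
           "undefined (gamma <= 0); supply kt_value", call. = FALSE)
    }
  }
  tau_strip <- tau_no_kt / kt_eff^d * lognormal_factor(1, mat$strength_cv)

  # phase boundaries (s)
  t0 <- rig$settle_s
  t_bite <- t0 + rig$bite_fraction * rig$engagement_revolutions * rev_s
  t_eng <- t0 + rig$engagement_revolutions * rev_s
  t_ins <- t_eng + rig$insertion_revolutions * rev_s
  t_tight <- t_ins + rig$tightening_revolutions * rev_s
  t_hold <- t_tight + rig$peak_hold_s
  t_end <- t_hold + rig$decay_revolutions * rev_s

  n <- floor(t_end * fs) + 1L
  time <- (seq_len(n) - 1L) / fs

  rotation <- pmax(0, time - t0) * omega

  # axial advance: zero until the tip bites, then the per-revolution advance
  # fraction ramps linearly to 1 over the rest of engagement
  ramp_len <- t_eng - t_bite
  z <- numeric(n)
  in_ramp <- time > t_bite & time <= t_eng
  z[in_ramp] <- (p * omega / (2 * pi)) *
    (time[in_ramp] - t_bite)^2 / (2 * ramp_len)
  z_eng <- (p * omega / (2 * pi)) * ramp_len / 2
  after <- time > t_eng
  z[after] <- z_eng + (p * omega / (2 * pi)) *
    (pmin(time[after], t_ins) - t_eng)
  phi_eq <- 2 * pi * z / p

  model_tau <- predict_insertion_torque(phi_eq, sigma_true, ico,
                                        geom$mu_thread)
  torque <- numeric(n)
  eng <- time > t_bite & time <= t_eng
  u <- (time[eng] - t_bite) / ramp_len
  torque[eng] <- u * model_tau[eng]
  ins <- time > t_eng & time <= t_ins
  torque[ins] <- model_tau[ins]
  tau_ins_end <- predict_insertion_torque(2 * pi * max(z) / p, sigma_true,
                                          ico, geom$mu_thread)
  tight <- time > t_ins & time <= t_tight
  torque[tight] <- tau_ins_end +
    (tau_strip - tau_ins_end) * (time[tight] - t_ins) /
      (t_tight - t_ins)
  hold <- time > t_tight & time <= t_hold
  torque[hold] <- tau_strip
  decay <- time > t_hold
  torque[decay] <- tau_strip * (rig$plateau_fraction +
    (1 - rig$plateau_fraction) *
      exp(-3 * (time[decay] - t_hold) / (t_end - t_hold)))

  rotation_m <- quantize(rotation, rig$encoder_resolution_deg * pi / 180)
  position_m <- quantize(z, rig$drawwire_resolution_mm)
  torque_m <- torque
  if (rig$torque_noise_sd > 0) {
    torque_m <- torque_m + stats::rnorm(n, 0, rig$torque_noise_sd)
  }

  list(
    trace = torque_trace(time, torque_m, rotation_m, position_m),
    truth = list(
      sigma_ucs_true = sigma_true,
      tau_strip_true = tau_strip,
      onset_time = t_ins,
      strip_time = t_tight,
      seed = seed,
      sensor_range_exceeded = tau_strip > 5000
    )
  )
}

#' Simulate a cohort of insertions
#'
#' Runs [simulate_insertion_trace()] `n_per_material` times per material
#' with independent per-trace seeds derived from a master seed.
#'
#' @param materials Tibble of materials ([default_materials()] by default).
#' @param n_per_material Insertions per material (default 10).
#' @param geom,rig,kt_value Passed to [simulate_insertion_trace()].
#' @param seed Master seed for the per-trace seed draw.
#' @return Tibble with one row per insertion: `material`, `rep`, `seed`,
#'   unnested ground-truth columns, and a `trace` list-column of
#'   [torque_trace()] objects.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(n_per_material = 2, seed = 1)
#' nrow(cohort)   # 16
#' }
#' @export
simulate_cohort <- function(materials = default_materials(),
                            n_per_material = 10, geom = screw_geometry(),
                            rig = rig_spec(), seed = NULL, kt_value = NULL) {
  stopifnot(n_per_material >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_total <- nrow(materials) * n_per_material
  trace_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  grid <- tidyr::expand_grid(
    material_row = seq_len(nrow(materials)),
    rep = seq_len(n_per_material)
  )
  grid$seed <- trace_seeds
  purrr::pmap_dfr(grid, function(material_row, rep, seed) {
    mat <- materials[material_row, ]
    sim <- simulate_insertion_trace(mat, geom, rig, seed = seed,
                                    kt_value = kt_value)
    tibble::tibble(
      material = mat$name,
      rep = rep,
      seed = seed,
      sigma_ucs_nominal = mat$sigma_ucs,
      sigma_ucs_true = sim$truth$sigma_ucs_true,
      tau_strip_true = sim$truth$tau_strip_true,
      onset_time = sim$truth$onset_time,
      strip_time = sim$truth$strip_time,
      sensor_range_exceeded = sim$truth$sensor_range_exceeded,
      trace = list(sim$trace)
    )
  })
}
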