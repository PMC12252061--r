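#' Read a trace CSV in rig-native units
#'
#' Trace files store what the bench writes: header exactly
#' `time_s,torque_Nm,rotation_deg,position_mm`, numeric rows, uniform
#' sampling. On read, torque is converted to N mm and rotation to radians
#' (the single unit-conversion boundary of the package); monotone and
#' uniform (1 ppm) sampling are validated with the offending row number in
#' the error.
#'
#' @param path CSV file path.
#' @return A [torque_trace()] in internal units.
#' @export
read_trace_csv <- function(path) {
  header <- readLines(path, n = 1L)
  expected <- "time_s,torque_Nm,rotation_deg,position_mm"
  if (!identical(trimws(header), expected)) {
    stop("trace CSV ", path, " has header `", header,
         "`; expected `", expected, "`", call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(),
    torque_Nm = readr::col_double(),
    rotation_deg = readr::col_double(),
    position_mm = readr::col_double()
  ))
  if (anyNA(raw)) {
    stop("trace CSV ", path, " has non-numeric or missing values at row ",
         which(!stats::complete.cases(raw))[1], call. = FALSE)
  }
  torque_trace(
    time = raw$time_s,
    torque = raw$torque_Nm * 1000,
    rotation = raw$rotation_deg * pi / 180,
    position = raw$position_mm
  )
}

#' Write a trace CSV in rig-native units
#'
#' Inverse of [read_trace_csv()]: converts internal units (N mm, rad) back
#' to N m and degrees and writes with shortest-round-trip precision, so a
#' write/read cycle reproduces the trace to floating-point accuracy.
#'
#' @param trace A [torque_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  validate_trace(trace)
  out <- tibble::tibble(
    time_s = trace$time,
    torque_Nm = trace$torque / 1000,
    rotation_deg = trace$rotation * 180 / pi,
    position_mm = trace$position
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write/read a ground-truth sidecar JSON for a simulated trace
#'
#' @param truth Truth list from [simulate_insertion_trace()].
#' @param path JSON path.
#' @return `path` (write) or the truth list (read).
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(sigma_ucs_true = truth$sigma_ucs_true,
         tau_strip_true_Nmm = truth$tau_strip_true,
         onset_time_s = truth$onset_time,
         strip_time_s = truth$strip_time,
         seed = truth$seed,
         sensor_range_exceeded = truth$sensor_range_exceeded),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Processing parameters for the pipeline
#'
#' Collects the tunable pre-processing and prediction parameters with the
#' bench defaults: 1 degree crop thresholds, 1 s torque smoothing, onset
#' threshold at 6 times the 90th percentile of the smoothed-torque
#' derivative, 0.03 s median window for the stripping peak, 2 revolutions of
#' engagement blanking, equivalent rotation from the draw-wire position, and
#' no stress-concentration correction.
#'
#' @param start_threshold_deg,end_threshold_deg Crop thresholds (degrees).
#' @param ma_window_s Torque smoothing window (s).
#' @param deriv_multiplier,deriv_percentile Onset threshold parameters.
#' @param median_window_s Stripping-peak median window (s).
#' @param blanking_revolutions Engagement blanking (revolutions).
#' @param use_position Use draw-wire-derived equivalent rotation for the
#'   strength fit (recommended); `FALSE` uses raw encoder rotation.
#' @param kt_mode,kt_value Stress-concentration handling, see
#'   [predict_stripping_torque()].
#' @param alpha_policy,alpha Engagement-offset policy, see
#'   [insertion_coefficients()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(start_threshold_deg = 1, end_threshold_deg = 1,
                            ma_window_s = 1.0, deriv_multiplier = 6,
                            deriv_percentile = 90, median_window_s = 0.03,
                            blanking_revolutions = 2, use_position = TRUE,
                            kt_mode = "none", kt_value = NULL,
                            alpha_policy = "from-taper-geometry",
                            alpha = NULL) {
  stopifnot(start_threshold_deg > 0, end_threshold_deg > 0,
            ma_window_s > 0, deriv_multiplier > 0, deriv_percentile > 0,
            deriv_percentile < 100, median_window_s > 0,
            blanking_revolutions >= 0, is.logical(use_position))
  kt_mode <- match.arg(kt_mode, c("none", "full", "value"))
  structure(
    list(start_threshold_deg = start_threshold_deg,
         end_threshold_deg = end_threshold_deg,
         ma_window_s = ma_window_s, deriv_multiplier = deriv_multiplier,
         deriv_percentile = deriv_percentile,
         median_window_s = median_window_s,
         blanking_revolutions = blanking_revolutions,
         use_position = use_position, kt_mode = kt_mode,
         kt_value = kt_value, alpha_policy = alpha_policy, alpha = alpha),
    class = "pipeline_config"
  )
}

#' Process a single insertion recording
#'
#' Runs the full per-trace chain: crop and segment the recording, derive
#' the equivalent rotation from the draw-wire position, identify the
#' material strength on the insertion segment, predict the stripping torque
#' (both concentration bounds), and measure the empirical stripping torque
#' from the whole recording.
#'
#' @param trace A [torque_trace()].
#' @param geom A [screw_geometry()].
#' @param config A [pipeline_config()].
#' @return One-row tibble: `sigma_hat`, `tau_pred` (per `kt_mode`),
#'   `tau_pred_no_kt`, `tau_pred_kt`, `kt_used`, `tau_true`, `onset_time`,
#'   `strip_time`, `n_fit`, `sse`, `fit_negative`.
#' @export
process_trace <- function(trace, geom = screw_geometry(),
                          config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  ico <- insertion_coefficients(geom, alpha_policy = config$alpha_policy,
                                alpha = config$alpha)
  sco <- stripping_coefficients(geom)
  seg <- segment_trace(
    trace,
    start_threshold = config$start_threshold_deg * pi / 180,
    end_threshold = config$end_threshold_deg * pi / 180,
    ma_window_s = config$ma_window_s,
    multiplier = config$deriv_multiplier,
    percentile = config$deriv_percentile,
    blanking_revolutions = config$blanking_revolutions,
    median_window_s = config$median_window_s
  )
  ct <- seg$trace
  b <- seg$bounds
  phi <- if (config$use_position) {
    position_to_rotation(ct$position, geom$pitch)
  } else {
    ct$rotation - ct$rotation[1]
  }
  if (b$blank_idx >= b$tightening_idx) {
    stop("insertion segment is empty: tightening onset detected before the ",
         "end of the engagement blanking period", call. = FALSE)
  }
  fit_rows <- (b$blank_idx - b$start_idx + 1L):(b$tightening_idx -
                                                  b$start_idx)
  fit <- identify_strength(phi[fit_rows], ct$torque[fit_rows], ico,
                           geom$mu_thread)
  pred <- predict_stripping_torque(max(fit$sigma_ucs, 0), geom, sco,
                                   kt_mode = config$kt_mode,
                                   kt_value = config$kt_value)
  strip <- measure_stripping_torque(ct, config$median_window_s)
  tibble::tibble(
    sigma_hat = fit$sigma_ucs,
    tau_pred = pred$tau_pred,
    tau_pred_no_kt = pred$tau_no_kt,
    tau_pred_kt = pred$tau_kt,
    kt_used = pred$kt_used,
    tau_true = strip$torque,
    onset_time = ct$time[b$tightening_idx - b$start_idx + 1L],
    strip_time = ct$time[strip$index],
    n_fit = fit$n_samples,
    sse = fit$sse,
    fit_negative = fit$negative
  )
}

#' Run the pipeline over a batch of trace files
#'
#' Reads each CSV, processes it with [process_trace()], and summarizes the
#' cohort with [analyze_cohort()]. Per-trace failures are logged to stderr
#' and collected; they do not abort the batch. Deterministic given inputs
#' and config.
#'
#' @param paths Character vector of trace CSV paths (>= 1).
#' @param geom A [screw_geometry()].
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-trace progress messages.
#' @return A `cohort_analysis` (see [analyze_cohort()]) whose `records`
#'   carry a `path` column; failed paths and their error messages are in
#'   `attr(result, "failures")`.
#' @export
run_pipeline <- function(paths, geom = screw_geometry(),
                         config = pipeline_config(), quiet = FALSE) {
  if (length(paths) == 0L) {
    stop("run_pipeline needs at least one trace path", call. = FALSE)
  }
  failures <- list()
  records <- purrr::map_dfr(paths, function(p) {
    rec <- tryCatch({
      tr <- read_trace_csv(p)
      out <- process_trace(tr, geom, config)
      out$path <- p
      if (!quiet) message("processed ", p)
      out
    }, error = function(e) {
      failures[[p]] <<- conditionMessage(e)
      message("FAILED ", p, ": ", conditionMessage(e))
      NULL
    })
    rec
  })
  if (nrow(records) == 0L) {
    stop("all traces failed to process", call. = FALSE)
  }
  res <- analyze_cohort(records)
  attr(res, "failures") <- failures
  res
}

#' Process a simulated cohort in memory
#'
#' Applies [process_trace()] to every trace of a [simulate_cohort()] tibble
#' and joins the ground truth, giving the records that [analyze_cohort()]
#' consumes (with `sigma_ref` set to the nominal data-sheet strength).
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param geom,config As in [process_trace()].
#' @return Records tibble: simulation metadata + per-trace pipeline output.
#' @export
process_cohort <- function(cohort, geom = screw_geometry(),
                           config = pipeline_config()) {
  out <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    rec <- process_trace(cohort$trace[[i]], geom, config)
    rec$material <- cohort$material[i]
    rec$rep <- cohort$rep[i]
    rec$sigma_ref <- cohort$sigma_ucs_nominal[i]
    rec$sigma_true <- cohort$sigma_ucs_true[i]
    rec$tau_strip_truth <- cohort$tau_strip_true[i]
    rec$onset_time_truth <- cohort$onset_time[i]
    rec
  })
  dplyr::relocate(out, "material", "rep")
}

#' Write a cohort summary JSON with provenance
#'
#' @param analysis A `cohort_analysis` from [analyze_cohort()].
#' @param path Output JSON path.
#' @param config Optional [pipeline_config()] embedded for provenance.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(analysis, path, config = NULL) {
  payload <- list(
    summary = as.list(analysis$summary),
    package_version = as.character(utils::packageVersion("screwstrip")),
    config = if (!is.null(config)) unclass(config) else NULL,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
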