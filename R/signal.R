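#' Torque-trace container
#'
#' A torque trace is a tibble with columns `time` (s, strictly increasing
#' and uniform), `torque` (N mm), `rotation` (rad) and `position` (mm),
#' carrying class `torque_trace`. Internal units are used throughout; the
#' CSV reader/writer ([read_trace_csv()]) converts to and from rig-native
#' units at the boundary.
#'
#' @param time,torque,rotation,position Equal-length numeric vectors
#'   (length >= 2).
#' @return A `torque_trace` tibble.
#' @export
torque_trace <- function(time, torque, rotation, position) {
  trace <- tibble::tibble(time = as.numeric(time),
                          torque = as.numeric(torque),
                          rotation = as.numeric(rotation),
                          position = as.numeric(position))
  class(trace) <- c("torque_trace", class(trace))
  validate_trace(trace)
  trace
}

validate_trace <- function(trace) {
  need <- c("time", "torque", "rotation", "position")
  missing <- setdiff(need, names(trace))
  if (length(missing) > 0) {
    stop("trace is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(trace)
  if (n < 2L) stop("trace must have at least 2 samples", call. = FALSE)
  dt <- diff(trace$time)
  bad <- which(dt <= 0)
  if (length(bad) > 0) {
    stop("trace time is not strictly increasing at row ", bad[1] + 1L,
         call. = FALSE)
  }
  dt_ref <- stats::median(dt)
  off <- which(abs(dt - dt_ref) > 1e-6 * dt_ref)
  if (length(off) > 0) {
    stop("trace sampling is non-uniform beyond 1 ppm at row ", off[1] + 1L,
         call. = FALSE)
  }
  invisible(trace)
}

#' Sample rate of a trace
#'
#' @param trace A [torque_trace()].
#' @return Sampling frequency in Hz (1 / median time step).
#' @export
trace_sample_rate <- function(trace) {
  1 / stats::median(diff(trace$time))
}

#' Centred moving-average filter with shrinking edges
#'
#' Centred moving mean over an odd window. Near the edges the window shrinks
#' symmetrically to what fits inside the signal, so no padding values are
#' invented: the first and last samples are averaged over progressively
#' smaller neighbourhoods (down to the sample itself). An even `window` is
#' incremented to the next odd value.
#'
#' @param x Numeric vector.
#' @param window Window length in samples (>= 1, <= `length(x)`).
#' @return Filtered vector, same length as `x`.
#' @examples
#' moving_average(c(0, 0, 3, 0, 0), 3)   # 0 1 1 1 0
#' @export
moving_average <- function(x, window) {
  stopifnot(is.numeric(x), length(window) == 1L, window >= 1)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  n <- length(x)
  if (window > n) {
    stop("moving_average window (", window, ") exceeds signal length (",
         n, ")", call. = FALSE)
  }
  if (window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Centred median filter with shrinking edges
#'
#' Running median over an odd window (via [stats::runmed()] with
#' `endrule = "median"`, i.e. shrinking odd windows at both ends). Removes
#' isolated spikes shorter than half the window while leaving monotone ramps
#' untouched away from the edges.
#'
#' @inheritParams moving_average
#' @return Filtered vector, same length as `x`.
#' @export
median_filter <- function(x, window) {
  stopifnot(is.numeric(x), length(window) == 1L, window >= 1)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window > length(x)) {
    stop("median_filter window (", window, ") exceeds signal length (",
         length(x), ")", call. = FALSE)
  }
  if (window == 1L) return(x)
  as.numeric(stats::runmed(x, window, endrule = "median"))
}

#' Equivalent rotation from linear position
#'
#' During early thread engagement the screw slips, so encoder rotation
#' overstates the true advance. The draw-wire position is the reliable depth
#' signal; this converts it to the equivalent rotation via the pitch:
#' `phi_equiv = 2 pi (position - position[1]) / pitch`.
#'
#' @param position Linear position samples (mm).
#' @param pitch Thread pitch (mm per revolution, > 0).
#' @return Equivalent rotation (rad), zero at the first sample.
#' @examples
#' position_to_rotation(c(0, 2.75), 2.75)   # 0, 2*pi
#' @export
position_to_rotation <- function(position, pitch) {
  stopifnot(is.numeric(position), length(pitch) == 1L, pitch > 0)
  2 * pi * (position - position[1]) / pitch
}

#' Crop a recording to the active insertion
#'
#' Finds the start of the experiment (first sample strictly more than
#' `start_threshold` away from the initial rotation) and the end (first
#' sample whose rotation is within `end_threshold` of the maximum rotation,
#' i.e. where insertion rotation effectively stops). Both thresholds default
#' to 1 degree.
#'
#' @param trace A [torque_trace()].
#' @param start_threshold,end_threshold Thresholds in radians
#'   (default `pi/180`, i.e. 1 degree).
#' @return List with `trace` (the cropped `torque_trace`), `start_idx` and
#'   `end_idx` (row indices into the input trace).
#' @export
crop_recording <- function(trace, start_threshold = pi / 180,
                           end_threshold = pi / 180) {
  validate_trace(trace)
  stopifnot(start_threshold > 0, end_threshold > 0)
  rot <- trace$rotation
  moved <- which(abs(rot - rot[1]) > start_threshold)
  if (length(moved) == 0L) {
    stop("no motion: rotation never exceeds the start threshold",
         call. = FALSE)
  }
  start_idx <- moved[1]
  end_idx <- which(rot >= max(rot) - end_threshold)[1]
  if (end_idx <= start_idx) {
    stop("degenerate crop: end index precedes start index", call. = FALSE)
  }
  cropped <- trace[start_idx:end_idx, ]
  class(cropped) <- c("torque_trace", setdiff(class(cropped), "torque_trace"))
  list(trace = cropped, start_idx = start_idx, end_idx = end_idx)
}

#' Detect the onset of screw tightening
#'
#' The tightening point is where the screw head seats and torque begins to
#' rise much faster than during free insertion. The torque is smoothed with
#' a moving average (`ma_window_s`, default 1 s), numerically differentiated
#' by central differences (per-sample units; one-sided at the endpoints),
#' and the onset is the first sample -- after a blanking period of
#' `blanking_revolutions` of encoder rotation that skips engagement spikes
#' -- where the derivative exceeds `multiplier` times the `percentile`-th
#' percentile of the derivative over the whole cropped trace. Because the
#' threshold is relative, the detection is invariant to torque rescaling and
#' to the choice of per-sample versus per-second derivative units.
#'
#' @param trace A cropped [torque_trace()].
#' @param ma_window_s Smoothing window in seconds (default 1).
#' @param multiplier Threshold multiplier (default 6).
#' @param percentile Percentile of the derivative used as reference
#'   (default 90).
#' @param blanking_revolutions Encoder revolutions to skip after the start
#'   (default 2).
#' @return Row index of the detected onset within `trace`.
#' @export
detect_tightening_onset <- function(trace, ma_window_s = 1.0,
                                    multiplier = 6, percentile = 90,
                                    blanking_revolutions = 2) {
  validate_trace(trace)
  stopifnot(ma_window_s > 0, multiplier > 0,
            percentile > 0, percentile < 100, blanking_revolutions >= 0)
  fs <- trace_sample_rate(trace)
  w <- max(1L, round(ma_window_s * fs))
  smooth <- moving_average(trace$torque, w)
  n <- length(smooth)
  d <- numeric(n)
  d[2:(n - 1)] <- (smooth[3:n] - smooth[1:(n - 2)]) / 2
  d[1] <- smooth[2] - smooth[1]
  d[n] <- smooth[n] - smooth[n - 1]
  threshold <- multiplier *
    stats::quantile(d, percentile / 100, names = FALSE)
  blank_end <- which(trace$rotation - trace$rotation[1] >
                       blanking_revolutions * 2 * pi)[1]
  if (is.na(blank_end)) blank_end <- 1L
  hits <- which(d > threshold)
  hits <- hits[hits > blank_end]
  if (length(hits) == 0L) {
    stop("no tightening detected: smoothed torque derivative never exceeds ",
         multiplier, "x its P", percentile, call. = FALSE)
  }
  hits[1]
}

#' Measure the empirical stripping torque
#'
#' The true stripping torque of a test is the maximum of the median-filtered
#' torque (default window 0.03 s, i.e. 30 samples at 1 kHz); the median
#' filter suppresses single-sample sensor spikes that would otherwise be
#' mistaken for the peak.
#'
#' @param trace A [torque_trace()].
#' @param median_window_s Median-filter window in seconds (default 0.03).
#' @return List with `torque` (N mm) and `index` (argmax row in `trace`).
#' @export
measure_stripping_torque <- function(trace, median_window_s = 0.03) {
  validate_trace(trace)
  stopifnot(median_window_s > 0)
  fs <- trace_sample_rate(trace)
  w <- max(1L, round(median_window_s * fs))
  filt <- median_filter(trace$torque, w)
  idx <- which.max(filt)
  list(torque = filt[idx], index = idx)
}

#' Segment a recording into insertion phases
#'
#' Composes [crop_recording()], [detect_tightening_onset()] and
#' [measure_stripping_torque()] into the four-phase segmentation of a
#' recording: engagement (narrow, from the crop start), insertion, tightening
#' and stripping. The insertion segment used for strength identification runs
#' from the end of the engagement blanking period to the tightening onset.
#'
#' @inheritParams detect_tightening_onset
#' @param start_threshold,end_threshold Crop thresholds (rad, default 1
#'   degree).
#' @param median_window_s Median window for the stripping-peak search (s).
#' @return List with `trace` (cropped `torque_trace`) and `bounds`, a
#'   one-row tibble of indices into the *input* trace:
#'   `start_idx < tightening_idx <= stripping_idx <= end_idx`, plus
#'   `blank_idx` (end of the engagement blanking, start of the usable
#'   insertion segment). Ordering is validated and violations raise.
#' @export
segment_trace <- function(trace, start_threshold = pi / 180,
                          end_threshold = pi / 180, ma_window_s = 1.0,
                          multiplier = 6, percentile = 90,
                          blanking_revolutions = 2, median_window_s = 0.03) {
  cr <- crop_recording(trace, start_threshold, end_threshold)
  ct <- cr$trace
  onset_rel <- detect_tightening_onset(ct, ma_window_s, multiplier,
                                       percentile, blanking_revolutions)
  strip <- measure_stripping_torque(ct, median_window_s)
  strip_rel <- max(strip$index, onset_rel)
  blank_rel <- which(ct$rotation - ct$rotation[1] >
                       blanking_revolutions * 2 * pi)[1]
  if (is.na(blank_rel)) blank_rel <- 1L
  bounds <- tibble::tibble(
    start_idx = cr$start_idx,
    blank_idx = cr$start_idx + blank_rel - 1L,
    tightening_idx = cr$start_idx + onset_rel - 1L,
    stripping_idx = cr$start_idx + strip_rel - 1L,
    end_idx = cr$end_idx
  )
  if (!(bounds$start_idx < bounds$tightening_idx &&
        bounds$tightening_idx <= bounds$stripping_idx &&
        bounds$stripping_idx <= bounds$end_idx)) {
    stop("segmentation produced inconsistent bounds (start ",
         bounds$start_idx, ", tightening ", bounds$tightening_idx,
         ", stripping ", bounds$stripping_idx, ", end ", bounds$end_idx, ")",
         call. = FALSE)
  }
  list(trace = ct, bounds = bounds)
}
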