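flat_trace <- function(torque, rotation, position = NULL, fs = 1000) {
  n <- length(torque)
  if (is.null(position)) position <- numeric(n)
  torque_trace((seq_len(n) - 1) / fs, torque, rotation, position)
}

test_that("moving average matches hand computations and is linear", {
  expect_equal(moving_average(c(0, 0, 3, 0, 0), 3), c(0, 1, 1, 1, 0))
  x <- rnorm(50)
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(rep(2.5, 20), 7), rep(2.5, 20))
  # even windows are promoted to the next odd value
  expect_equal(moving_average(c(0, 0, 3, 0, 0), 2),
               moving_average(c(0, 0, 3, 0, 0), 3))
  # linearity and additive-constant commutation
  y <- rnorm(50)
  expect_equal(moving_average(2 * x + 3 * y, 9),
               2 * moving_average(x, 9) + 3 * moving_average(y, 9),
               tolerance = 1e-12)
  expect_equal(moving_average(x + 10, 9), moving_average(x, 9) + 10,
               tolerance = 1e-12)
  expect_error(moving_average(1:5, 7), "exceeds")
})

test_that("median filter removes spikes but keeps constants and ramps", {
  expect_equal(median_filter(rep(4, 10), 5), rep(4, 10))
  spiky <- c(rep(1, 5), 50, rep(1, 5))
  expect_equal(median_filter(spiky, 3), rep(1, 11))
  ramp <- as.numeric(1:20)
  expect_equal(median_filter(ramp, 3), ramp)   # shrinking edges leave ends
  # additive constants commute
  x <- rnorm(40)
  expect_equal(median_filter(x + 5, 5), median_filter(x, 5) + 5,
               tolerance = 1e-12)
  expect_error(median_filter(1:3, 9), "exceeds")
})

test_that("position converts to equivalent rotation via the pitch", {
  expect_equal(position_to_rotation(rep(3, 10), 2.75), rep(0, 10))
  expect_equal(position_to_rotation(c(0, 2.75), 2.75), c(0, 2 * pi),
               tolerance = 1e-14)
  expect_equal(position_to_rotation(c(0, 30), 2.75)[2], 68.5438,
               tolerance = 1e-5)
  expect_error(position_to_rotation(c(0, 1), 0))
})

test_that("cropping finds start and end by the 1-degree rules", {
  # 0 -> 10 degrees over 100 samples, then a 50-sample plateau
  rot_deg <- c(seq(0, 10, length.out = 100), rep(10, 50))
  tr <- flat_trace(numeric(150), rot_deg * pi / 180)
  cr <- crop_recording(tr)
  expect_equal(cr$start_idx, 11L)   # first sample strictly past 1 degree
  expect_equal(cr$end_idx, 91L)     # first sample within 1 degree of max
  expect_equal(nrow(cr$trace), 91L - 11L + 1L)
  # time is preserved, not re-zeroed
  expect_equal(cr$trace$time[1], tr$time[11])

  expect_error(crop_recording(flat_trace(numeric(10), numeric(10))),
               "no motion")
})

test_that("trace validation catches malformed inputs", {
  expect_error(torque_trace(c(0, 1, 1.5), 1:3, 1:3, 1:3), "non-uniform")
  expect_error(torque_trace(c(0, 1, 0.5), 1:3, 1:3, 1:3),
               "strictly increasing")
  expect_error(torque_trace(0, 1, 1, 1), "at least 2")
})

test_that("tightening onset is detected at a constructed slope change", {
  fs <- 100
  t_slow <- 25; t_fast <- 2
  tt <- seq(0, t_slow + t_fast, by = 1 / fs)
  torque <- ifelse(tt <= t_slow, 1 * tt,
                   t_slow + 30 * (tt - t_slow))
  rot <- 2 * pi * 0.5 * tt   # half a revolution per second
  tr <- torque_trace(tt, torque, rot, numeric(length(tt)))
  idx <- detect_tightening_onset(tr)
  expect_lt(abs(tr$time[idx] - t_slow), 0.5)
  # relative threshold: invariant to torque rescaling
  tr_scaled <- torque_trace(tt, 1000 * torque, rot, numeric(length(tt)))
  expect_equal(detect_tightening_onset(tr_scaled), idx)
})

test_that("constant-slope torque yields no tightening detection", {
  fs <- 100
  tt <- seq(0, 20, by = 1 / fs)
  tr <- torque_trace(tt, 5 * tt, 2 * pi * 0.5 * tt, numeric(length(tt)))
  expect_error(detect_tightening_onset(tr), "no tightening")
})

test_that("stripping torque is the max of the median-filtered signal", {
  fs <- 100
  tt <- seq(0, 10, by = 1 / fs)
  torque <- pmin(3000, 600 * tt)                 # ramp to a 3000 plateau
  tr <- torque_trace(tt, torque, 2 * pi * tt, numeric(length(tt)))
  m <- measure_stripping_torque(tr)
  expect_equal(m$torque, 3000)
  # a one-sample 10x spike is suppressed by the median filter
  torque_spike <- torque
  torque_spike[700] <- 30000
  tr2 <- torque_trace(tt, torque_spike, 2 * pi * tt, numeric(length(tt)))
  expect_equal(measure_stripping_torque(tr2)$torque, 3000)
})

test_that("segmentation of simulated traces keeps the phase ordering", {
  for (seed in 1:4) {
    sim <- simulate_insertion_trace(material_spec("M330", 4), seed = seed)
    seg <- segment_trace(sim$trace)
    b <- seg$bounds
    expect_true(b$start_idx < b$tightening_idx)
    expect_true(b$tightening_idx <= b$stripping_idx)
    expect_true(b$stripping_idx <= b$end_idx)
    expect_true(b$blank_idx > b$start_idx && b$blank_idx < b$tightening_idx)
  }
})

test_that("insertion segments do not run past the true onset across materials", {
  # two noisy traces per default material
  mats <- default_materials()
  count <- 0L
  for (i in seq_len(nrow(mats))) {
    for (rep in 1:2) {
      count <- count + 1L
      sim <- simulate_insertion_trace(mats[i, ], seed = 9000 + count)
      seg <- segment_trace(sim$trace)
      onset_detected <- sim$trace$time[seg$bounds$tightening_idx]
      expect_lt(onset_detected - sim$truth$onset_time, 0.5)
    }
  }
})
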