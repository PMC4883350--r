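test_that("DC removal and normalization center and scale the signal", {
  out <- remove_dc_and_normalize(c(5, 5, 5), sampling_rate = 10)
  expect_equal(out$values, c(0, 0, 0))
  expect_true(out$degenerate)

  out <- remove_dc_and_normalize(c(-1, 0, 1), sampling_rate = 10)
  expect_equal(out$values, c(-1, 0, 1))
  expect_false(out$degenerate)

  out <- remove_dc_and_normalize(c(0, 2, 4), sampling_rate = 10)
  expect_equal(out$values, c(-1, 0, 1))
  expect_lt(abs(mean(out$values)), 1e-9)
  expect_error(remove_dc_and_normalize(numeric(0), 10), "empty")
})

test_that("band-pass keeps QRS-band tones and rejects DC and powerline", {
  fs <- 360
  t <- (0:(4 * fs - 1)) / fs
  probe <- function(f) sin(2 * pi * f * t)
  core <- (fs + 1):(3 * fs)  # ignore filter edges
  gain <- function(f) {
    y <- bandpass_filter(probe(f), fs)$values
    max(abs(y[core]))
  }
  expect_gte(gain(10), 0.9)
  expect_lte(gain(50), 0.1)
  expect_lte(gain(1), 0.1)
  dc <- bandpass_filter(rep(1, 4 * fs), fs)$values
  expect_lte(max(abs(dc[core])), 1e-3)
  expect_error(bandpass_filter(probe(10), fs = 25), "too low")
})

test_that("five-point derivative matches its difference equation", {
  expect_equal(derivative_filter(rep(3, 10), fs = 1)$values[3:8],
               rep(0, 6))
  ramp <- derivative_filter(as.numeric(1:20), fs = 1)$values
  expect_equal(ramp[3:18], rep(1, 16))
  x <- sin(1:50)
  expect_equal(derivative_filter(-x, fs = 7)$values,
               -derivative_filter(x, fs = 7)$values)
  expect_error(derivative_filter(1:4, fs = 1), "5 samples")
})

test_that("squaring is elementwise and nonnegative", {
  expect_equal(square_signal(c(-2, 3))$values, c(4, 9))
  x <- rnorm(100)
  expect_true(all(square_signal(x)$values >= 0))
  expect_equal(square_signal(-x)$values, square_signal(x)$values)
})

test_that("moving-window integration is a trailing mean", {
  # W = 2 samples at fs = 1000 and window_ms = 2
  out <- moving_window_integrate(c(0, 1, 2, 3), fs = 1000, window_ms = 2)
  expect_equal(out$values, c(0, 0.5, 1.5, 2.5))

  imp <- moving_window_integrate(c(1, rep(0, 9)), fs = 1000,
                                 window_ms = 3)
  expect_equal(imp$values, c(rep(1 / 3, 3), rep(0, 7)))

  const <- moving_window_integrate(rep(2, 8), fs = 360, window_ms = 150)
  w <- round(150 * 360 / 1000)
  expect_equal(const$values[length(const$values)],
               2 * min(8, w) / w)
  expect_error(moving_window_integrate(1:10, fs = 360, window_ms = 0.5),
               "window")
})

test_that("R detection is exact on clean records and scale-invariant", {
  cfg <- clean_config(minutes = 1)
  rec <- synthesize_record(cfg, 0, seed = 4)
  idx <- detect_r_peaks(rec)
  det_t <- (idx - 1) / rec$sampling_rate
  matched <- vapply(rec$beat_times,
                    function(b) any(abs(det_t - b) <= 0.05), logical(1))
  expect_true(all(matched))          # sensitivity 100%
  expect_length(idx, length(rec$beat_times))  # positive predictivity 100%

  scaled <- rec
  scaled$voltage <- rec$voltage * 10
  expect_identical(detect_r_peaks(scaled), idx)

  flat <- ecg_record(rep(1, 6 * 360), 360)
  expect_warning(out <- detect_r_peaks(flat), "flat")
  expect_length(out, 0)
  expect_error(detect_r_peaks(ecg_record(rnorm(360), 360)), "5 s")
})

test_that("beat segmentation uses midpoints and tiles the record", {
  rec <- ecg_record(rnorm(700), 100)
  segs <- segment_beats(rec, c(100, 300, 500))
  expect_equal(nrow(segs), 3)
  expect_equal(segs$start[2], 200)
  expect_equal(segs$end[2], 400)
  expect_equal(segs$r[2], 300)
  # half-open segments tile the spanned region without overlap
  expect_equal(segs$start[-1], segs$end[-nrow(segs)])
  expect_true(all(segs$start <= segs$r & segs$r < segs$end))
  expect_error(segment_beats(rec, c(100)), "2 R peaks")
})

test_that("initial-discard trims samples and shifts annotations", {
  rec <- ecg_record(rnorm(120 * 100), 100,
                    beat_times = c(10, 31, 100))
  out <- discard_initial(rec, 30)
  expect_length(out$voltage, 90 * 100)
  expect_equal(out$beat_times, c(1, 70))
  expect_identical(discard_initial(rec, 0), rec)
  expect_error(discard_initial(rec, 1000), "exceeds")
})

test_that("irregular R-R neighbors are flagged as corrupt", {
  fs <- 100
  r <- c(100, 200, 300, 400, 450, 600, 700)  # one mistimed beat
  keep <- reject_corrupt_beats(r)
  expect_true(all(keep[c(1, 2, 3, 7)]))
  expect_false(keep[5])  # 50-sample and 150-sample intervals around it
  expect_true(all(reject_corrupt_beats(seq(0, 1000, by = 100))))
})
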