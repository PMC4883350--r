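test_that("beat templates follow the closed-form sum of Gaussians", {
  m <- separated_morphology()

  zero <- m
  zero$amplitude_mV[] <- 0
  expect_equal(synthesize_beat(zero, 360), rep(0, 2 * 216 + 1))

  beat <- synthesize_beat(m, 360)
  mid <- (length(beat) + 1) / 2
  expect_equal(beat[mid], m$amplitude_mV[["R"]], tolerance = 1e-6)

  m2 <- m
  m2$amplitude_mV[["R"]] <- 2 * m$amplitude_mV[["R"]]
  expect_equal(max(synthesize_beat(m2, 360)), 2 * max(beat),
               tolerance = 1e-6)

  bad <- m
  bad$width_ms[["P"]] <- -1
  expect_error(beat_morphology(bad$amplitude_mV, bad$center_ms,
                               bad$width_ms),
               "width")
  expect_error(synthesize_beat(m, 100), "250")
})

test_that("drunk shifts scale amplitudes and P width/jitter as configured", {
  m <- default_morphology()
  d <- default_drunk_deltas()
  s <- apply_drunk_shift(m, d)

  expect_equal(s$amplitude_mV[["R"]] / m$amplitude_mV[["R"]], 1.1954)
  expect_equal(s$amplitude_mV[["P"]] / m$amplitude_mV[["P"]], 1 - 0.1121)
  expect_equal(s$amplitude_mV[["S"]] / m$amplitude_mV[["S"]], 1.0814)
  expect_equal(s$p_jitter_ms / m$p_jitter_ms, 1.2377)
  # population sup shifts: (sigma + j) scales with the Pmax delta
  expect_equal((s$width_ms[["P"]] + s$p_jitter_ms) /
                 (m$width_ms[["P"]] + m$p_jitter_ms), 1.0907)

  zero <- lapply(d, function(x) 0)
  expect_equal(apply_drunk_shift(m, zero), m)

  inv <- lapply(d, function(x) -x / (1 + x))
  back <- apply_drunk_shift(s, inv)
  expect_equal(back$amplitude_mV, m$amplitude_mV, tolerance = 1e-9)

  huge <- d
  huge$Pmax <- -0.99
  expect_error(apply_drunk_shift(m, huge), "width")
})

test_that("records place beats at the configured rate with faithful annotations", {
  cfg <- cohort_config(n_subjects = 1, record_minutes = 2, mean_hr_bpm = 71,
                       seed = 5)
  rec <- synthesize_record(cfg, 0, seed = 5)
  nb <- length(rec$beat_times)
  expect_gte(nb, 142 - 15)
  expect_lte(nb, 142 + 15)
  expect_true(all(diff(rec$beat_times) > 0))
  expect_length(rec$voltage, 2 * 60 * cfg$sampling_rate)

  rec2 <- synthesize_record(cfg, 0, seed = 5)
  expect_identical(rec$voltage, rec2$voltage)
  expect_identical(rec$beat_times, rec2$beat_times)

  # noiseless record equals the sum of its per-beat templates
  ccfg <- clean_config(minutes = 0.5, morphology = default_morphology())
  clean <- synthesize_record(ccfg, 0, seed = 9)
  fs <- clean$sampling_rate
  n <- length(clean$voltage)
  manual <- numeric(n)
  h <- round(0.6 * fs)
  for (b in seq_along(clean$beat_times)) {
    beat <- synthesize_beat(clean$meta$morphology, fs,
                            p_width_ms = clean$meta$p_widths_ms[b])
    ctr <- round(clean$beat_times[b] * fs) + 1
    lo <- max(1, ctr - h)
    hi <- min(n, ctr + h)
    src <- (lo - (ctr - h) + 1):(length(beat) - ((ctr + h) - hi))
    manual[lo:hi] <- manual[lo:hi] + beat[src]
  }
  expect_equal(clean$voltage, manual, tolerance = 1e-12)

  # annotation fidelity: every beat time is a local maximum within 1 sample
  for (b in clean$beat_times) {
    i <- round(b * fs) + 1
    win <- clean$voltage[(i - 2):(i + 2)]
    expect_lte(abs(which.max(win) - 3), 1)
  }
})

test_that("cohorts are labeled, deterministic, and carry the injected contrast", {
  cfg <- cohort_config(n_subjects = 2, sessions_per_subject = 1,
                       record_minutes = 0.2, seed = 3)
  recs <- generate_cohort(cfg)
  expect_length(recs, 4)
  labels <- vapply(recs, function(r) r$class_label, numeric(1))
  expect_equal(sum(labels == 0), 2)
  expect_equal(sum(labels == 1), 2)
  expect_true(all(!vapply(recs, function(r) is.null(r$class_label),
                          logical(1))))

  recs2 <- generate_cohort(cfg)
  expect_identical(lapply(recs, `[[`, "voltage"),
                   lapply(recs2, `[[`, "voltage"))

  # effect-size injection over 50 subject pairs, on template amplitudes
  big <- cohort_config(n_subjects = 50, record_minutes = 0.1, seed = 8)
  pairs <- generate_cohort(big)
  r_amp <- vapply(pairs, function(r) r$meta$morphology$amplitude_mV[["R"]],
                  numeric(1))
  cls <- vapply(pairs, function(r) r$class_label, numeric(1))
  ratio <- mean(r_amp[cls == 1]) / mean(r_amp[cls == 0])
  expect_lt(abs(100 * (ratio - 1) - 19.54), 1)
})

test_that("expected cohort size follows the sample-count arithmetic", {
  expect_identical(expected_cohort_size(71, 50, 3, 1.5), 15975)
  expect_identical(expected_cohort_size(60, 1, 1, 1), 60)
  expect_identical(expected_cohort_size(71, 50, 3, 2.0), 21300)
  expect_error(expected_cohort_size(-1, 1, 1, 1))
})

test_that("substream seeds are deterministic and distinct by name", {
  expect_identical(substream_seed(42, "simulate"),
                   substream_seed(42, "simulate"))
  expect_false(substream_seed(42, "simulate") ==
                 substream_seed(42, "folds"))
  expect_false(substream_seed(42, "simulate") ==
                 substream_seed(43, "simulate"))
  expect_lt(substream_seed(2^30, "x"), 2^31)
})
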