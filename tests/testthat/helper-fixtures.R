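# Shared fixtures: small cohorts and clean configurations built in code.

# morphology with widely separated, narrow waves: neighboring-wave overlap
# is negligible, so delineation can be checked against the template
separated_morphology <- function() {
  beat_morphology(
    amplitude_mV = c(P = 0.20, Q = -0.08, R = 1.00, S = -0.20, T = 0.30),
    center_ms = c(P = -200, Q = -40, R = 0, S = 40, T = 320),
    width_ms = c(P = 15, Q = 6, R = 9, S = 7, T = 40),
    p_jitter_ms = 0
  )
}

no_noise <- function() {
  list(baseline_amp_mV = 0, baseline_hz = 0.3,
       powerline_amp_mV = 0, powerline_hz = 50, white_sd_mV = 0)
}

# one-subject clean cohort config for precision checks
clean_config <- function(minutes = 1, morphology = separated_morphology(),
                         seed = 11) {
  cohort_config(n_subjects = 1, record_minutes = minutes,
                subject_amp_sd = 0, hr_sd = 0, morphology = morphology,
                noise = no_noise(), seed = seed)
}

# small labeled dataset with a clean margin between classes, for
# classifier tests that need separability
separable_dataset <- function(n_per_class = 30, p = 10, gap = 6,
                              seed = 42) {
  withr_seed <- function(code) ecgddd:::with_seed(seed, code)
  X <- withr_seed({
    rbind(matrix(stats::rnorm(n_per_class * p), ncol = p),
          matrix(stats::rnorm(n_per_class * p, mean = gap), ncol = p))
  })
  colnames(X) <- ecgddd:::FEATURE_NAMES[seq_len(p)]
  ecgddd:::new_dataset(X, rep(c(0L, 1L), each = n_per_class),
                       as.character(seq_len(2 * n_per_class)))
}

# delineated beat table for a record, as build_dataset produces it
delineate_pipeline <- function(record, trim = 5) {
  rt <- discard_initial(record, trim)
  idx <- detect_r_peaks(rt)
  segs <- segment_beats(rt, idx)
  list(record = rt, r = idx, segments = segs,
       beats = delineate_record(rt, segs))
}

# per-class percent change of selected features between drunk and normal
cohort_percent_changes <- function(records, W = 10, stride = 1) {
  ds <- build_dataset(records, W = W, stride = stride)
  m0 <- colMeans(ds$X[ds$y == 0, , drop = FALSE])
  m1 <- colMeans(ds$X[ds$y == 1, , drop = FALSE])
  100 * (m1 - m0) / m0
}
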