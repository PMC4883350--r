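## Synthetic ECG cohort generation.
##
## Each heartbeat is modeled as a sum of five Gaussian bumps (P, Q, R, S, T)
## around the R peak; the closed form makes every downstream measurement
## testable against ground truth.  The drunk class is derived from the
## normal morphology by fractional shifts of the P/R/S amplitudes, the mean
## R-R interval, and the P-wave width/jitter (which carry the maximal
## P duration Pmax and the P-wave dispersion Pd).

WAVE_NAMES <- c("P", "Q", "R", "S", "T")

# 10%-relative-threshold duration of a Gaussian bump of width sigma is
# 2 * sigma * sqrt(2 * log(10)); the constant recurs throughout.
GAUSS_DUR10 <- 2 * sqrt(2 * log(10))

#' Describe the morphology of one heartbeat
#'
#' A beat is a sum of five Gaussian bumps, one per ECG wave.  Amplitudes
#' are in millivolt, centers are offsets from the R peak in milliseconds,
#' and widths are Gaussian standard deviations in milliseconds.  The P-wave
#' width additionally jitters from beat to beat (uniformly within
#' `p_jitter_ms` of its nominal value), which is what gives a record a
#' nonzero P-wave dispersion.
#'
#' @param amplitude_mV named numeric, one amplitude per wave P,Q,R,S,T.
#' @param center_ms named numeric, wave center offsets from R (P,Q before R
#'   are negative; S,T after R are positive; R itself is 0).
#' @param width_ms named numeric, positive Gaussian widths (sigma).
#' @param p_jitter_ms half-width of the uniform per-beat jitter applied to
#'   the P width (ms, `>= 0`).
#' @return An object of class `beat_morphology`.
#' @seealso [default_morphology()], [apply_drunk_shift()],
#'   [synthesize_beat()]
#' @export
beat_morphology <- function(amplitude_mV, center_ms, width_ms,
                            p_jitter_ms = 0) {
  for (v in list(amplitude_mV, center_ms, width_ms)) {
    stopifnot(is.numeric(v), setequal(names(v), WAVE_NAMES))
  }
  amplitude_mV <- amplitude_mV[WAVE_NAMES]
  center_ms <- center_ms[WAVE_NAMES]
  width_ms <- width_ms[WAVE_NAMES]
  if (any(width_ms <= 0)) {
    stop("invalid morphology: all wave widths must be positive")
  }
  if (p_jitter_ms < 0 || p_jitter_ms >= width_ms[["P"]]) {
    stop("invalid morphology: P width jitter must lie in [0, P width)")
  }
  if (!(center_ms[["P"]] < center_ms[["Q"]] && center_ms[["Q"]] < 0 &&
        center_ms[["S"]] > 0 && center_ms[["T"]] > center_ms[["S"]])) {
    stop("invalid morphology: wave centers must be ordered P < Q < R < S < T")
  }
  structure(list(amplitude_mV = amplitude_mV, center_ms = center_ms,
                 width_ms = width_ms, p_jitter_ms = p_jitter_ms),
            class = "beat_morphology")
}

#' Default normal-class beat morphology
#'
#' Textbook lead-II-like shape: a 0.15 mV P wave about 160 ms before the R
#' peak, a 1 mV R peak flanked by small Q and S deflections, and a broad
#' 0.35 mV T wave about 300 ms after R.  The nominal P width of 22 ms with
#' a 6 ms uniform jitter yields 10%-threshold P durations of roughly
#' 70--120 ms and a within-record P-wave dispersion in the 30--50 ms range,
#' consistent with resting adult ECG.
#'
#' @return A `beat_morphology` object.
#' @export
default_morphology <- function() {
  beat_morphology(
    amplitude_mV = c(P = 0.15, Q = -0.10, R = 1.00, S = -0.25, T = 0.35),
    center_ms = c(P = -160, Q = -30, R = 0, S = 30, T = 300),
    width_ms = c(P = 22, Q = 7, R = 10, S = 8, T = 45),
    p_jitter_ms = 6
  )
}

#' Default fractional class shifts for the drunk morphology
#'
#' Averaged drunk-vs-normal variations of the six discriminative ECG
#' characteristics: P peak -11.21%, R peak +19.54%, S peak +8.14%,
#' R-R interval -8.43%, maximal P duration (Pmax) +9.07%, and P-wave
#' dispersion (Pd) +23.77%.
#'
#' @return Named list of fractional shifts.
#' @export
default_drunk_deltas <- function() {
  list(P = -0.1121, R = 0.1954, S = 0.0814,
       RR = -0.0843, Pmax = 0.0907, Pd = 0.2377)
}

#' Derive the drunk-class morphology from a normal one
#'
#' Wave amplitudes P, R, S are scaled by `1 + delta`.  The P-wave width and
#' its per-beat jitter are rescaled so that, at the population level (over
#' the full jitter range), the maximal P duration shifts by `deltas$Pmax`
#' and the P-wave dispersion by `deltas$Pd`: a Gaussian P of width sigma
#' has a 10%-threshold duration proportional to sigma, so the dispersion
#' scales with the jitter half-width `j` and the maximal duration with
#' `sigma + j`.  The mean R-R interval shift `deltas$RR` is applied at
#' record synthesis, not here.
#'
#' @param morph a `beat_morphology`.
#' @param deltas named list of fractional shifts (see
#'   [default_drunk_deltas()]).
#' @return A new `beat_morphology`.
#' @export
#' @examples
#' m <- apply_drunk_shift(default_morphology(), default_drunk_deltas())
#' m$amplitude_mV[["R"]] / default_morphology()$amplitude_mV[["R"]]  # 1.1954
apply_drunk_shift <- function(morph, deltas = default_drunk_deltas()) {
  stopifnot(inherits(morph, "beat_morphology"))
  stopifnot(all(c("P", "R", "S", "Pmax", "Pd") %in% names(deltas)))
  amp <- morph$amplitude_mV
  for (w in c("P", "R", "S")) {
    amp[[w]] <- amp[[w]] * (1 + deltas[[w]])
  }
  wid <- morph$width_ms
  j0 <- morph$p_jitter_ms
  # sup-based population targets: sigma' + j' = (1+dmax)(sigma + j) and
  # 2j' = (1+dpd) 2j  =>  sigma' = (1+dmax) sigma + j (dmax - dpd)
  j1 <- (1 + deltas$Pd) * j0
  s1 <- (1 + deltas$Pmax) * wid[["P"]] + j0 * (deltas$Pmax - deltas$Pd)
  if (s1 <= 0 || j1 >= s1) {
    stop("drunk shift produces a non-positive or jitter-dominated P width")
  }
  wid[["P"]] <- s1
  beat_morphology(amp, morph$center_ms, wid, p_jitter_ms = j1)
}

#' Evaluate one beat template on a sample grid
#'
#' Closed-form sum of the five Gaussian bumps, evaluated at `fs` Hz on a
#' window centered on the R peak.
#'
#' @param morph a `beat_morphology`.
#' @param fs sampling rate in Hz (`>= 250`).
#' @param half_window_ms half-width of the evaluation window around R (ms).
#' @param p_width_ms optional override of the P width for this beat (used
#'   by the generator to apply the per-beat jitter).
#' @return Numeric vector of `2 * round(half_window_ms * fs / 1000) + 1`
#'   voltages (mV); the R center falls on the middle sample.
#' @export
synthesize_beat <- function(morph, fs, half_window_ms = 600,
                            p_width_ms = NULL) {
  stopifnot(inherits(morph, "beat_morphology"))
  if (fs < 250) stop("sampling rate must be at least 250 Hz")
  wid <- morph$width_ms
  if (!is.null(p_width_ms)) {
    if (p_width_ms <= 0) stop("invalid morphology: non-positive P width")
    wid[["P"]] <- p_width_ms
  }
  h <- round(half_window_ms * fs / 1000)
  t_ms <- (seq(-h, h) / fs) * 1000
  v <- numeric(length(t_ms))
  for (w in WAVE_NAMES) {
    v <- v + morph$amplitude_mV[[w]] *
      exp(-((t_ms - morph$center_ms[[w]])^2) / (2 * wid[[w]]^2))
  }
  v
}

#' Cohort configuration
#'
#' Bundles every knob of the synthetic study: cohort layout, heart rate,
#' class shifts, noise model, and the root seed.  Defaults mirror the data
#' collection protocol the pipeline stands in for: 50 subjects, 2-minute
#' records per class and session, a mean normal heart rate of 71 bpm, and a
#' class contrast given by [default_drunk_deltas()].
#'
#' @param n_subjects number of subjects (`>= 1`).
#' @param sessions_per_subject recording sessions per subject (`>= 1`).
#' @param record_minutes record duration in minutes.
#' @param mean_hr_bpm mean normal-class heart rate (beats/min).
#' @param hr_sd between-subject heart-rate standard deviation (beats/min).
#' @param rr_sd_s within-record beat-to-beat R-R standard deviation (s),
#'   truncated at 3 SD to keep beats ordered.
#' @param subject_amp_sd between-subject log-normal spread (sdlog) of a
#'   common amplitude scale applied to all five waves.
#' @param drunk_deltas fractional class shifts, see [default_drunk_deltas()].
#' @param noise list with elements `baseline_amp_mV`, `baseline_hz`,
#'   `powerline_amp_mV`, `powerline_hz`, `white_sd_mV`.
#' @param sampling_rate sampling rate in Hz (`>= 250`).
#' @param morphology normal-class `beat_morphology`.
#' @param seed integer root seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 50,
                          sessions_per_subject = 1,
                          record_minutes = 2,
                          mean_hr_bpm = 71,
                          hr_sd = 3,
                          rr_sd_s = 0.04,
                          subject_amp_sd = 0.15,
                          drunk_deltas = default_drunk_deltas(),
                          noise = list(baseline_amp_mV = 0.05,
                                       baseline_hz = 0.3,
                                       powerline_amp_mV = 0,
                                       powerline_hz = 50,
                                       white_sd_mV = 0.02),
                          sampling_rate = 360,
                          morphology = default_morphology(),
                          seed = 42) {
  stopifnot(n_subjects >= 1, sessions_per_subject >= 1, record_minutes > 0,
            mean_hr_bpm > 0, hr_sd >= 0, rr_sd_s >= 0, subject_amp_sd >= 0)
  if (sampling_rate < 250) stop("sampling_rate must be at least 250 Hz")
  need <- c("baseline_amp_mV", "baseline_hz", "powerline_amp_mV",
            "powerline_hz", "white_sd_mV")
  stopifnot(all(need %in% names(noise)))
  structure(list(n_subjects = as.integer(n_subjects),
                 sessions_per_subject = as.integer(sessions_per_subject),
                 record_minutes = record_minutes,
                 mean_hr_bpm = mean_hr_bpm, hr_sd = hr_sd,
                 rr_sd_s = rr_sd_s, subject_amp_sd = subject_amp_sd,
                 drunk_deltas = drunk_deltas, noise = noise[need],
                 sampling_rate = sampling_rate, morphology = morphology,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Construct an ECG record object
#'
#' @param voltage numeric voltage trace (mV).
#' @param sampling_rate sampling rate (Hz).
#' @param beat_times optional ground-truth R-peak times (s), strictly
#'   increasing.
#' @param class_label optional class: 0 = normal, 1 = drunk.
#' @param meta optional list of provenance fields (subject, session,
#'   morphology, ...).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(voltage, sampling_rate, beat_times = NULL,
                       class_label = NULL, meta = list()) {
  stopifnot(is.numeric(voltage), length(voltage) > 0, sampling_rate > 0)
  if (!is.null(beat_times)) {
    if (any(diff(beat_times) <= 0)) {
      stop("beat_times must be strictly increasing")
    }
  }
  if (!is.null(class_label)) stopifnot(class_label %in% c(0, 1))
  structure(list(voltage = as.numeric(voltage),
                 sampling_rate = sampling_rate,
                 beat_times = beat_times, class_label = class_label,
                 meta = meta),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  dur <- length(x$voltage) / x$sampling_rate
  cat(sprintf("<ecg_record> %.1f s @ %g Hz", dur, x$sampling_rate))
  if (!is.null(x$beat_times)) {
    cat(sprintf(", %d annotated beats", length(x$beat_times)))
  }
  if (!is.null(x$class_label)) {
    cat(sprintf(", class %d (%s)", x$class_label,
                if (x$class_label == 1) "drunk" else "normal"))
  }
  cat("\n")
  invisible(x)
}

#' Synthesize one annotated ECG record
#'
#' Places beats at R-R intervals drawn from a truncated Gaussian around
#' `60 / hr`, evaluates the beat template (with per-beat P-width jitter) at
#' each beat position, and adds baseline wander, optional powerline
#' interference, and white noise.  Deterministic given `seed`.
#'
#' @param cfg a [cohort_config()].
#' @param class_label 0 (normal) or 1 (drunk).
#' @param seed integer seed for this record.
#' @param morphology optional subject-specific normal morphology override
#'   (the drunk shift is still applied internally when `class_label == 1`).
#' @param hr_bpm optional subject-specific normal heart rate override.
#' @return An [ecg_record()] with ground-truth `beat_times`, the class
#'   label, and the noiseless per-beat template parameters in `meta`.
#' @export
synthesize_record <- function(cfg, class_label, seed,
                              morphology = NULL, hr_bpm = NULL) {
  stopifnot(inherits(cfg, "cohort_config"), class_label %in% c(0, 1))
  fs <- cfg$sampling_rate
  morph <- morphology %||% cfg$morphology
  hr <- hr_bpm %||% cfg$mean_hr_bpm
  if (class_label == 1) {
    morph <- apply_drunk_shift(morph, cfg$drunk_deltas)
  }
  mean_rr <- 60 / hr
  if (class_label == 1) mean_rr <- mean_rr * (1 + cfg$drunk_deltas$RR)
  n <- round(cfg$record_minutes * 60 * fs)
  dur_s <- n / fs
  with_seed(seed, {
    # beat placement: first R about one interval in, then truncated
    # Gaussian R-R steps until the record ends
    r_times <- numeric(0)
    t <- mean_rr * stats::runif(1, 0.4, 0.9)
    while (t < dur_s - 0.35) {
      r_times <- c(r_times, t)
      step <- mean_rr + max(-3 * cfg$rr_sd_s,
                            min(3 * cfg$rr_sd_s,
                                stats::rnorm(1, 0, cfg$rr_sd_s)))
      t <- t + step
    }
    nb <- length(r_times)
    p_widths <- morph$width_ms[["P"]] +
      stats::runif(nb, -morph$p_jitter_ms, morph$p_jitter_ms)
    v <- numeric(n)
    h <- round(600 * fs / 1000)
    for (b in seq_len(nb)) {
      ctr <- round(r_times[b] * fs) + 1L
      beat <- synthesize_beat(morph, fs, half_window_ms = 600,
                              p_width_ms = p_widths[b])
      lo <- ctr - h
      hi <- ctr + h
      src <- seq_along(beat)
      if (lo < 1L) {
        src <- src[(2L - lo):length(beat)]
        lo <- 1L
      }
      if (hi > n) {
        src <- src[seq_len(length(src) - (hi - n))]
        hi <- n
      }
      v[lo:hi] <- v[lo:hi] + beat[src]
    }
    tt <- seq_len(n) / fs
    nz <- cfg$noise
    if (nz$baseline_amp_mV > 0) {
      v <- v + nz$baseline_amp_mV *
        sin(2 * pi * nz$baseline_hz * tt + stats::runif(1, 0, 2 * pi))
    }
    if (nz$powerline_amp_mV > 0) {
      v <- v + nz$powerline_amp_mV *
        sin(2 * pi * nz$powerline_hz * tt + stats::runif(1, 0, 2 * pi))
    }
    if (nz$white_sd_mV > 0) {
      v <- v + stats::rnorm(n, 0, nz$white_sd_mV)
    }
    # ground-truth R times on the sample grid (where the template peaks)
    r_grid <- (round(r_times * fs)) / fs
    ecg_record(v, fs, beat_times = r_grid, class_label = class_label,
               meta = list(morphology = morph, p_widths_ms = p_widths,
                           mean_rr_s = mean_rr, seed = seed))
  })
}

#' Generate a labeled two-class cohort
#'
#' One normal and one drunk record per subject and session.  Each subject
#' gets its own amplitude scale (log-normal) and heart rate (Gaussian),
#' shared by its normal and drunk records so the class contrast is purely
#' the configured morphology shift.  All record seeds derive
#' deterministically from `cfg$seed` via named substreams.
#'
#' @param cfg a [cohort_config()].
#' @return List of [ecg_record()]s, length
#'   `2 * n_subjects * sessions_per_subject`, each with `meta$subject` and
#'   `meta$session`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  records <- list()
  for (s in seq_len(cfg$n_subjects)) {
    subj_seed <- substream_seed(cfg$seed, paste0("subject", s))
    subj <- with_seed(subj_seed, {
      list(amp = exp(stats::rnorm(1, 0, cfg$subject_amp_sd)),
           hr = max(40, stats::rnorm(1, cfg$mean_hr_bpm, cfg$hr_sd)))
    })
    m <- cfg$morphology
    m$amplitude_mV <- m$amplitude_mV * subj$amp
    for (sess in seq_len(cfg$sessions_per_subject)) {
      for (cls in c(0L, 1L)) {
        rec_seed <- substream_seed(
          cfg$seed, sprintf("record.s%d.v%d.c%d", s, sess, cls))
        rec <- synthesize_record(cfg, cls, rec_seed,
                                 morphology = m, hr_bpm = subj$hr)
        rec$meta$subject <- s
        rec$meta$session <- sess
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  records
}

#' Expected number of one-beat samples in a cohort
#'
#' Arithmetic of the sample-count bookkeeping: beats per minute times
#' subjects times sessions times retained minutes per record.
#'
#' @param hr_bpm average heart rate (beats/min).
#' @param n_subjects number of subjects.
#' @param n_sessions sessions per subject.
#' @param retained_minutes analyzed minutes per record (after any initial
#'   discard).
#' @return Rounded expected beat count.
#' @export
#' @examples
#' expected_cohort_size(71, 50, 3, 1.5)  # 15975
expected_cohort_size <- function(hr_bpm, n_subjects, n_sessions,
                                 retained_minutes) {
  stopifnot(hr_bpm > 0, n_subjects > 0, n_sessions > 0,
            retained_minutes > 0)
  round(hr_bpm * n_subjects * n_sessions * retained_minutes)
}
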