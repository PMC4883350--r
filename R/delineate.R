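## Wave delineation: locate P, Q, R, S, T peaks inside each beat segment
## and measure the P-wave duration per beat.
##
## QRS waves are read off the DC-removed raw signal (they are large and
## sharp); the low-amplitude P and T waves are located on a zero-phase
## low-pass smoothed copy so that white noise does not dislodge their
## peaks, with amplitudes then read from the raw signal at the located
## index (unbiased under additive zero-mean noise).

# Zero-phase low-pass smoother used for P/T search and P-duration
# measurement: 2nd-order Butterworth applied forward-backward.
SMOOTH_FC_HZ <- 18


smooth_for_waves <- function(v, fs, fc = SMOOTH_FC_HZ) {
  bf <- signal::butter(2, fc / (fs / 2), type = "low")
  signal::filtfilt(bf, v)
}

# Equivalent Gaussian broadening width (ms) of the smoother, calibrated
# once per (fs, fc) by smoothing a known Gaussian bump and solving
# width_out^2 = width_in^2 + h^2 at the 10% threshold.  Cached.
smoother_broadening_ms <- local({
  cache <- list()
  function(fs, fc = SMOOTH_FC_HZ, probe_sigma_ms = 25) {
    key <- paste(fs, fc)
    if (!is.null(cache[[key]])) return(cache[[key]])
    t_ms <- ((seq_len(2 * fs) - fs) / fs) * 1000
    g <- exp(-t_ms^2 / (2 * probe_sigma_ms^2))
    sm <- smooth_for_waves(g, fs, fc)
    p <- which.max(sm)
    d <- p_wave_duration(sm, p, fs, baseline = 0, persist_ms = 0,
                         search_lo = p - fs %/% 2,
                         search_hi = p + fs %/% 2)
    sig_eff <- d[["duration_ms"]] / GAUSS_DUR10
    h <- sqrt(max(sig_eff^2 - probe_sigma_ms^2, 0))
    cache[[key]] <<- h
    h
  }
})

# Correct a 10%-threshold duration for the smoother's broadening by
# subtracting the equivalent kernel width in quadrature.  Exact for
# Gaussian waves, first-order correct for any smooth unimodal wave.
deconvolve_duration <- function(duration_ms, broadening_ms) {
  kd <- GAUSS_DUR10 * broadening_ms
  sqrt(pmax(duration_ms^2 - kd^2, 0))
}

# Zero-phase high-pass that strips baseline wander before delineation:
# a 2nd-order 0.5 Hz Butterworth applied forward-backward twice (the
# cascade is numerically safer than one high-order filter at so low a
# normalized cutoff).  0.5 Hz leaves the P/QRS/T morphology intact but
# flattens the slow drift whose slope would otherwise defeat the 10%
# duration threshold.
remove_baseline_wander <- function(v, fs, fc = 0.5) {
  bf <- signal::butter(2, fc / (fs / 2), type = "high")
  signal::filtfilt(bf, signal::filtfilt(bf, v))
}

ms_to_samp <- function(ms, fs) as.integer(round(ms * fs / 1000))

invalid_waveset <- function() {
  data.frame(wave = c("P", "Q", "R", "S", "T"),
             index = NA_integer_, time_s = NA_real_, amp_mV = NA_real_,
             valid = FALSE, stringsAsFactors = FALSE)
}

#' Locate the five waves of one beat
#'
#' Within a beat segment anchored at its R peak: Q is the minimum in
#' `[R - 80 ms, R)`, S the minimum in `(R, R + 80 ms]`, P the maximum of
#' the smoothed signal in `[R - 250 ms, R - 60 ms]`, and T the largest
#' smoothed excursion from baseline in `[R + 100 ms, R + 400 ms]`, all
#' clipped to the segment.  A P peak must rise at least 5% of the R
#' amplitude above the PR-segment baseline to count; windows that fall
#' outside the beat yield invalid waves, and beats shorter than 200 ms are
#' entirely invalid.
#'
#' @param beat one row of [segment_beats()] output (`start`, `end`, `r`).
#' @param signal DC-removed raw signal (mV) for the whole record.
#' @param fs sampling rate (Hz).
#' @param smoothed optional precomputed [smoothed][locate_waves] signal
#'   (the low-pass copy); computed on the fly when missing.
#' @param flank_levels optional numeric pair `c(left, right)` of
#'   externally estimated floor levels for the pre-P and PR flanks (mV);
#'   [delineate_record()] supplies levels smoothed across neighboring
#'   beats, which are less noisy than one beat's own medians.
#' @return A `data.frame` with one row per wave (`wave`, `index`,
#'   `time_s`, `amp_mV`, `valid`), plus attributes `p_onset`, `p_offset`,
#'   `p_duration_ms` (NA when the P duration cannot be measured) and
#'   `baseline_mV`.
#' @export
locate_waves <- function(beat, signal, fs, smoothed = NULL,
                         flank_levels = NULL) {
  start <- as.integer(beat[["start"]])
  end <- as.integer(beat[["end"]])
  r <- as.integer(beat[["r"]])
  stopifnot(start <= r, r < end)
  ws <- invalid_waveset()
  if ((end - start) / fs < 0.2) {
    return(structure(ws, p_onset = NA_real_, p_offset = NA_real_,
                     p_duration_ms = NA_real_, baseline_mV = NA_real_))
  }
  if (is.null(smoothed)) smoothed <- smooth_for_waves(signal, fs)
  n <- length(signal)
  clip <- function(lo, hi) {
    lo <- max(lo, start, 1L)
    hi <- min(hi, end - 1L, n)
    if (lo > hi) NULL else lo:hi
  }
  # Local isoelectric baseline: medians of the smoothed floor over two
  # flat stretches flanking the P wave -- the pre-P (TP) floor and the PR
  # segment just before Q -- interpolated linearly at the nominal P
  # position.  The interpolation cancels any residual linear drift of
  # the floor across the beat, and amplitudes read relative to it are
  # immune to slow wander and to the record-mean offset contributed by
  # the beats themselves.
  bw_left <- clip(r - ms_to_samp(330, fs), r - ms_to_samp(270, fs))
  bw_right <- clip(r - ms_to_samp(90, fs), r - ms_to_samp(55, fs))
  p_ctr <- r - ms_to_samp(160, fs)
  b1 <- if (is.null(bw_left)) NA_real_ else stats::median(smoothed[bw_left])
  b2 <- if (is.null(bw_right)) NA_real_ else {
    stats::median(smoothed[bw_right])
  }
  if (!is.null(flank_levels)) {
    if (is.finite(flank_levels[1])) b1 <- flank_levels[1]
    if (is.finite(flank_levels[2])) b2 <- flank_levels[2]
  }
  baseline <- if (is.na(b1) && is.na(b2)) {
    0
  } else if (is.na(b1) || is.na(b2)) {
    max(b1, b2, na.rm = TRUE)
  } else {
    t1 <- r - ms_to_samp(300, fs)
    t2 <- r - ms_to_samp(72, fs)
    b1 + (b2 - b1) * (p_ctr - t1) / (t2 - t1)
  }
  set_wave <- function(ws, w, idx) {
    k <- match(w, ws$wave)
    ws$index[k] <- idx
    ws$time_s[k] <- (idx - 1) / fs
    ws$amp_mV[k] <- signal[idx] - baseline
    ws$valid[k] <- TRUE
    ws
  }
  ws <- set_wave(ws, "R", r)
  win <- clip(r - ms_to_samp(80, fs), r - 1L)
  if (!is.null(win)) ws <- set_wave(ws, "Q", win[which.min(signal[win])])
  win <- clip(r + 1L, r + ms_to_samp(80, fs))
  if (!is.null(win)) ws <- set_wave(ws, "S", win[which.min(signal[win])])

  p_on <- NA_real_
  p_off <- NA_real_
  p_dur <- NA_real_
  win <- clip(r - ms_to_samp(250, fs), r - ms_to_samp(60, fs))
  if (!is.null(win) && length(win) >= 3) {
    p_idx <- win[which.max(smoothed[win])]
    r_amp <- abs(signal[r] - baseline)
    if (smoothed[p_idx] - baseline >= 0.05 * r_amp) {
      ws <- set_wave(ws, "P", p_idx)
      # peak level for the duration threshold from a local parabola fit:
      # the sample maximum of a noisy signal is upward-biased, and that
      # bias would shorten every measured duration
      pf <- (max(p_idx - 4L, 1L)):(min(p_idx + 4L, n))
      pk <- NULL
      if (length(pf) >= 5) {
        x <- pf - p_idx
        co <- stats::lm.fit(cbind(1, x, x^2), smoothed[pf])$coefficients
        if (is.finite(co[3]) && co[3] < 0) {
          pk <- co[1] - co[2]^2 / (4 * co[3])
        }
      }
      dur <- p_wave_duration(smoothed, p_idx, fs, baseline = baseline,
                             search_lo = max(start, p_idx -
                                               ms_to_samp(120, fs)),
                             search_hi = min(r - ms_to_samp(30, fs),
                                             p_idx + ms_to_samp(120, fs)),
                             peak_value = pk)
      p_on <- dur[["onset"]]
      p_off <- dur[["offset"]]
      p_dur <- deconvolve_duration(dur[["duration_ms"]],
                                   smoother_broadening_ms(fs))
    }
  }
  win <- clip(r + ms_to_samp(100, fs), r + ms_to_samp(400, fs))
  if (!is.null(win) && length(win) >= 3) {
    t_idx <- win[which.max(abs(smoothed[win] - baseline))]
    ws <- set_wave(ws, "T", t_idx)
  }
  structure(ws, p_onset = p_on, p_offset = p_off, p_duration_ms = p_dur,
            baseline_mV = baseline)
}

#' Measure the duration of a P wave
#'
#' Onset and offset are the first crossings, moving outwards from the
#' peak, below 10% of the peak amplitude relative to the local baseline;
#' crossing positions are refined by linear interpolation between the
#' bracketing samples.  To reject brief noise dips, a crossing counts
#' only if the signal then stays below the threshold for
#' `persist_ms` milliseconds.  The threshold is relative, so the
#' measurement is invariant to amplitude scaling.
#'
#' @param signal smoothed signal (mV) over the whole record.
#' @param p_peak sample index of the P peak.
#' @param fs sampling rate (Hz).
#' @param baseline local baseline level (mV), typically the pooled
#'   PR-segment / pre-P floor median.
#' @param search_lo,search_hi sample bounds of the search; crossings must
#'   occur inside them or the duration is invalid (NA).
#' @param persist_ms below-threshold persistence required of a crossing
#'   (ms; 0 disables the debounce).
#' @param peak_value optional externally estimated peak level (mV)
#'   replacing `signal[p_peak]` in the threshold; a local parabola fit
#'   around the peak avoids the upward max-selection bias of the raw
#'   sample maximum.
#' @return Named numeric vector `onset`, `offset` (fractional sample
#'   indices) and `duration_ms`; all NA when no crossing is found.
#' @export
p_wave_duration <- function(signal, p_peak, fs, baseline = 0,
                            search_lo = NULL, search_hi = NULL,
                            persist_ms = 15, peak_value = NULL) {
  p_peak <- as.integer(p_peak)
  stopifnot(p_peak >= 1, p_peak <= length(signal))
  search_lo <- max(1L, as.integer(search_lo %||%
                                    (p_peak - ms_to_samp(160, fs))))
  search_hi <- min(length(signal),
                   as.integer(search_hi %||%
                                (p_peak + ms_to_samp(160, fs))))
  peak_amp <- (peak_value %||% signal[p_peak]) - baseline
  bad <- c(onset = NA_real_, offset = NA_real_, duration_ms = NA_real_)
  if (!is.finite(peak_amp) || peak_amp <= 0) return(bad)
  thr <- baseline + 0.1 * peak_amp
  np <- max(1L, ms_to_samp(persist_ms, fs))
  cross_out <- function(idx_seq) {
    # first sample below threshold (moving outwards) from which the
    # signal stays below for the persistence window; interpolate between
    # the crossing sample and its inward neighbor
    m <- length(idx_seq)
    under <- signal[idx_seq] < thr
    k <- NA_integer_
    for (q in seq_len(m)) {
      if (under[q] && all(under[q:min(m, q + np - 1L)])) {
        k <- q
        break
      }
    }
    if (is.na(k)) return(NA_real_)
    if (k == 1) return(as.numeric(idx_seq[1]))
    a <- idx_seq[k - 1]
    b <- idx_seq[k]
    frac <- (signal[a] - thr) / (signal[a] - signal[b])
    a + frac * (b - a)
  }
  if (p_peak <= search_lo || p_peak >= search_hi) return(bad)
  onset <- cross_out(seq(p_peak - 1L, search_lo))
  offset <- cross_out(seq(p_peak + 1L, search_hi))
  if (is.na(onset) || is.na(offset)) return(bad)
  c(onset = onset, offset = offset,
    duration_ms = (offset - onset) / fs * 1000)
}

#' Maximal P duration and P-wave dispersion
#'
#' `Pmax` is the maximum P-wave duration over a set of beats and `Pd`
#' (P-wave dispersion) the difference between the maximum and minimum.
#'
#' @param durations numeric P-wave durations (ms); NAs are dropped.
#' @return Named numeric vector `Pmax`, `Pd` (ms).
#' @export
#' @examples
#' compute_pmax_pd(c(80, 95, 110))  # Pmax 110, Pd 30
compute_pmax_pd <- function(durations) {
  d <- durations[is.finite(durations)]
  if (length(d) == 0) stop("no valid P-wave durations")
  c(Pmax = max(d), Pd = max(d) - min(d))
}

#' Delineate every beat of a record
#'
#' Convenience wrapper: DC-removes the record (mean subtraction, so
#' amplitudes stay in mV), strips baseline wander with a zero-phase
#' 0.5 Hz high-pass, smooths once, runs [locate_waves()] on each
#' segment, and tabulates the per-beat measurements used by the feature
#' extractor.
#'
#' @param record an [ecg_record()].
#' @param segments output of [segment_beats()].
#' @return A `data.frame` with one row per beat: `beat`, `r_index`,
#'   `r_time_s`, `p_amp`, `r_amp`, `s_amp`, `t_amp` (mV), `p_dur_ms`, and
#'   validity flags `p_valid`, `r_valid`, `s_valid`, `dur_valid`.
#' @export
delineate_record <- function(record, segments) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$sampling_rate
  v <- remove_baseline_wander(record$voltage - mean(record$voltage), fs)
  sm <- smooth_for_waves(v, fs)
  nb <- nrow(segments)
  # Per-beat floor levels over the two flat flanks of the P window
  flank <- function(lo_ms, hi_ms) {
    vapply(seq_len(nb), function(b) {
      lo <- max(segments$start[b], segments$r[b] - ms_to_samp(lo_ms, fs), 1L)
      hi <- min(segments$r[b] - ms_to_samp(hi_ms, fs), segments$end[b] - 1L)
      if (lo > hi) NA_real_ else stats::median(sm[lo:hi])
    }, numeric(1))
  }
  # The floor level varies only slowly from beat to beat (residual
  # wander the high-pass let through), so a short running median across
  # beats tracks it while suppressing most of each beat's own noise.
  smooth_series <- function(x, k = 9L) {
    ok <- is.finite(x)
    if (sum(ok) >= 5) {
      x[ok] <- stats::runmed(x[ok], min(k, sum(ok) - (sum(ok) + 1) %% 2))
    }
    x
  }
  b_left <- smooth_series(flank(330, 270))
  b_right <- smooth_series(flank(90, 55))
  out <- data.frame(beat = seq_len(nb), r_index = segments$r,
                    r_time_s = (segments$r - 1) / fs,
                    p_amp = NA_real_, r_amp = NA_real_, s_amp = NA_real_,
                    t_amp = NA_real_, p_dur_ms = NA_real_,
                    p_valid = FALSE, r_valid = FALSE, s_valid = FALSE,
                    dur_valid = FALSE)
  for (b in seq_len(nb)) {
    ws <- locate_waves(segments[b, ], v, fs, smoothed = sm,
                       flank_levels = c(b_left[b], b_right[b]))
    amp <- function(w) ws$amp_mV[match(w, ws$wave)]
    ok <- function(w) ws$valid[match(w, ws$wave)]
    out$p_amp[b] <- amp("P")
    out$r_amp[b] <- amp("R")
    out$s_amp[b] <- amp("S")
    out$t_amp[b] <- amp("T")
    out$p_dur_ms[b] <- attr(ws, "p_duration_ms")
    out$p_valid[b] <- ok("P")
    out$r_valid[b] <- ok("R")
    out$s_valid[b] <- ok("S")
    out$dur_valid[b] <- is.finite(attr(ws, "p_duration_ms"))
  }
  out
}
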