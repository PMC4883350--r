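## Pan-Tompkins style QRS detection and beat segmentation.
##
## Fixed stage order: DC removal / normalization -> 5-15 Hz bandpass ->
## five-point derivative -> squaring -> moving-window integration ->
## adaptive thresholding, followed by refinement of each trigger to the
## local raw-signal maximum so that amplitudes feed the feature extractor
## undistorted.

filtered_signal <- function(values, stage, sampling_rate,
                            degenerate = FALSE) {
  structure(list(values = as.numeric(values), stage = stage,
                 sampling_rate = sampling_rate, degenerate = degenerate),
            class = "filtered_signal")
}

sig_values <- function(x) {
  if (inherits(x, "filtered_signal")) x$values
  else if (inherits(x, "ecg_record")) x$voltage
  else as.numeric(x)
}

#' Remove DC offset and normalize amplitude
#'
#' Subtracts the mean and divides by the maximum absolute value, so the
#' output has zero mean and unit peak amplitude.  A constant input has no
#' waveform to preserve: it maps to all zeros and is flagged degenerate.
#'
#' @param x numeric signal, `filtered_signal`, or [ecg_record()].
#' @param sampling_rate sampling rate (Hz); taken from `x` when it carries
#'   one.
#' @return A `filtered_signal` (stage `"dc_removed"`) with a `degenerate`
#'   flag.
#' @export
remove_dc_and_normalize <- function(x, sampling_rate = NULL) {
  fs <- sampling_rate %||% attr_fs(x)
  v <- sig_values(x)
  if (length(v) == 0) stop("empty signal")
  v <- v - mean(v)
  m <- max(abs(v))
  if (m < .Machine$double.eps) {
    return(filtered_signal(numeric(length(v)), "dc_removed", fs,
                           degenerate = TRUE))
  }
  filtered_signal(v / m, "dc_removed", fs)
}

attr_fs <- function(x) {
  if (inherits(x, "ecg_record")) x$sampling_rate
  else if (inherits(x, "filtered_signal")) x$sampling_rate
  else NA_real_
}

#' Band-pass filter for QRS energy
#'
#' Zero-phase (forward-backward) 2nd-order Butterworth band-pass.  The
#' default 5--15 Hz band brackets the QRS energy spectrum while rejecting
#' baseline wander, P/T energy, and powerline interference.
#'
#' @param x signal (numeric, `filtered_signal`, or [ecg_record()]).
#' @param fs sampling rate (Hz); required when `x` is a bare vector.
#' @param low,high band edges (Hz); `fs` must exceed `2 * high`.
#' @return A `filtered_signal` (stage `"bandpassed"`).
#' @export
bandpass_filter <- function(x, fs = NULL, low = 5, high = 15) {
  fs <- fs %||% attr_fs(x)
  if (is.na(fs)) stop("sampling rate required")
  if (fs <= 2 * high) stop("sampling rate too low for the requested band")
  v <- sig_values(x)
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  filtered_signal(signal::filtfilt(bf, v), "bandpassed", fs)
}

#' Five-point derivative filter
#'
#' `y(n) = (fs / 8) * (-x(n-2) - 2 x(n-1) + 2 x(n+1) + x(n+2))`, the
#' classic QRS-slope estimator; edges use symmetric padding.
#'
#' @param x signal.
#' @param fs sampling rate (Hz).
#' @return A `filtered_signal` (stage `"differentiated"`).
#' @export
derivative_filter <- function(x, fs = NULL) {
  fs <- fs %||% attr_fs(x)
  if (is.na(fs)) stop("sampling rate required")
  v <- sig_values(x)
  n <- length(v)
  if (n < 5) stop("derivative filter needs at least 5 samples")
  xp <- c(v[2], v[1], v, v[n], v[n - 1])  # symmetric padding
  i <- seq_len(n) + 2
  y <- (-xp[i - 2] - 2 * xp[i - 1] + 2 * xp[i + 1] + xp[i + 2]) * fs / 8
  filtered_signal(y, "differentiated", fs)
}

#' Square a signal elementwise
#'
#' Makes every sample nonnegative and emphasizes large slopes.
#'
#' @param x signal.
#' @param fs sampling rate (Hz), optional bookkeeping.
#' @return A `filtered_signal` (stage `"squared"`).
#' @export
square_signal <- function(x, fs = NULL) {
  fs <- fs %||% attr_fs(x)
  filtered_signal(sig_values(x)^2, "squared", fs)
}

#' Moving-window integration
#'
#' Trailing mean over `round(window_ms * fs / 1000)` samples (zero-padded
#' before the first sample), turning the squared slope train into an
#' energy envelope whose plateaus mark QRS complexes.
#'
#' @param x signal.
#' @param fs sampling rate (Hz).
#' @param window_ms integration window (ms); must span at least 1 sample.
#' @return A `filtered_signal` (stage `"integrated"`).
#' @export
moving_window_integrate <- function(x, fs = NULL, window_ms = 150) {
  fs <- fs %||% attr_fs(x)
  if (is.na(fs)) stop("sampling rate required")
  v <- sig_values(x)
  w <- round(window_ms * fs / 1000)
  if (w < 1) stop("integration window spans less than one sample")
  cs <- cumsum(c(rep(0, w), v))
  y <- (cs[seq_along(v) + w] - cs[seq_along(v)]) / w
  filtered_signal(y, "integrated", fs)
}

# local maxima with a minimum separation (samples); ties resolve earliest
local_maxima <- function(v, min_sep) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] >= v[1:(n - 2)] &
                  v[2:(n - 1)] > v[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= min_sep) {
      keep <- c(keep, i)
      last <- i
    } else if (v[i] > v[keep[length(keep)]]) {
      keep[length(keep)] <- i
      last <- i
    }
  }
  keep
}

#' Detect R peaks
#'
#' Runs the full detection chain (normalize, band-pass, derivative,
#' square, integrate) and thresholds the integrated envelope with running
#' signal/noise peak estimates (`threshold = noise + 0.25 (signal -
#' noise)`, exponential update with gain 1/8), a 200 ms refractory period,
#' and a search-back pass at half threshold when a gap exceeds 1.66 times
#' the running median R-R.  Each accepted trigger is delay-compensated for
#' the trailing integration window and refined to the local maximum of the
#' DC-removed raw signal within +/-50 ms.  Thresholds adapt to the
#' normalized envelope, so detection is invariant to amplitude scaling of
#' the input.
#'
#' @param record an [ecg_record()] at least 5 s long.
#' @return Integer vector of R-peak sample indices (possibly empty, with a
#'   warning when nothing is found).
#' @export
detect_r_peaks <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$sampling_rate
  n <- length(record$voltage)
  if (n / fs < 5) stop("record must be at least 5 s long")
  dc <- remove_dc_and_normalize(record)
  if (dc$degenerate) {
    warning("flat record: no R peaks found")
    return(integer(0))
  }
  mwi <- moving_window_integrate(
    square_signal(derivative_filter(bandpass_filter(dc))), fs)
  env <- mwi$values
  refr <- round(0.2 * fs)
  peaks <- local_maxima(env, min_sep = round(0.15 * fs))
  if (length(peaks) == 0) {
    warning("no R peaks found")
    return(integer(0))
  }
  learn <- env[seq_len(min(n, round(2 * fs)))]
  spk <- max(learn) * 0.75
  npk <- mean(learn) * 0.5
  accepted <- integer(0)
  pending <- integer(0)  # sub-threshold peaks since the last QRS
  for (i in peaks) {
    thr <- npk + 0.25 * (spk - npk)
    if (length(accepted) > 0 && i - accepted[length(accepted)] < refr) {
      next
    }
    if (env[i] > thr) {
      accepted <- c(accepted, i)
      spk <- 0.125 * env[i] + 0.875 * spk
      pending <- integer(0)
    } else {
      pending <- c(pending, i)
      npk <- 0.125 * env[i] + 0.875 * npk
      # search-back: a long silence means a missed beat
      if (length(accepted) >= 2) {
        rr_med <- stats::median(diff(accepted))
        gap_from <- accepted[length(accepted)]
        if (i - gap_from > 1.66 * rr_med && length(pending) > 0) {
          ok <- pending[env[pending] > 0.5 * thr &
                          pending - gap_from >= refr]
          if (length(ok) > 0) {
            best <- ok[which.max(env[ok])]
            accepted <- c(accepted, best)
            accepted <- sort(accepted)
            spk <- 0.25 * env[best] + 0.75 * spk
            pending <- pending[pending > best]
          }
        }
      }
    }
  }
  if (length(accepted) == 0) {
    warning("no R peaks found")
    return(integer(0))
  }
  # delay-compensate the trailing integration window, then refine to the
  # raw-signal local maximum within +/-50 ms
  delay <- round(0.075 * fs)
  half <- round(0.05 * fs)
  raw <- dc$values
  refined <- vapply(accepted, function(i) {
    c0 <- max(1L, as.integer(i) - delay)
    lo <- max(1L, c0 - half)
    hi <- min(n, c0 + half)
    as.integer(lo + which.max(raw[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period on the refined indices
  if (length(refined) > 1) {
    keep <- c(TRUE, diff(refined) >= refr)
    while (!all(keep)) {
      drop <- which(!keep)[1]
      a <- refined[drop - 1]
      b <- refined[drop]
      refined <- refined[-(if (raw[a] >= raw[b]) drop else drop - 1)]
      keep <- c(TRUE, diff(refined) >= refr)
    }
  }
  refined
}

#' Split a record into one-beat segments
#'
#' Beat boundaries fall at the midpoints between adjacent R peaks; the
#' first and last beats extend half the median R-R interval outwards
#' (clipped to the record).  Segments are half-open `[start, end)`, tile
#' the spanned region, and contain their R peak.
#'
#' @param record an [ecg_record()].
#' @param r_indices integer R-peak sample indices (at least 2).
#' @return A `data.frame` with columns `start`, `end`, `r` (sample
#'   indices).
#' @export
segment_beats <- function(record, r_indices) {
  stopifnot(inherits(record, "ecg_record"))
  r <- sort(as.integer(r_indices))
  if (length(r) < 2) stop("at least 2 R peaks are required")
  n <- length(record$voltage)
  med_rr <- stats::median(diff(r))
  mids <- floor((r[-length(r)] + r[-1]) / 2)
  start <- c(max(1L, r[1] - as.integer(round(med_rr / 2))), mids)
  end <- c(mids, min(n + 1L, r[length(r)] + as.integer(round(med_rr / 2))))
  data.frame(start = as.integer(start), end = as.integer(end), r = r)
}

#' Drop the unstable start of a record
#'
#' Removes the first `seconds` of signal (measurement stabilization) and
#' shifts the ground-truth annotations accordingly.
#'
#' @param record an [ecg_record()].
#' @param seconds seconds to discard (default 30).
#' @return A trimmed [ecg_record()].
#' @export
discard_initial <- function(record, seconds = 30) {
  stopifnot(inherits(record, "ecg_record"), seconds >= 0)
  if (seconds == 0) return(record)
  fs <- record$sampling_rate
  k <- round(seconds * fs)
  if (k >= length(record$voltage)) stop("discard exceeds record length")
  bt <- record$beat_times
  if (!is.null(bt)) {
    bt <- bt[bt >= seconds] - k / fs
    if (length(bt) == 0) bt <- NULL
  }
  out <- record
  out$voltage <- record$voltage[(k + 1):length(record$voltage)]
  out$beat_times <- bt
  out
}

#' Flag beats with irregular neighboring R-R intervals
#'
#' A beat is kept only if every R-R interval to an existing neighbor lies
#' within 40% of the record's median R-R; corrupted stretches (electrode
#' movement, missed or spurious detections) are thereby excluded from
#' feature extraction.
#'
#' @param r_indices integer R-peak sample indices.
#' @param max_dev maximal fractional deviation from the median R-R.
#' @return Logical keep-vector aligned with `r_indices`.
#' @export
reject_corrupt_beats <- function(r_indices, max_dev = 0.4) {
  r <- as.numeric(r_indices)
  nb <- length(r)
  if (nb < 3) return(rep(TRUE, nb))
  rr <- diff(r)
  med <- stats::median(rr)
  ok_int <- abs(rr - med) / med <= max_dev
  keep <- rep(TRUE, nb)
  keep[1] <- ok_int[1]
  keep[nb] <- ok_int[nb - 1]
  if (nb > 2) {
    mid <- 2:(nb - 1)
    keep[mid] <- ok_int[mid - 1] & ok_int[mid]
  }
  keep
}
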