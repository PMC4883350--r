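## 10-dimensional feature vectors over sliding windows of consecutive
## beats, and dataset assembly (balancing, standardization).
##
## One heartbeat alone cannot carry a mean, a variance, or a dispersion,
## so each feature vector summarizes a window of W consecutive valid beats
## (default W = 10, stride 1): means and population variances of the P, R,
## S peak amplitudes and of the W-1 R-R intervals, plus the maximal P
## duration (Pmax) and the P-wave dispersion (Pd) over the window.

FEATURE_NAMES <- c("mean_P_amp", "var_P_amp", "mean_R_amp", "var_R_amp",
                   "mean_S_amp", "var_S_amp", "mean_RR", "var_RR",
                   "Pmax", "Pd")

pop_var <- function(x) mean((x - mean(x))^2)

#' Extract the 10 features of one beat window
#'
#' @param beats a `data.frame` of `W >= 3` consecutive delineated beats
#'   (rows of [delineate_record()] output), all with valid P, R, S and
#'   P-duration measurements.
#' @return Named numeric vector of length 10 in the canonical order
#'   `mean_P_amp, var_P_amp, mean_R_amp, var_R_amp, mean_S_amp, var_S_amp,
#'   mean_RR, var_RR, Pmax, Pd` (amplitudes in mV/mV^2, intervals in
#'   s/s^2, durations in ms).
#' @export
extract_window_features <- function(beats) {
  if (nrow(beats) < 3) stop("a feature window needs at least 3 beats")
  need <- c("p_amp", "r_amp", "s_amp", "p_dur_ms", "r_time_s")
  stopifnot(all(need %in% names(beats)))
  if (any(!is.finite(as.matrix(beats[need])))) {
    stop("feature window contains invalid beat measurements")
  }
  rr <- diff(beats$r_time_s)
  pp <- compute_pmax_pd(beats$p_dur_ms)
  out <- c(mean(beats$p_amp), pop_var(beats$p_amp),
           mean(beats$r_amp), pop_var(beats$r_amp),
           mean(beats$s_amp), pop_var(beats$s_amp),
           mean(rr), pop_var(rr),
           pp[["Pmax"]], pp[["Pd"]])
  names(out) <- FEATURE_NAMES
  out
}

new_dataset <- function(X, y, groups, stats = NULL) {
  stopifnot(nrow(X) == length(y))
  structure(list(X = X, y = as.integer(y), groups = groups,
                 stats = stats),
            class = "ddd_dataset")
}

#' @export
print.ddd_dataset <- function(x, ...) {
  cat(sprintf("<ddd_dataset> %d windows x %d features (class 0: %d, class 1: %d)%s\n",
              nrow(x$X), ncol(x$X), sum(x$y == 0), sum(x$y == 1),
              if (is.null(x$stats)) "" else ", standardized"))
  invisible(x)
}

#' Build a labeled window-feature dataset from records
#'
#' Runs (or reuses) preprocessing and delineation per record, drops beats
#' with irregular R-R neighbors or invalid P/R/S measurements, and slides
#' a window of `W` contiguous valid beats (stride `stride`) over each
#' record; each window yields one feature vector labeled with the record's
#' class.  Records without a class label are skipped with a warning.
#'
#' @param records list of [ecg_record()]s (labeled).
#' @param W window length in beats (`>= 3`).
#' @param stride window stride in beats.
#' @param trim_seconds initial seconds discarded per record before
#'   detection (see [discard_initial()]).
#' @return A `ddd_dataset`: feature matrix `X` (n x 10), labels `y` in
#'   {0,1}, and `groups` (subject id when present, else record index) for
#'   group-aware cross-validation.
#' @export
build_dataset <- function(records, W = 10, stride = 1, trim_seconds = 30) {
  stopifnot(W >= 3, stride >= 1)
  rows <- list()
  labs <- integer(0)
  grps <- character(0)
  for (k in seq_along(records)) {
    rec <- records[[k]]
    if (is.null(rec$class_label)) {
      warning(sprintf("record %d has no class label; skipped", k))
      next
    }
    rec_t <- discard_initial(rec, trim_seconds)
    r_idx <- detect_r_peaks(rec_t)
    if (length(r_idx) < W + 2) next
    segs <- segment_beats(rec_t, r_idx)
    tab <- delineate_record(rec_t, segs)
    keep <- reject_corrupt_beats(segs$r) &
      tab$p_valid & tab$r_valid & tab$s_valid & tab$dur_valid
    grp <- as.character(rec$meta$subject %||% k)
    nb <- nrow(tab)
    b <- 1L
    while (b + W - 1L <= nb) {
      span <- b:(b + W - 1L)
      if (all(keep[span])) {
        rows[[length(rows) + 1L]] <- extract_window_features(tab[span, ])
        labs <- c(labs, rec$class_label)
        grps <- c(grps, grp)
        b <- b + stride
      } else {
        b <- b + 1L
      }
    }
  }
  if (length(rows) == 0) stop("no feature windows could be extracted")
  X <- do.call(rbind, rows)
  colnames(X) <- FEATURE_NAMES
  new_dataset(X, labs, grps)
}

#' Subsample the majority class to balance a dataset
#'
#' An unequal class split biases the margin of an SVM, so the majority
#' class is randomly subsampled (seeded, without replacement) down to the
#' minority count.  Feature values are untouched; only row membership
#' changes.
#'
#' @param ds a `ddd_dataset`.
#' @param seed integer seed.
#' @return A balanced `ddd_dataset`.
#' @export
balance_classes <- function(ds, seed = 1) {
  stopifnot(inherits(ds, "ddd_dataset"))
  n0 <- sum(ds$y == 0)
  n1 <- sum(ds$y == 1)
  if (n0 == n1) return(ds)
  maj <- if (n0 > n1) 0L else 1L
  keep_min <- which(ds$y != maj)
  maj_idx <- which(ds$y == maj)
  pick <- with_seed(seed, sample(maj_idx, min(n0, n1)))
  sel <- sort(c(keep_min, pick))
  new_dataset(ds$X[sel, , drop = FALSE], ds$y[sel], ds$groups[sel],
              ds$stats)
}

#' Fit per-feature standardization statistics
#'
#' @param ds a `ddd_dataset` of training rows.
#' @return List with `mean`, `sd` (per feature) and `constant` flags;
#'   constant features get `sd = 1` so they map to zeros.
#' @export
fit_standardization <- function(ds) {
  stopifnot(inherits(ds, "ddd_dataset"))
  mu <- colMeans(ds$X)
  sd <- apply(ds$X, 2, stats::sd)
  constant <- sd < .Machine$double.eps
  sd[constant] <- 1
  list(mean = mu, sd = sd, constant = constant)
}

#' Standardize a dataset with given (training-fold) statistics
#'
#' Z-scores each feature with statistics fit on training rows only;
#' validation rows must be transformed with the training statistics, never
#' their own.  The 10 features span millivolts to milliseconds, and the
#' polynomial and radial-basis kernels are scale-sensitive, so
#' standardization precedes every kernel evaluation.
#'
#' @param ds a `ddd_dataset`.
#' @param stats output of [fit_standardization()]; defaults to statistics
#'   fit on `ds` itself (training use).
#' @return A standardized `ddd_dataset` carrying `stats`.
#' @export
standardize_dataset <- function(ds, stats = NULL) {
  stopifnot(inherits(ds, "ddd_dataset"))
  st <- stats %||% fit_standardization(ds)
  X <- sweep(sweep(ds$X, 2, st$mean), 2, st$sd, "/")
  new_dataset(X, ds$y, ds$groups, st)
}

#' Apply stored standardization to a bare feature matrix
#'
#' @param X numeric matrix (n x 10) in canonical feature order.
#' @param stats output of [fit_standardization()].
#' @return Standardized matrix.
#' @export
apply_standardization <- function(X, stats) {
  sweep(sweep(X, 2, stats$mean), 2, stats$sd, "/")
}

#' Write / read a feature table as TSV
#'
#' Round-trips the feature matrix, labels, and groups losslessly through
#' a tab-separated file with the 10 canonical column names plus `label`
#' and `group`.
#'
#' @param ds a `ddd_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "ddd_dataset"))
  df <- as.data.frame(ds$X)
  df$label <- ds$y
  df$group <- ds$groups
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#",
                          colClasses = c(rep("numeric", 10), "integer",
                                         "character"))
  stopifnot(all(FEATURE_NAMES %in% names(df)))
  X <- as.matrix(df[FEATURE_NAMES])
  new_dataset(X, df$label, df$group)
}
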