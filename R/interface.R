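## File formats, run configuration, and the end-to-end pipeline driver.
## Records travel as CSV (`time_s,voltage_mV`) with a plain-text sidecar
## of beat annotations; feature tables as TSV; models and reports as
## JSON.  Every artifact embeds the configuration hash and root seed.

#' Read an ECG record from CSV
#'
#' Expects columns `time_s` and `voltage_mV`; the sampling rate is
#' inferred from the median time step.  Non-monotone time stamps are
#' rejected.
#'
#' @param path CSV file path.
#' @param min_seconds minimum accepted duration (seconds; default 0 --
#'   downstream detection enforces its own 5 s floor).
#' @return An [ecg_record()]; a sidecar annotation file `<path>.ann`
#'   (one beat time in seconds per line), when present, populates
#'   `beat_times`.
#' @export
load_ecg_csv <- function(path, min_seconds = 0) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "voltage_mV") %in% names(df))) {
    stop("ECG CSV must have columns time_s and voltage_mV")
  }
  dt <- diff(df$time_s)
  if (length(dt) > 0 && any(dt <= 0)) {
    stop("time_s must be strictly increasing")
  }
  fs <- if (length(dt) > 0) 1 / stats::median(dt) else 1
  if (nrow(df) / fs < min_seconds) {
    stop(sprintf("record shorter than %g s", min_seconds))
  }
  ann_path <- paste0(path, ".ann")
  bt <- NULL
  if (file.exists(ann_path)) {
    bt <- as.numeric(readLines(ann_path))
    bt <- bt[is.finite(bt)]
    if (length(bt) == 0) bt <- NULL
  }
  ecg_record(df$voltage_mV, fs, beat_times = bt,
             meta = list(source = path))
}

#' Write an ECG record to CSV (plus annotation sidecar)
#'
#' @param record an [ecg_record()].
#' @param path CSV output path; ground-truth beat times, when present,
#'   go to `<path>.ann` (one time in seconds per line).
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  n <- length(record$voltage)
  df <- data.frame(time_s = (seq_len(n) - 1) / record$sampling_rate,
                   voltage_mV = record$voltage)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(record$beat_times)) {
    writeLines(format(record$beat_times, digits = 15, trim = TRUE,
                      scientific = FALSE),
               paste0(path, ".ann"))
  }
  invisible(path)
}

#' Write a cohort to a directory
#'
#' One CSV (+ annotation sidecar) per record plus a JSON manifest listing
#' file, subject, session, and class for each, with the configuration
#' hash and seed for provenance.
#'
#' @param records list of [ecg_record()]s (e.g. from [generate_cohort()]).
#' @param dir output directory (created if missing).
#' @param cfg the [cohort_config()] that produced the records.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(records, dir, cfg) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    fn <- sprintf("record_%03d_s%s_v%s_c%d.csv", i,
                  rec$meta$subject %||% 0, rec$meta$session %||% 0,
                  rec$class_label)
    write_ecg_csv(rec, file.path(dir, fn))
    entries[[i]] <- list(file = fn, subject = rec$meta$subject,
                         session = rec$meta$session,
                         class = rec$class_label)
  }
  manifest <- list(config_hash = config_hash(unclass(cfg)[
    setdiff(names(cfg), "morphology")]),
    seed = cfg$seed, records = entries)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

RUN_CONFIG_KEYS <- c("cohort", "window", "stride", "trim_seconds",
                     "kernels", "C", "k", "seed", "out_dir")

#' Load and validate a run configuration
#'
#' YAML with keys `cohort` (fields of [cohort_config()]), `window`,
#' `stride`, `trim_seconds`, `kernels` (`"all"` or a list of families),
#' `C`, `k`, `seed`, `out_dir`.  Unknown keys are rejected.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return A validated run-config list with defaults filled in.
#' @export
load_run_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  raw <- raw %||% list()
  unknown <- setdiff(names(raw), RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown run-config keys: ", paste(unknown, collapse = ", "))
  }
  seed <- raw$seed %||% 42
  coh <- raw$cohort %||% list()
  bad <- setdiff(names(coh),
                 setdiff(names(formals(cohort_config)), "morphology"))
  if (length(bad) > 0) {
    stop("unknown cohort keys: ", paste(bad, collapse = ", "))
  }
  coh$seed <- coh$seed %||% substream_seed(seed, "simulate")
  cfg <- list(cohort = do.call(cohort_config, coh),
              window = raw$window %||% 10,
              stride = raw$stride %||% 1,
              trim_seconds = raw$trim_seconds %||% 30,
              kernels = raw$kernels %||% "all",
              C = raw$C %||% 1,
              k = raw$k %||% 10,
              seed = seed,
              out_dir = raw$out_dir %||% "ecgddd_out")
  stopifnot(cfg$window >= 3, cfg$stride >= 1, cfg$k >= 2, cfg$C > 0)
  cfg
}

#' Run the full pipeline
#'
#' Simulate (or ingest) a cohort, preprocess and delineate every record,
#' extract window features, cross-validate all eight kernel variants, and
#' write every stage's artifact: `features.tsv`, `comparison.json`
#' (8-row kernel table), and `report.json` (config, hash, seed, stage
#' log).
#'
#' @param cfg run configuration (path or list, see [load_run_config()]).
#' @param records optional pre-loaded list of [ecg_record()]s; when given,
#'   simulation is skipped.
#' @param write_records also write the simulated cohort CSVs (default
#'   FALSE; they are large and reproducible from the seed).
#' @return Invisibly, a list with the dataset, the comparison table, and
#'   the output paths.
#' @export
run_pipeline <- function(cfg, records = NULL, write_records = FALSE) {
  if (is.character(cfg) || !inherits(cfg$cohort %||% NULL,
                                     "cohort_config")) {
    cfg <- load_run_config(cfg)
  }
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  hash <- config_hash(list(window = cfg$window, stride = cfg$stride,
                           k = cfg$k, C = cfg$C, seed = cfg$seed,
                           cohort_seed = cfg$cohort$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.null(records)) {
    records <- stage("simulate", generate_cohort(cfg$cohort))
    if (write_records) {
      stage("simulate", write_cohort(records, file.path(out, "cohort"),
                                     cfg$cohort))
    }
  }
  ds <- stage("features",
              build_dataset(records, W = cfg$window, stride = cfg$stride,
                            trim_seconds = cfg$trim_seconds))
  fpath <- file.path(out, "features.tsv")
  write_feature_tsv(ds, fpath)
  comparison <- stage("cv",
                      compare_kernels(ds, k = cfg$k,
                                      seed = substream_seed(cfg$seed,
                                                            "cv"),
                                      C = cfg$C))
  cpath <- file.path(out, "comparison.json")
  jsonlite::write_json(list(config_hash = hash, seed = cfg$seed,
                            table = comparison),
                       cpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  rpath <- file.path(out, "report.json")
  jsonlite::write_json(
    list(config_hash = hash, seed = cfg$seed,
         n_records = length(records), n_windows = nrow(ds$X),
         class_counts = as.list(table(ds$y)),
         best_kernel = comparison$kernel_id[comparison$best]),
    rpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = ds, comparison = comparison,
                 paths = list(features = fpath, comparison = cpath,
                              report = rpath)))
}
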