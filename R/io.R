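#' Write a record as delimited text with a JSON sidecar
#'
#' One sample per line (microvolts) in `<path>`, plus `<path>.json` holding
#' the sampling rate, channel label and, for synthetic records, the
#' generator configuration. Ground-truth phase and generator components are
#' not persisted; regenerate from the stored configuration when needed.
#'
#' @param record an [eeg_record()].
#' @param path output text file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  if (!inherits(record, "eeg_record"))
    stop("`record` must be an eeg_record", call. = FALSE)
  writeLines(formatC(record$samples, format = "g", digits = 17), path)
  meta <- list(fs = record$fs, label = record$label)
  if (!is.null(record$meta)) meta$config <- unclass(record$meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a record written by [write_record()]
#'
#' @param path text file path; `<path>.json` must exist unless `fs` is
#'   given.
#' @param fs sampling rate in Hz, overriding the sidecar.
#' @return an [eeg_record()].
#' @export
read_record <- function(path, fs = NULL) {
  samples <- as.numeric(readLines(path))
  sidecar <- paste0(path, ".json")
  label <- "Oz"
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(fs)) fs <- meta$fs
    if (!is.null(meta$label)) label <- meta$label
  }
  if (is.null(fs))
    stop("no sampling rate: sidecar missing and `fs` not given",
         call. = FALSE)
  eeg_record(samples, fs, label = label)
}

#' Write trigger events to CSV
#'
#' @param events trigger-event data frame (from [run_closed_loop()] or
#'   [pipeline_step()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Write run summary statistics to JSON
#'
#' @param stats a [phase_summary()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a phase-triggered response to CSV
#'
#' Columns `sample_offset` (samples relative to the trigger) and
#' `mean_amplitude` (microvolts).
#'
#' @param x a [ptr()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ptr_csv <- function(x, path) {
  off <- seq_along(x$waveform) - 1L - x$half_window
  write.csv(data.frame(sample_offset = off, mean_amplitude = x$waveform),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a Watson comparison to JSON
#'
#' @param x a [watson_u2()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Published per-participant summary statistics
#'
#' Summary tables from a five-participant closed-loop alpha-phase-targeting
#' EEG experiment (resting and visual conditions; Yule-Walker and LMS
#' predictors, peak and trough targets): per-participant trial counts, PLF
#' and Rayleigh Z values, mean trigger phases, and two-sample Watson
#' U-squared comparisons between the two predictors. Shipped as plain CSV
#' under `inst/extdata/reference/`; participant-level re-aggregation (mean
#' Z via [zplf_all()], mean angles via [circular_mean()]) reproduces the
#' published group rows.
#'
#' @return a list of data frames: `zplf` (condition, participant, method,
#'   target, n_trials, plf, zplf), `angles` (condition, participant,
#'   method, target, mean_angle_rad) and `watson` (condition, participant,
#'   target, u2).
#' @export
reference_phase_stats <- function() {
  dir <- system.file("extdata", "reference", package = "phaselock",
                     mustWork = TRUE)
  read1 <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  list(zplf = read1("summary_zplf.csv"),
       angles = read1("mean_angles.csv"),
       watson = read1("watson_u2.csv"))
}
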