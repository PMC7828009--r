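#' Configuration of a closed-loop simulation run
#'
#' Bundles the synthetic-signal settings with the online pipeline
#' parameters for one of the four conditions (method YW/LMS crossed with
#' target peak/trough).
#'
#' @param signal a [signal_config()] (its `seed` governs the run).
#' @param method `"yw"` or `"lms"`.
#' @param target `"peak"` or `"trough"`.
#' @param refractory minimum inter-trigger interval, seconds.
#' @param warmup seconds of valid samples before triggers may fire.
#' @param mu LMS step size.
#' @param order AR/LMS model order.
#' @param horizon forward-prediction length, samples.
#' @param phase_extend extra forecast samples beyond time-zero (see
#'   [pipeline_init()]); 0 reads the raw analytic-signal endpoint.
#' @param margin edge-trim margin, samples.
#' @param win sliding-window length, samples.
#' @param fs working (post-decimation) sampling rate, Hz.
#' @param filter_order online FIR bandpass order.
#' @return an object of class `run_config`.
#' @export
run_config <- function(signal = signal_config(duration = 300, seed = 1),
                       method = c("yw", "lms"),
                       target = c("peak", "trough"),
                       refractory = 0.5, warmup = 2, mu = 1e-3,
                       order = 30, horizon = 85, phase_extend = 97,
                       margin = 85, win = 500,
                       fs = 500, filter_order = 128) {
  structure(list(signal = signal, method = match.arg(method),
                 target = match.arg(target), refractory = refractory,
                 warmup = warmup, mu = mu, order = as.integer(order),
                 horizon = as.integer(horizon),
                 phase_extend = as.integer(phase_extend),
                 margin = as.integer(margin),
                 win = as.integer(win), fs = fs,
                 filter_order = as.integer(filter_order)),
            class = "run_config")
}

#' Run the closed loop over a record
#'
#' Generates the synthetic record (or takes a supplied one), decimates it to
#' the working rate, streams it through the online pipeline with a 1-sample
#' hop, and evaluates the emitted triggers against the offline ground-truth
#' phase of the same decimated record (two-pass filter plus Hilbert over the
#' full record). Events falling inside the offline filter's edge margin are
#' excluded from the statistics. Fully reproducible from the signal seed.
#'
#' @param config a [run_config()].
#' @param record optional [eeg_record()]; when `NULL` one is synthesised
#'   from `config$signal`. Records at a higher rate are decimated to
#'   `config$fs`.
#' @return an object of class `run_result` with elements `events` (trigger
#'   data frame), `truth_phases` (offline phase at the retained events),
#'   `stats` ([phase_summary()] of `truth_phases`, or `NULL` with
#'   `no_events = TRUE` when nothing fired), `ptr`, `record` (the decimated
#'   record) and the `config`.
#' @export
run_closed_loop <- function(config, record = NULL) {
  if (!inherits(config, "run_config"))
    stop("`config` must be a run_config", call. = FALSE)
  if (is.null(record)) record <- synth_eeg(config$signal)
  if (record$fs != config$fs) {
    if (record$fs < config$fs)
      stop("record sampled below the working rate", call. = FALSE)
    record <- decimate_record(record, config$fs)
  }
  spec <- filter_spec(band = config$signal$alpha_band,
                      order = config$filter_order, fs = config$fs)
  loop <- cpp_closed_loop(
    record$samples, spec$taps, config$order, config$margin,
    config$horizon, config$phase_extend, config$win,
    if (config$method == "lms") 1L else 0L, config$mu,
    target_phase(config$target),
    as.integer(round(config$refractory * config$fs)),
    as.integer(round(config$warmup * config$fs)), FALSE)
  idx0 <- as.integer(loop$index0)
  events <- data.frame(
    time_s = idx0 / config$fs, sample_index = idx0 + 1L,
    method = rep(config$method, length(idx0)),
    target = rep(config$target, length(idx0)),
    predicted_phase = as.numeric(loop$predicted_phase),
    stringsAsFactors = FALSE)
  truth <- ground_truth_phase(record, band = config$signal$alpha_band,
                              filter_order = config$filter_order)
  edge <- attr(truth, "edge_margin")
  n <- length(record$samples)
  interior <- events$sample_index > edge & events$sample_index <= n - edge
  truth_phases <- truth[events$sample_index[interior]]
  res <- list(events = events, truth_phases = as.numeric(truth_phases),
              n_edge_excluded = sum(!interior),
              record = record, config = config, no_events = FALSE,
              stats = NULL, ptr = NULL)
  if (length(truth_phases) > 0) {
    res$stats <- phase_summary(truth_phases)
  } else {
    res$no_events <- TRUE
    warning("run produced no usable trigger events")
  }
  if (nrow(events) > 0) {
    ok <- events$sample_index > 500 & events$sample_index + 500 <= n
    if (any(ok)) res$ptr <- ptr(record, events)
  }
  class(res) <- "run_result"
  res
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %s/%s: %d triggers over %.0f s\n",
              x$config$method, x$config$target, nrow(x$events),
              length(x$record$samples) / x$record$fs))
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}

#' Compare the phase dispersion of two runs
#'
#' Recenters each run's ground-truth phase sample on its own circular mean
#' (removing mean-direction differences) and applies the two-sample Watson
#' U-squared test, so only the phase variances are compared.
#'
#' @param a,b [run_closed_loop()] results with at least two events each.
#' @return a [watson_u2()] result.
#' @export
compare_runs <- function(a, b) {
  pa <- a$truth_phases; pb <- b$truth_phases
  if (length(pa) < 2L || length(pb) < 2L)
    stop("need at least two events in each run", call. = FALSE)
  watson_u2(recenter_phases(pa), recenter_phases(pb))
}

#' Tabulate one or more runs
#'
#' One row per condition (n, PLF, ZPLF, mean angle, significance) plus a
#' `Mean` row computed with [zplf_all()] and [circular_mean()] when more
#' than one run is given. Runs with no events yield explicit `NA` cells.
#'
#' @param ... [run_closed_loop()] results (or a single list of them).
#' @return a data frame.
#' @export
run_report <- function(...) {
  results <- list(...)
  if (length(results) == 1L && !inherits(results[[1L]], "run_result"))
    results <- results[[1L]]
  if (length(results) == 0L) stop("no results supplied", call. = FALSE)
  row_of <- function(r) {
    s <- r$stats
    data.frame(
      method = r$config$method, target = r$config$target,
      n = if (is.null(s)) NA_integer_ else s$n,
      plf = if (is.null(s)) NA_real_ else s$plf,
      zplf = if (is.null(s)) NA_real_ else s$zplf,
      mean_angle_rad = if (is.null(s)) NA_real_ else s$mean_angle,
      significant = if (is.null(s)) NA else s$significant,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, lapply(results, row_of))
  rownames(tab) <- NULL
  if (nrow(tab) > 1L) {
    ok <- !is.na(tab$zplf)
    mean_row <- data.frame(
      method = "all", target = "mean", n = NA_integer_,
      plf = mean(tab$plf[ok]),
      zplf = if (any(ok)) zplf_all(tab$zplf[ok]) else NA_real_,
      mean_angle_rad = if (any(ok)) circular_mean(tab$mean_angle_rad[ok])
                       else NA_real_,
      significant = NA, stringsAsFactors = FALSE)
    tab <- rbind(tab, mean_row)
  }
  tab
}
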