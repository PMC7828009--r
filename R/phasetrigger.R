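#' Discrete analytic signal
#'
#' Returns `x + i * H(x)` where `H` is the discrete Hilbert transform
#' (negative-frequency DFT components zeroed). The real part equals the
#' input; the argument of the result is the instantaneous phase, 0 rad at a
#' positive peak of a cosine and pi at a trough.
#'
#' @param x numeric vector, length >= 4.
#' @return complex vector, same length as `x`.
#' @export
analytic_signal <- function(x) {
  if (length(x) < 4L)
    stop("input too short for an analytic signal", call. = FALSE)
  as.complex(cpp_analytic(as.numeric(x)))
}

#' Instantaneous phase at time-zero
#'
#' Applies the analytic signal to the full (known + predicted) concatenation
#' of a [prediction_window()] and reads the phase at the final sample.
#'
#' @param window a [prediction_window()].
#' @param method optional tag (`"yw"` or `"lms"`) recorded on the estimate.
#' @param sample_index optional position of time-zero in the parent record.
#' @return an object of class `phase_estimate` with `theta` in `(-pi, pi]`.
#' @export
phase_at_time_zero <- function(window, method = NA_character_,
                               sample_index = NA_integer_) {
  if (!inherits(window, "prediction_window"))
    stop("`window` must be a prediction_window", call. = FALSE)
  z <- analytic_signal(window$samples)
  theta <- wrap_phase(Arg(z[length(z)]))
  structure(list(theta = theta, sample_index = sample_index,
                 method = method),
            class = "phase_estimate")
}

#' Detect a target-phase crossing between successive estimates
#'
#' Fires when the phase advances forward through the target: the wrapped
#' step `delta = wrap(curr - prev)` must be positive but smaller than pi/2
#' (guarding against wrap-around artifacts and noise jumps), and the target
#' must lie within the traversed arc `(prev, prev + delta]`. The target is
#' 0 rad for a positive peak and pi for a trough.
#'
#' @param prev,curr successive phase estimates in `(-pi, pi]` (radians).
#' @param target target phase in radians.
#' @return logical flag.
#' @export
detect_crossing <- function(prev, curr, target = 0) {
  delta <- wrap_phase(curr - prev)
  d <- wrap_phase(target - prev)
  delta > 0 && delta < pi / 2 && d > 0 && d <= delta
}

target_phase <- function(target) {
  switch(match.arg(target, c("peak", "trough")), peak = 0, trough = pi)
}

#' Initialise the online phase-targeting pipeline
#'
#' Creates the mutable state for sample-by-sample processing with
#' [pipeline_step()]: the sliding window buffer, the bandpass
#' specification, the forecaster (Yule-Walker refit per window or persistent
#' adaptive LMS weights), the previous phase estimate and the refractory
#' clock. This R path mirrors the compiled whole-record loop used by
#' [run_closed_loop()] sample for sample.
#'
#' @param spec a [filter_spec()].
#' @param method `"yw"` or `"lms"`.
#' @param target `"peak"` (0 rad) or `"trough"` (pi rad).
#' @param order AR/LMS model order.
#' @param horizon forward-prediction length in samples.
#' @param margin edge-trim margin in samples.
#' @param win sliding-window length in samples.
#' @param phase_extend extra forecast samples beyond time-zero. The phase is
#'   always read at the time-zero index; extending the forecast keeps that
#'   read point clear of the analytic-signal window edge, where the discrete
#'   Hilbert transform's phase is badly biased by spectral leakage. The
#'   default 97 puts time-zero 97 samples inside the window (and makes the
#'   analytic window 512 samples). Set 0 to read the raw endpoint.
#' @param mu LMS step size (applied to RMS-normalised windows).
#' @param refractory minimum interval between triggers, seconds.
#' @param warmup valid samples to process before triggers may fire
#'   (seconds; counted after the buffer first fills).
#' @return an environment of class `phase_pipeline`.
#' @export
pipeline_init <- function(spec = filter_spec(), method = c("yw", "lms"),
                          target = c("peak", "trough"), order = 30,
                          horizon = 85, margin = 85, win = 500,
                          phase_extend = 97,
                          mu = 1e-3, refractory = 0.5, warmup = 2) {
  method <- match.arg(method)
  target <- match.arg(target)
  p <- new.env(parent = emptyenv())
  p$spec <- spec
  p$method <- method
  p$target <- target
  p$target_rad <- target_phase(target)
  p$order <- as.integer(order)
  p$horizon <- as.integer(horizon)
  p$phase_extend <- as.integer(phase_extend)
  p$margin <- as.integer(margin)
  p$win <- as.integer(win)
  p$mu <- mu
  p$fs <- spec$fs
  p$refractory_samples <- as.integer(round(refractory * spec$fs))
  p$warmup_steps <- as.integer(round(warmup * spec$fs))
  p$buffer <- numeric(0)
  p$weights <- numeric(order)
  p$prev <- NA_real_
  p$valid <- 0L
  p$seen <- 0L
  p$last_trigger <- -Inf
  class(p) <- "phase_pipeline"
  p
}

# One window evaluation; returns the phase at time-zero and whether the
# window was degenerate (all-constant, no AR fit possible).
evaluate_window <- function(p, window) {
  w <- window - mean(window)
  f <- as.numeric(cpp_fir_two_pass(w, p$spec$taps))
  trimmed <- f[(p$margin + 1L):(length(f) - p$margin)]
  L <- length(trimmed)
  degenerate <- FALSE
  if (p$method == "lms") {
    rms <- sqrt(mean(trimmed^2))
    if (rms > 0) {
      tn <- trimmed / rms
      hist_new_first <- tn[(L - 1L):(L - p$order)]
      y <- sum(p$weights * hist_new_first)
      e <- tn[L] - y
      p$weights <- p$weights + 2 * p$mu * e * hist_new_first
    }
    coef <- p$weights
  } else {
    r <- as.numeric(cpp_autocov(trimmed, p$order))
    if (r[1] > 1e-300) {
      coef <- as.numeric(cpp_levinson(r)$coeffs)
    } else {
      coef <- numeric(p$order)
      degenerate <- TRUE
    }
  }
  fc <- ar_forecast(coef, trimmed, p$horizon + p$phase_extend)
  conc <- c(trimmed, fc)
  z <- analytic_signal(conc)
  theta <- wrap_phase(Arg(z[L + p$horizon]))  # time-zero index
  list(theta = theta, degenerate = degenerate)
}

#' Feed samples through the online pipeline
#'
#' Appends a block of 500 Hz samples; once the window buffer is full, every
#' new sample triggers a full window evaluation (demean, two-pass bandpass,
#' trim, forecast, phase at time-zero) and a crossing check against the
#' target phase, subject to warm-up and the refractory interval.
#'
#' @param p a [pipeline_init()] state (modified in place).
#' @param block numeric vector of new samples at the working rate.
#' @return a data frame of trigger events emitted while processing the
#'   block (possibly zero rows) with columns `time_s`, `sample_index`
#'   (1-based), `method`, `target`, `predicted_phase`.
#' @export
pipeline_step <- function(p, block) {
  if (!inherits(p, "phase_pipeline"))
    stop("`p` must come from pipeline_init()", call. = FALSE)
  events <- list()
  for (s in as.numeric(block)) {
    p$seen <- p$seen + 1L
    p$buffer <- c(p$buffer, s)
    nb <- length(p$buffer)
    if (nb > p$win) {
      p$buffer <- p$buffer[(nb - p$win + 1L):nb]
      nb <- p$win
    }
    if (nb < p$win) next
    ev <- evaluate_window(p, p$buffer)
    p$valid <- p$valid + 1L
    t0 <- p$seen - 1L  # 0-based index of the newest sample
    if (!is.na(p$prev) && !ev$degenerate && p$valid > p$warmup_steps &&
        (t0 - p$last_trigger) >= p$refractory_samples &&
        detect_crossing(p$prev, ev$theta, p$target_rad)) {
      events[[length(events) + 1L]] <- data.frame(
        time_s = t0 / p$fs, sample_index = p$seen,
        method = p$method, target = p$target,
        predicted_phase = ev$theta, stringsAsFactors = FALSE)
      p$last_trigger <- t0
    }
    p$prev <- ev$theta
  }
  if (length(events) == 0L)
    return(data.frame(time_s = numeric(0), sample_index = integer(0),
                      method = character(0), target = character(0),
                      predicted_phase = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, events)
}
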