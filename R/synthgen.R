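#' Configuration of the synthetic alpha-EEG generator
#'
#' Describes a single-channel recording to be synthesised: an alpha-band
#' oscillation embedded in 1/f-type background noise at a prescribed
#' band-limited signal-to-noise ratio, emulating an occipital channel
#' digitised at 2 kHz.
#'
#' @param duration recording length in seconds (> 0).
#' @param fs_acq acquisition sampling rate in Hz (default 2000); must exceed
#'   twice the upper alpha band edge.
#' @param alpha_center centre frequency of the alpha oscillation in Hz.
#' @param alpha_band numeric length-2, lower and upper band edges in Hz;
#'   must bracket `alpha_center`.
#' @param alpha_bandwidth Gaussian spectral width (sigma, Hz) of the alpha
#'   peak around `alpha_center` (default 1; about 2.4 Hz full width at half
#'   maximum, emulating a typical occipital alpha resonance). Larger values
#'   give faster amplitude/frequency drift; `Inf` spreads the oscillation
#'   evenly over the whole `alpha_band`.
#' @param snr_db band-limited SNR in dB: the ratio of alpha-band (8-13 Hz)
#'   power of the oscillation component to alpha-band power of the noise
#'   component. `Inf` disables the noise entirely.
#' @param noise_exponent spectral slope of the background: power spectral
#'   density proportional to `1/f^noise_exponent` (default 1, i.e. pink).
#' @param alpha_model `"stochastic"` (white noise band-limited to
#'   `alpha_band`, giving realistic amplitude and frequency drift) or
#'   `"cosine"` (deterministic pure tone at `alpha_center`, for exact tests).
#' @param seed integer seed; identical seeds give bit-identical records.
#' @return an object of class `signal_config`.
#' @seealso [synth_eeg()]
#' @export
signal_config <- function(duration, fs_acq = 2000, alpha_center = 10,
                          alpha_band = c(8, 13), alpha_bandwidth = 1,
                          snr_db = 10, noise_exponent = 1,
                          alpha_model = c("stochastic", "cosine"),
                          seed = NULL) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(fs_acq, "fs_acq", positive = TRUE)
  stopifnot_scalar(alpha_center, "alpha_center", positive = TRUE)
  if (length(alpha_band) != 2L || !all(is.finite(alpha_band)) ||
      alpha_band[1] <= 0 || alpha_band[1] >= alpha_band[2])
    stop("`alpha_band` must be an increasing pair of positive frequencies",
         call. = FALSE)
  if (fs_acq <= 2 * alpha_band[2])
    stop("`fs_acq` must exceed twice the upper band edge", call. = FALSE)
  if (alpha_center <= alpha_band[1] || alpha_center >= alpha_band[2])
    stop("`alpha_center` must lie strictly inside `alpha_band`",
         call. = FALSE)
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db))
    stop("`snr_db` must be a single number (possibly Inf)", call. = FALSE)
  if (!is.numeric(alpha_bandwidth) || length(alpha_bandwidth) != 1L ||
      is.na(alpha_bandwidth) || alpha_bandwidth <= 0)
    stop("`alpha_bandwidth` must be positive (possibly Inf)", call. = FALSE)
  stopifnot_scalar(noise_exponent, "noise_exponent")
  alpha_model <- match.arg(alpha_model)
  structure(
    list(duration = duration, fs_acq = fs_acq, alpha_center = alpha_center,
         alpha_band = alpha_band, alpha_bandwidth = alpha_bandwidth,
         snr_db = snr_db,
         noise_exponent = noise_exponent, alpha_model = alpha_model,
         seed = seed),
    class = "signal_config")
}

#' Construct a single-channel EEG record
#'
#' @param samples numeric vector of amplitudes (microvolts); must be finite.
#' @param fs sampling rate in Hz.
#' @param label channel name.
#' @param truth_phase optional per-sample ground-truth phase in `(-pi, pi]`,
#'   same length as `samples`.
#' @param meta optional [signal_config()] that produced the record.
#' @return an object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs, label = "Oz", truth_phase = NULL,
                       meta = NULL) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples)))
    stop("all samples must be finite", call. = FALSE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (!is.null(truth_phase)) {
    if (length(truth_phase) != length(samples))
      stop("`truth_phase` must match the number of samples", call. = FALSE)
    if (any(truth_phase <= -pi | truth_phase > pi, na.rm = TRUE))
      stop("`truth_phase` values must lie in (-pi, pi]", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = fs, label = label,
         truth_phase = truth_phase, meta = meta),
    class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s: %d samples at %g Hz (%.2f s)%s\n",
              x$label, length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.null(x$truth_phase)) "" else ", with ground-truth phase"))
  invisible(x)
}

# One-sided periodogram power in a frequency band (sum of |DFT|^2 over the
# band's positive-frequency bins; a relative measure, constant factors cancel
# in SNR ratios).
#' Band-limited periodogram power
#'
#' Sum of squared DFT magnitudes over the positive-frequency bins inside
#' `band`. Used by the generator to calibrate band-limited SNR; absolute
#' scale is arbitrary, ratios are meaningful.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param band numeric length-2 frequency band in Hz.
#' @return a non-negative scalar.
#' @export
band_power <- function(x, fs, band = c(8, 13)) {
  n <- length(x)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= band[1] & f <= band[2] & f <= fs / 2
  sum(Mod(X[keep])^2)
}

# Spectrally shape white noise: multiply DFT by a real mask that depends on
# |f| only (keeps the signal real up to rounding; Re() drops residuals).
shape_spectrum <- function(white, fs, mask_fun) {
  n <- length(white)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  Re(fft(fft(white) * mask_fun(f), inverse = TRUE)) / n
}

#' Generate a synthetic alpha-EEG record
#'
#' Synthesises `duration * fs_acq` samples: an alpha-band oscillation (a
#' band-limited Gaussian process, or a pure cosine in `"cosine"` mode) mixed
#' with `1/f`-type noise, scaled so that the band-limited SNR equals
#' `config$snr_db`. The record carries the exact instantaneous phase of the
#' noiseless oscillation component as `truth_phase`, and the two components
#' themselves in `$components` (not persisted by [write_record()]).
#'
#' @param config a [signal_config()].
#' @return an [eeg_record()] at `config$fs_acq` Hz, overall RMS scaled to
#'   10 microvolts.
#' @examples
#' rec <- synth_eeg(signal_config(duration = 2, snr_db = 10, seed = 1))
#' rec
#' @export
synth_eeg <- function(config) {
  if (!inherits(config, "signal_config"))
    stop("`config` must be a signal_config", call. = FALSE)
  n <- round(config$duration * config$fs_acq)
  fs <- config$fs_acq
  t <- (seq_len(n) - 1) / fs
  with_seed(config$seed, {
    if (config$alpha_model == "cosine") {
      alpha <- cos(2 * pi * config$alpha_center * t)
      truth <- wrap_phase(2 * pi * config$alpha_center * t)
    } else {
      lo <- config$alpha_band[1]; hi <- config$alpha_band[2]
      f0 <- config$alpha_center
      bw <- config$alpha_bandwidth
      edge <- 0.6  # Hz; Gaussian roll-off of the band gate
      mask <- function(f) {
        d <- pmax(lo - f, 0) + pmax(f - hi, 0)
        gate <- exp(-0.5 * (d / edge)^2)
        peak <- if (is.finite(bw)) exp(-0.5 * ((f - f0) / bw)^2) else 1
        out <- gate * peak
        out[f == 0] <- 0
        out
      }
      alpha <- shape_spectrum(rnorm(n), fs, mask)
      truth <- NULL  # filled in after scaling (phase is scale-invariant)
    }
    if (is.finite(config$snr_db)) {
      ex <- config$noise_exponent
      noise_mask <- function(f) ifelse(f > 0, f^(-ex / 2), 0)
      noise <- shape_spectrum(rnorm(n), fs, noise_mask)
      pa <- band_power(alpha, fs, config$alpha_band)
      pn <- band_power(noise, fs, config$alpha_band)
      alpha <- alpha * sqrt(10^(config$snr_db / 10) * pn / pa)
    } else {
      noise <- numeric(n)
    }
    x <- alpha + noise
    scale <- 10 / sqrt(mean(x^2))  # overall RMS 10 uV
    x <- x * scale
    alpha <- alpha * scale
    noise <- noise * scale
    if (is.null(truth)) truth <- Arg(cpp_analytic(alpha))
    rec <- eeg_record(x, fs, label = "Oz", truth_phase = wrap_phase(truth),
                      meta = config)
    rec$components <- list(alpha = alpha, noise = noise)
    rec
  })
}

#' Offline ground-truth instantaneous phase
#'
#' The non-causal reference against which the online predictor is scored:
#' the full record is two-pass (forward-backward) FIR bandpass filtered and
#' the phase taken from the analytic signal. The first and last
#' `filter_order` samples are edge transients and are flagged unreliable.
#'
#' @param record an [eeg_record()].
#' @param band bandpass edges in Hz.
#' @param filter_order FIR order (even; `filter_order + 1` taps). The
#'   default `NULL` keeps the filter's time span constant across sampling
#'   rates: order 128 at the 500 Hz working rate, scaled proportionally for
#'   other rates.
#' @return numeric vector of per-sample phase in `(-pi, pi]`, with attribute
#'   `edge_margin` giving the number of unreliable samples at each end.
#' @export
ground_truth_phase <- function(record, band = c(8, 13),
                               filter_order = NULL) {
  if (!inherits(record, "eeg_record"))
    stop("`record` must be an eeg_record", call. = FALSE)
  if (is.null(filter_order))
    filter_order <- 2L * as.integer(round(128 * record$fs / 500 / 2))
  n <- length(record$samples)
  if (n <= 4 * filter_order)
    stop("record too short for offline phase estimation", call. = FALSE)
  taps <- signal::fir1(filter_order, band / (record$fs / 2), type = "pass")
  filt <- cpp_fir_two_pass(record$samples, as.numeric(taps))
  ph <- Arg(cpp_analytic(filt))
  ph <- wrap_phase(ph)
  attr(ph, "edge_margin") <- filter_order
  ph
}

#' Split a record into an ordered sequence of sample blocks
#'
#' Emulates a chunked acquisition feed: concatenating the returned blocks
#' reproduces `record$samples` exactly; the last block may be short.
#'
#' @param record an [eeg_record()].
#' @param chunk block length in samples (>= 1).
#' @return a list of numeric vectors.
#' @export
stream_blocks <- function(record, chunk) {
  if (!inherits(record, "eeg_record"))
    stop("`record` must be an eeg_record", call. = FALSE)
  if (!is.numeric(chunk) || length(chunk) != 1L || chunk < 1)
    stop("`chunk` must be a positive count", call. = FALSE)
  chunk <- as.integer(chunk)
  n <- length(record$samples)
  starts <- seq.int(1L, n, by = chunk)
  lapply(starts, function(s)
    record$samples[s:min(s + chunk - 1L, n)])
}
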