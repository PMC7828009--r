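#' Phase-locking factor
#'
#' Resultant length of the unit phasors: `|sum(exp(1i * phases))| / N`.
#' 1 means all trials share a phase, 0 maximal dispersion.
#'
#' @param phases numeric vector of angles in radians, length >= 1.
#' @return a value in `[0, 1]`.
#' @export
plf <- function(phases) {
  if (length(phases) == 0L) stop("empty phase sample", call. = FALSE)
  min(1, Mod(sum(exp(1i * phases))) / length(phases))
}

#' Rayleigh Z from a phase-locking factor
#'
#' @param n trial count.
#' @param plf phase-locking factor in `[0, 1]`.
#' @return `n * plf^2`.
#' @export
zplf <- function(n, plf) n * plf^2

#' Participant-averaged Rayleigh Z
#'
#' Arithmetic mean of per-participant Z values.
#'
#' @param values numeric vector of Rayleigh Z values, length >= 1.
#' @return their mean.
#' @export
zplf_all <- function(values) {
  if (length(values) == 0L) stop("empty value list", call. = FALSE)
  mean(values)
}

#' Large-sample critical value of the Rayleigh test
#'
#' For `Z = N * PLF^2` the large-sample null tail is `P(Z > z) = exp(-z)`,
#' so the critical value at level `alpha` is `-log(alpha)`; at 0.05 this is
#' 2.9957 (2.995 after truncation to three decimals).
#'
#' @param alpha significance level in (0, 1].
#' @return the critical Z value.
#' @export
rayleigh_critical <- function(alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  -log(alpha)
}

#' Circular mean direction
#'
#' Four-quadrant angle of the mean cosine and sine,
#' `atan2(mean(sin(theta)), mean(cos(theta)))`, in `(-pi, pi]`.
#'
#' @param phases numeric vector of angles in radians, length >= 1.
#' @return the mean direction in radians.
#' @export
circular_mean <- function(phases) {
  if (length(phases) == 0L) stop("empty phase sample", call. = FALSE)
  C <- mean(cos(phases)); S <- mean(sin(phases))
  if (sqrt(C^2 + S^2) < 1e-12)
    stop("circular mean undefined: zero resultant", call. = FALSE)
  wrap_phase(atan2(S, C))
}

#' Recenter a phase sample on its circular mean
#'
#' Subtracts the circular mean and re-wraps to `(-pi, pi]`, so the output
#' has circular mean (numerically) zero. Used before the two-sample Watson
#' test when only the phase variances are to be compared.
#'
#' @param phases numeric vector of angles in radians.
#' @return recentered angles.
#' @export
recenter_phases <- function(phases) {
  wrap_phase(phases - circular_mean(phases))
}

#' Two-sample Watson U-squared test
#'
#' Rotation-invariant comparison of two circular samples. The pooled angles
#' are sorted; with cumulative fractions `i/n` and `j/m` at each pooled
#' value, `d = i/n - j/m` and
#' `U2 = (n * m / N^2) * (sum(t * d^2) - sum(t * d)^2 / N)` where `t` are
#' tie-group sizes (ties advance both cumulative counts before `d` is
#' recorded). Significant at p < 0.05 when U2 exceeds the asymptotic
#' critical value 0.187.
#'
#' @param a,b numeric vectors of angles in radians, non-empty.
#' @param alpha significance level for the reported criterion.
#' @return an object of class `watson_result` with `u2`, `critical`,
#'   `significant`, `n` and `m`.
#' @export
watson_u2 <- function(a, b, alpha = 0.05) {
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("empty phase sample", call. = FALSE)
  N <- n + m
  pooled <- c(a, b)
  from_a <- rep(c(TRUE, FALSE), c(n, m))
  o <- order(pooled)
  v <- pooled[o]; fa <- from_a[o]
  grp <- cumsum(c(TRUE, diff(v) > 0))
  ta <- tapply(fa, grp, sum)
  tt <- tapply(rep(1L, N), grp, sum)
  cum_a <- cumsum(ta)
  cum_b <- cumsum(tt - ta)
  d <- cum_a / n - cum_b / m
  u2 <- (n * m / N^2) * (sum(tt * d^2) - sum(tt * d)^2 / N)
  crit <- watson_critical(alpha)
  structure(list(u2 = as.numeric(u2), critical = crit,
                 significant = u2 > crit, n = n, m = m),
            class = "watson_result")
}

#' @export
print.watson_result <- function(x, ...) {
  cat(sprintf("<watson_result> U2 = %.4f (critical %.3f): %s\n",
              x$u2, x$critical,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Asymptotic critical value of Watson's two-sample U-squared
#'
#' Inverts the asymptotic tail probability
#' `P(U2 >= u) = 2 * sum_{m>=1} (-1)^(m-1) * exp(-2 m^2 pi^2 u)` at `alpha`.
#' At 0.05 this is 0.187 (three decimals); at 0.01, 0.268.
#'
#' @param alpha significance level in (0, 0.5).
#' @return the critical U-squared value.
#' @export
watson_critical <- function(alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 ||
      alpha >= 0.5)
    stop("`alpha` must lie in (0, 0.5)", call. = FALSE)
  tail_p <- function(u) {
    m <- 1:60
    2 * sum((-1)^(m - 1) * exp(-2 * m^2 * pi^2 * u))
  }
  stats::uniroot(function(u) tail_p(u) - alpha,
                 lower = 1e-4, upper = 5, tol = 1e-12)$root
}

#' Summary statistics of a phase sample
#'
#' @param phases numeric vector of angles in radians.
#' @param alpha significance level for the Rayleigh criterion.
#' @return an object of class `summary_stats` with `n`, `plf`, `zplf`,
#'   `mean_angle` and `significant` (`zplf > rayleigh_critical(alpha)`).
#' @export
phase_summary <- function(phases, alpha = 0.05) {
  r <- plf(phases)
  n <- length(phases)
  z <- zplf(n, r)
  structure(list(n = n, plf = r, zplf = z,
                 mean_angle = circular_mean(phases),
                 significant = z > rayleigh_critical(alpha)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "<summary_stats> n = %d, PLF = %.3f, ZPLF = %.3f, mean = %.3f rad (%s)\n",
    x$n, x$plf, x$zplf, x$mean_angle,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Phase-triggered response
#'
#' Grand average of trigger-locked epochs of the raw (unfiltered) 500 Hz
#' signal: a `2 * half_window + 1`-sample window centred on each trigger
#' (time-zero at index `half_window + 1`). Events too close to the record
#' edges are dropped and counted.
#'
#' @param record an [eeg_record()] at the working rate.
#' @param events a trigger-event data frame with a `sample_index` column
#'   (1-based indices into `record$samples`).
#' @param half_window samples on each side of the trigger (default 500).
#' @return an object of class `ptr_result` with the averaged `waveform`,
#'   `n_trials`, `n_excluded` and `half_window`.
#' @export
ptr <- function(record, events, half_window = 500) {
  if (!inherits(record, "eeg_record"))
    stop("`record` must be an eeg_record", call. = FALSE)
  idx <- events$sample_index
  n <- length(record$samples)
  usable <- idx > half_window & idx + half_window <= n
  if (!any(usable))
    stop("no events with a full epoch on both sides", call. = FALSE)
  keep <- idx[usable]
  acc <- numeric(2L * half_window + 1L)
  for (i in keep)
    acc <- acc + record$samples[(i - half_window):(i + half_window)]
  structure(list(waveform = acc / length(keep),
                 n_trials = length(keep),
                 n_excluded = sum(!usable),
                 half_window = as.integer(half_window)),
            class = "ptr_result")
}

#' @export
print.ptr_result <- function(x, ...) {
  cat(sprintf(
    "<ptr_result> %d-sample average of %d epochs (%d excluded)\n",
    length(x$waveform), x$n_trials, x$n_excluded))
  invisible(x)
}

#' @export
plot.ptr_result <- function(x, fs = 500, ...) {
  tt <- (seq_along(x$waveform) - 1L - x$half_window) / fs * 1000
  graphics::plot(tt, x$waveform, type = "l",
                 xlab = "time from trigger (ms)",
                 ylab = "amplitude (uV)", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Rose-histogram bin counts for a phase sample
#'
#' Bins phases on `(-pi, pi]` into equal angular sectors; the total count
#' equals the sample size. Rendering is left to the caller.
#'
#' @param phases numeric vector of angles in radians.
#' @param bins number of sectors (default 24).
#' @return a data frame with `lower`, `upper` (radians) and `count`.
#' @export
rose_histogram <- function(phases, bins = 24) {
  edges <- seq(-pi, pi, length.out = bins + 1L)
  w <- wrap_phase(phases)
  cut_idx <- findInterval(w, edges, left.open = TRUE, all.inside = TRUE)
  counts <- tabulate(cut_idx, nbins = bins)
  data.frame(lower = edges[-(bins + 1L)], upper = edges[-1L],
             count = counts)
}
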