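# Shared fixtures: all synthetic, generated at test time.

# A cosine record sampled at `fs`, duration in seconds.
make_cosine <- function(freq = 10, fs = 500, duration = 10, phase = 0) {
  t <- (seq_len(round(fs * duration)) - 1) / fs
  cos(2 * pi * freq * t + phase)
}

# von Mises sampler (Best & Fisher rejection scheme); used as the
# independent draw source for circular-statistics Monte-Carlo checks.
rvm <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(stats::runif(m) - 0.5) * acos(pmin(1, pmax(-1, f)))
    out <- c(out, th[acc])
  }
  wrap_phase(out[seq_len(n)] + mu)
}

# Default 10 dB study-condition config at a given duration/seed.
alpha_run_config <- function(duration, seed, method = "yw",
                             target = "peak", ...) {
  run_config(signal = signal_config(duration = duration, snr_db = 10,
                                    seed = seed),
             method = method, target = target, ...)
}

# Offset (rad) of a run's mean trigger phase from its target.
target_offset <- function(run) {
  tgt <- if (run$config$target == "peak") 0 else pi
  wrap_phase(run$stats$mean_angle - tgt)
}
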