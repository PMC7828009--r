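test_that("analytic signal matches an independently built Hilbert pair", {
  set.seed(8)
  x <- rnorm(500)
  z <- analytic_signal(x)
  expect_lt(max(abs(Re(z) - x)), 1e-9)
  # independent construction straight from the DFT definition
  n <- length(x)
  h <- c(1, rep(2, n / 2 - 1), 1, rep(0, n / 2 - 1))
  zref <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  expect_lt(max(Mod(z - zref)), 1e-9)
  expect_error(analytic_signal(1:3), "short")
})

test_that("analytic phase and envelope follow the cosine convention", {
  x <- make_cosine(10, 500, 1)
  z <- analytic_signal(x)
  expect_lt(abs(Arg(z[251])), 0.05)  # interior peak at t = 0.5 s
  # envelope of an AM tone tracks the modulator
  t <- (0:999) / 500
  mod <- 1 + 0.5 * sin(2 * pi * 0.7 * t)
  zam <- analytic_signal(mod * cos(2 * pi * 10 * t))
  i <- 150:850
  expect_lt(max(abs(Mod(zam[i]) - mod[i]) / mod[i]), 0.05)
})

test_that("time-zero phase read at the window endpoint carries the leakage bias", {
  # the raw endpoint of a finite analytic window is biased by spectral
  # leakage; the pipeline therefore forecasts past time-zero and reads the
  # phase at an interior index
  n <- 0:414
  w <- 2 * pi * 10 / 500
  ends_at_peak <- cos(w * (n - 414))
  pe <- phase_at_time_zero(prediction_window(ends_at_peak[1:330],
                                             ends_at_peak[331:415]))
  expect_equal(pe$theta, 0.5954544, tolerance = 1e-4)  # known bias value
  ends_at_trough <- cos(w * (n - 414) + pi)
  pe2 <- phase_at_time_zero(prediction_window(ends_at_trough[1:330],
                                              ends_at_trough[331:415]))
  expect_lt(abs(wrap_phase(pe2$theta - pi - 0.5954544)), 1e-4)
  # a read 97 samples inside the window shrinks the bias ~40-fold
  n2 <- 0:511
  x2 <- cos(w * (n2 - 414))
  expect_lt(abs(Arg(analytic_signal(x2)[415])), 0.02)
})

test_that("phase estimates are invariant to amplitude scaling", {
  x <- synth_eeg(signal_config(duration = 8, snr_db = 10, seed = 2))
  x5 <- decimate_signal(x$samples, 2000, 500)
  spec <- filter_spec()
  run1 <- phaselock:::cpp_closed_loop(x5, spec$taps, 30L, 85L, 85L, 97L,
                                      500L, 0L, 1e-3, 0, 250L, 1000L, TRUE)
  run2 <- phaselock:::cpp_closed_loop(3.7 * x5, spec$taps, 30L, 85L, 85L,
                                      97L, 500L, 0L, 1e-3, 0, 250L, 1000L,
                                      TRUE)
  i <- which(!is.na(run1$phase_trace))
  expect_equal(run1$phase_trace[i], run2$phase_trace[i], tolerance = 1e-9)
  expect_identical(run1$index0, run2$index0)
})

test_that("crossing detector fires on wrapped upward crossings only", {
  expect_true(detect_crossing(-0.05, 0.03, target = 0))
  expect_false(detect_crossing(0.2, 0.2, target = 0))
  expect_true(detect_crossing(3.10, -3.10, target = pi))  # across the wrap
  expect_false(detect_crossing(0.03, -0.05, target = 0))  # downward
  # backward slip across the +/-pi wrap passes the antipode, not the target
  expect_false(detect_crossing(-3, 3, target = 0))
  expect_false(detect_crossing(0.5, 2.5, target = 1))  # jump too wide
})

test_that("pipeline emits one trigger per cycle on a clean tone", {
  spec <- filter_spec()
  p <- pipeline_init(spec, method = "yw", target = "peak",
                     refractory = 0.05, warmup = 2)
  x <- make_cosine(10, 500, 8)
  ev <- pipeline_step(p, x)
  expect_gt(nrow(ev), 20)
  iti <- diff(ev$sample_index) / 500
  expect_true(all(abs(iti - 0.1) <= 0.005))
  # trigger instants sit on true peaks within +/- 1 sample
  truth <- wrap_phase(2 * pi * 10 * (ev$sample_index - 1) / 500)
  expect_true(all(abs(truth) <= 2 * pi * 10 / 500 + 1e-9))
})

test_that("buffer fill and refractory contracts hold", {
  p <- pipeline_init(filter_spec(), refractory = 1, warmup = 0)
  ev0 <- pipeline_step(p, make_cosine(10, 500, 0.998))  # 499 samples
  expect_equal(nrow(ev0), 0)
  p2 <- pipeline_init(filter_spec(), refractory = 1, warmup = 2)
  ev <- pipeline_step(p2, make_cosine(10, 500, 10))
  expect_gt(nrow(ev), 2)
  expect_true(all(diff(ev$time_s) >= 1))
})

test_that("R pipeline and compiled closed loop agree trigger for trigger", {
  rec <- synth_eeg(signal_config(duration = 8, snr_db = 10, seed = 6))
  x5 <- decimate_signal(rec$samples, 2000, 500)
  spec <- filter_spec()
  p <- pipeline_init(spec, method = "lms", target = "peak",
                     refractory = 0.5, warmup = 2)
  ev_r <- pipeline_step(p, x5)
  loop <- phaselock:::cpp_closed_loop(x5, spec$taps, 30L, 85L, 85L, 97L,
                                      500L, 1L, 1e-3, 0, 250L, 1000L, FALSE)
  expect_equal(ev_r$sample_index, loop$index0 + 1L)
  expect_equal(ev_r$predicted_phase, loop$predicted_phase,
               tolerance = 1e-10)
  # and the same for the Yule-Walker method
  p2 <- pipeline_init(spec, method = "yw", target = "trough",
                      refractory = 0.5, warmup = 2)
  ev_r2 <- pipeline_step(p2, x5)
  loop2 <- phaselock:::cpp_closed_loop(x5, spec$taps, 30L, 85L, 85L, 97L,
                                       500L, 0L, 1e-3, pi, 250L, 1000L,
                                       FALSE)
  expect_equal(ev_r2$sample_index, loop2$index0 + 1L)
  expect_equal(ev_r2$predicted_phase, loop2$predicted_phase,
               tolerance = 1e-10)
})

test_that("online phase at time-zero is unbiased against the offline truth", {
  rec <- synth_eeg(signal_config(duration = 60, snr_db = 10, seed = 11))
  rec5 <- decimate_record(rec)
  spec <- filter_spec()
  loop <- phaselock:::cpp_closed_loop(rec5$samples, spec$taps, 30L, 85L,
                                      85L, 97L, 500L, 0L, 1e-3, 0, 250L,
                                      1000L, TRUE)
  truth <- ground_truth_phase(rec5)
  i <- 2000:28000
  err <- wrap_phase(loop$phase_trace[i] - truth[i])
  expect_lt(abs(Arg(mean(exp(1i * err)))), 0.3)
})
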