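test_that("signal_config validates its inputs", {
  expect_s3_class(signal_config(duration = 1, seed = 1), "signal_config")
  expect_error(signal_config(duration = 0), "duration")
  expect_error(signal_config(duration = 1, fs_acq = 20), "twice")
  expect_error(signal_config(duration = 1, alpha_center = 15), "inside")
  expect_error(signal_config(duration = 1, alpha_band = c(13, 8)),
               "increasing")
})

test_that("generated records have the configured length and are seeded", {
  rec <- synth_eeg(signal_config(duration = 2, fs_acq = 2000, seed = 1))
  expect_length(rec$samples, 4000)
  expect_true(all(is.finite(rec$samples)))
  expect_length(rec$truth_phase, 4000)
  expect_true(all(rec$truth_phase > -pi & rec$truth_phase <= pi))
  rec2 <- synth_eeg(signal_config(duration = 2, fs_acq = 2000, seed = 1))
  expect_identical(rec$samples, rec2$samples)
  rec3 <- synth_eeg(signal_config(duration = 2, fs_acq = 2000, seed = 2))
  expect_false(identical(rec$samples, rec3$samples))
})

test_that("pure cosine mode has zero truth phase at amplitude maxima", {
  cfg <- signal_config(duration = 2, fs_acq = 2000, snr_db = Inf,
                       alpha_model = "cosine", seed = 1)
  rec <- synth_eeg(cfg)
  peaks <- which(rec$samples == max(rec$samples))
  expect_true(all(abs(rec$truth_phase[peaks]) < 0.02))
})

test_that("band-limited SNR of generated output matches the request", {
  # measured with an independent spectral estimator, not the generator's own
  for (snr in c(0, 10, 20)) {
    rec <- synth_eeg(signal_config(duration = 60, snr_db = snr, seed = 3))
    pw <- function(x) {
      sp <- stats::spec.pgram(stats::ts(x, frequency = rec$fs), taper = 0,
                              plot = FALSE, detrend = FALSE)
      sum(sp$spec[sp$freq >= 8 & sp$freq <= 13])
    }
    measured <- 10 * log10(pw(rec$components$alpha) /
                           pw(rec$components$noise))
    expect_lt(abs(measured - snr), 1)
  }
})

test_that("offline phase of the mixture tracks the noiseless oscillation", {
  rec <- synth_eeg(signal_config(duration = 60, snr_db = 20, seed = 3))
  gt <- ground_truth_phase(rec)
  margin <- attr(gt, "edge_margin")
  i <- (margin + 1):(length(gt) - margin)
  mae <- mean(abs(wrap_phase(gt[i] - rec$truth_phase[i])))
  expect_lt(mae, 0.2)
})

test_that("offline phase is zero at cosine peaks and advances at the tone rate", {
  fs <- 500
  rec <- eeg_record(make_cosine(10, fs, 10), fs)
  ph <- ground_truth_phase(rec)
  expect_true(all(ph > -pi & ph <= pi))
  at_peaks <- seq(1, length(ph), by = fs / 10)  # t = k/10 s
  interior <- at_peaks[at_peaks > 200 & at_peaks < length(ph) - 200]
  expect_true(all(abs(ph[interior]) < 0.02))
  d <- wrap_phase(diff(ph[500:4500]))
  expect_lt(abs(mean(d) - 2 * pi * 10 / fs) / (2 * pi * 10 / fs), 0.02)
  expect_error(ground_truth_phase(eeg_record(rnorm(100), fs)), "short")
})

test_that("stream_blocks partitions a record without loss", {
  rec <- eeg_record(rnorm(4000), 500)
  b <- stream_blocks(rec, 4)
  expect_length(b, 1000)
  expect_true(all(lengths(b) == 4))
  expect_identical(unlist(b), rec$samples)
  expect_length(stream_blocks(rec, 4000), 1)
  rec1 <- eeg_record(rnorm(4001), 500)
  b1 <- stream_blocks(rec1, 4)
  expect_length(b1, 1001)
  expect_length(b1[[1001]], 1)
  expect_identical(unlist(b1), rec1$samples)
})

test_that("records round-trip through text plus sidecar", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "rec.txt")
  rec <- synth_eeg(signal_config(duration = 1, seed = 5))
  write_record(rec, path)
  back <- read_record(path)
  expect_equal(back$samples, rec$samples)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$label, rec$label)
})
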