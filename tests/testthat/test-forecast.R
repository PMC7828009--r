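test_that("Yule-Walker agrees with the reference solver", {
  set.seed(4)
  x <- as.numeric(stats::filter(rnorm(3000), c(1.2, -0.6),
                                method = "recursive"))
  m <- fit_yule_walker(x, 30)
  ref <- stats::ar.yw(x, aic = FALSE, order.max = 30, demean = TRUE)
  expect_equal(m$coeffs, unname(ref$ar), tolerance = 1e-8)
  expect_true(all(abs(m$reflection) < 1))
})

test_that("Yule-Walker recovers known processes", {
  # noiseless sinusoid: x(t+1) = 2 cos(w) x(t) - x(t-1)
  w <- 2 * pi * 25 / 500
  m2 <- fit_yule_walker(make_cosine(25, 500, 200), 2)
  expect_lt(max(abs(m2$coeffs - c(2 * cos(w), -1))), 1e-3)
  # AR(1) with coefficient 0.9
  set.seed(1)
  x1 <- as.numeric(stats::filter(rnorm(1e5), 0.9, method = "recursive"))
  expect_lt(abs(fit_yule_walker(x1, 1)$coeffs - 0.9), 0.01)
  # white noise: all 30 coefficients near zero
  set.seed(2)
  m30 <- fit_yule_walker(rnorm(1e5), 30)
  expect_true(all(abs(m30$coeffs) < 0.05))
  expect_error(fit_yule_walker(rep(1, 100), 30), "degenerate|constant")
  expect_error(fit_yule_walker(rnorm(50), 30), "short")
})

test_that("LMS update follows the stochastic-gradient rule", {
  st <- lms_init(order = 4, mu = 0.1)
  h <- c(1, -1, 0.5, 2)
  # zero error leaves the weights unchanged
  st1 <- lms_init(order = 4, mu = 0.1)
  st1$weights <- c(0.5, 0, 0, 0)
  r <- lms_step(st1, h, next_sample = 0.5)  # y = 0.5, e = 0
  expect_equal(r$e, 0)
  expect_equal(r$state$weights, st1$weights)
  expect_equal(r$state$update_count, 1L)
  # mu = 0 freezes the weights but still predicts
  st2 <- lms_init(order = 4, mu = .Machine$double.xmin)
  st2$mu <- 0
  r2 <- lms_step(st2, h, 3)
  expect_equal(r2$y, 0)
  expect_equal(r2$state$weights, numeric(4))
  # general update: A + 2 mu e X
  r3 <- lms_step(st, h, 2)
  expect_equal(r3$state$weights, 2 * 0.1 * 2 * h)
  expect_error(lms_step(st, h[1:3], 1), "order")
})

test_that("LMS converges on a stationary in-band sinusoid", {
  st <- lms_init()
  x <- make_cosine(10, 500, 9)
  x <- x / sqrt(mean(x^2))
  errs <- numeric(0)
  for (t in 31:4000) {
    r <- lms_step(st, x[(t - 1):(t - 30)], x[t])
    st <- r$state
    if (st$update_count > 2000) errs <- c(errs, r$e^2)
  }
  expect_lt(mean(errs), 0.01)  # < 1% of unit signal power
})

test_that("AR forecasting continues a sinusoid exactly and respects the horizon", {
  w <- 2 * pi * 10 / 500
  exact <- structure(list(coeffs = c(2 * cos(w), -1), order = 2L,
                          method = "yw"),
                     class = "ar_model")
  x <- make_cosine(10, 500, 2)
  fc <- predict(exact, x[1:330], horizon = 85)
  expect_length(fc, 85)
  expect_lt(max(abs(fc - x[331:415])), 1e-6)
  expect_length(predict(exact, x[1:330], horizon = 0), 0)
  expect_error(predict(exact, x[1:330], horizon = -1), "non-negative")
  # LMS path uses the same recursion with the current weights
  st <- lms_init(order = 2, mu = 1e-3)
  st$weights <- c(2 * cos(w), -1)
  expect_equal(predict(st, x[1:330], 85), fc)
})

test_that("Yule-Walker forecasts of bounded windows stay bounded", {
  spec <- filter_spec()
  for (seed in 1:5) {
    rec <- synth_eeg(signal_config(duration = 3, snr_db = 5, seed = seed))
    x <- decimate_signal(rec$samples, 2000, 500)
    win <- x[501:1000]
    tr <- trim_edges(bandpass_two_pass(demean(win), spec))
    m <- fit_yule_walker(tr, 30)
    expect_true(all(abs(m$reflection) < 1))
    fc <- predict(m, tr, 85)
    expect_lt(max(abs(fc)), 10 * max(abs(tr)))
  }
})

test_that("models serialise to JSON", {
  dir <- withr::local_tempdir()
  m <- fit_yule_walker(make_cosine(10, 500, 4), 5)
  path <- write_model_json(m, file.path(dir, "m.json"))
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$coeffs, m$coeffs, tolerance = 1e-12)
  expect_equal(back$method, "yw")
})
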