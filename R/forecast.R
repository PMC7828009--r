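#' Fit an autoregressive model by the Yule-Walker equations
#'
#' Solves the Yule-Walker normal equations built from the biased
#' (divide-by-n) sample autocovariance via the Levinson-Durbin recursion.
#' The biased estimator guarantees a positive semidefinite Toeplitz system,
#' hence reflection coefficients of magnitude below one and a stable
#' forecasting recursion.
#'
#' The fitted model is \eqn{x(t+1) = \sum_{k=0}^{K-1} \alpha_k x(t-k)}, i.e.
#' `coeffs[1]` multiplies the newest sample.
#'
#' @param x numeric series, longer than `2 * order` and not constant.
#' @param order model order K (default 30).
#' @return an object of class `ar_model` with elements `order`, `coeffs`,
#'   `reflection` and `method = "yw"`.
#' @examples
#' x <- cos(2 * pi * 10 * (0:4999) / 500)
#' fit_yule_walker(x, order = 2)$coeffs  # ~ c(2 * cos(2*pi*10/500), -1)
#' @export
fit_yule_walker <- function(x, order = 30) {
  x <- as.numeric(x)
  if (length(x) <= 2 * order)
    stop("series too short for the requested order", call. = FALSE)
  r <- as.numeric(cpp_autocov(x, as.integer(order)))
  if (r[1] <= 0)
    stop("zero-variance input: AR fit is degenerate", call. = FALSE)
  ld <- cpp_levinson(r)
  structure(list(order = as.integer(order),
                 coeffs = as.numeric(ld$coeffs),
                 reflection = as.numeric(ld$reflection),
                 method = "yw"),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> Yule-Walker fit, order %d; |reflection| max %.3f\n",
              x$order, max(abs(x$reflection))))
  invisible(x)
}

#' Initialise an adaptive LMS predictor
#'
#' Weights start at zero and persist across analysis windows; they are
#' updated once per newly acquired valid sample by [lms_step()]. The default
#' step size assumes the input has been normalised to unit RMS (the pipeline
#' divides each trimmed window by its RMS before updating), which makes
#' `mu` scale-free.
#'
#' @param order filter order K (default 30).
#' @param mu step size (> 0; default 0.001).
#' @return an object of class `lms_state`.
#' @export
lms_init <- function(order = 30, mu = 1e-3) {
  stopifnot_scalar(mu, "mu", positive = TRUE)
  structure(list(order = as.integer(order),
                 weights = numeric(order), mu = mu,
                 update_count = 0L, method = "lms"),
            class = "lms_state")
}

#' @export
print.lms_state <- function(x, ...) {
  cat(sprintf("<lms_state> order %d, mu %g, %d updates\n",
              x$order, x$mu, x$update_count))
  invisible(x)
}

#' One LMS adaptation step
#'
#' Computes the one-step prediction `y = sum(weights * history)` from the
#' most recent K samples (newest first), the prediction error
#' `e = next_sample - y`, and the stochastic-gradient weight update
#' `weights + 2 * mu * e * history`.
#'
#' @param state an [lms_init()] state.
#' @param history numeric vector of length `state$order`, newest sample
#'   first.
#' @param next_sample the sample being predicted.
#' @return a list with the updated `state`, the prediction `y` and the
#'   error `e`.
#' @export
lms_step <- function(state, history, next_sample) {
  if (!inherits(state, "lms_state"))
    stop("`state` must be an lms_state", call. = FALSE)
  history <- as.numeric(history)
  if (length(history) != state$order)
    stop("`history` must have exactly `order` samples, newest first",
         call. = FALSE)
  y <- sum(state$weights * history)
  e <- next_sample - y
  state$weights <- state$weights + 2 * state$mu * e * history
  state$update_count <- state$update_count + 1L
  list(state = state, y = y, e = e)
}

ar_forecast <- function(coeffs, history, horizon) {
  if (horizon < 0) stop("`horizon` must be non-negative", call. = FALSE)
  if (length(history) < length(coeffs))
    stop("history shorter than the model order", call. = FALSE)
  as.numeric(cpp_ar_forecast(as.numeric(coeffs), as.numeric(history),
                             as.integer(horizon)))
}

#' Forecast ahead with a fitted AR model
#'
#' Iterates the AR recursion with the innovation set to zero, feeding
#' predictions back as inputs.
#'
#' @param object an `ar_model`.
#' @param history numeric series, oldest first, at least `order` samples.
#' @param horizon number of samples to predict (default 85).
#' @param ... unused.
#' @return numeric vector of length `horizon`.
#' @export
predict.ar_model <- function(object, history, horizon = 85, ...) {
  ar_forecast(object$coeffs, history, horizon)
}

#' Forecast ahead with the current LMS weights
#'
#' The weights are frozen for the duration of the forecast.
#'
#' @param object an `lms_state`.
#' @inheritParams predict.ar_model
#' @return numeric vector of length `horizon`.
#' @export
predict.lms_state <- function(object, history, horizon = 85, ...) {
  ar_forecast(object$weights, history, horizon)
}

#' Known plus predicted samples around time-zero
#'
#' Bundles the trimmed valid samples with the forward-predicted extension;
#' the final predicted sample is "time-zero", the instant whose phase the
#' online system estimates.
#'
#' @param known numeric vector of valid filtered samples (330 under the
#'   standard settings).
#' @param predicted numeric vector of forecast samples (85 under the
#'   standard settings).
#' @return an object of class `prediction_window` with the concatenated
#'   `samples` and the 0-based `time_zero_index` (last sample).
#' @export
prediction_window <- function(known, predicted) {
  known <- as.numeric(known); predicted <- as.numeric(predicted)
  samples <- c(known, predicted)
  structure(list(known = known, predicted = predicted, samples = samples,
                 time_zero_index = length(samples) - 1L),
            class = "prediction_window")
}

#' Serialise a fitted model or adaptive state to JSON
#'
#' @param model an `ar_model` or `lms_state`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  fields <- unclass(model)
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
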