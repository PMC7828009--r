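// Numerical core of the closed-loop phase-targeting pipeline.
// Everything here is deterministic; all randomness lives on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double wrap_pi(double x) {
  // wrap to (-pi, pi]
  const double twopi = 2.0 * M_PI;
  return x - twopi * std::ceil((x - M_PI) / twopi);
}

// Causal FIR y[i] = sum_k b[k] x[i-k] as a sliding dot product with the
// reversed taps. ext must hold nz history samples followed by the input.
static void fir_into(const arma::vec& ext, const arma::vec& brev,
                     arma::vec& y, int n) {
  const int nb = brev.n_elem;
  const double* e = ext.memptr();
  const double* br = brev.memptr();
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    const double* seg = e + i;
    for (int k = 0; k < nb; ++k) acc += br[k] * seg[k];
    y[i] = acc;
  }
}

// [[Rcpp::export]]
arma::vec cpp_fir_filter(const arma::vec& x, const arma::vec& b,
                         const arma::vec& zi) {
  const int n = x.n_elem, nb = b.n_elem, nz = nb - 1;
  if ((int)zi.n_elem != nz)
    stop("filter state must have length(b) - 1 samples");
  arma::vec brev = arma::reverse(b);
  arma::vec ext(nz + n);
  if (nz > 0) ext.head(nz) = zi;
  ext.tail(n) = x;
  arma::vec y(n);
  fir_into(ext, brev, y, n);
  return y;
}

// Forward-backward ("two-pass") FIR over a finite window, no padding:
// transients stay at both edges and are handled downstream by trimming.
static void two_pass_into(const arma::vec& x, const arma::vec& brev,
                          arma::vec& ext, arma::vec& y, arma::vec& out) {
  const int n = x.n_elem, nz = brev.n_elem - 1;
  ext.head(nz).zeros();
  ext.subvec(nz, nz + n - 1) = x;
  fir_into(ext, brev, y, n);
  ext.head(nz).zeros();
  for (int i = 0; i < n; ++i) ext[nz + i] = y[n - 1 - i];  // reversed
  fir_into(ext, brev, y, n);
  for (int i = 0; i < n; ++i) out[i] = y[n - 1 - i];
}

// [[Rcpp::export]]
arma::vec cpp_fir_two_pass(const arma::vec& x, const arma::vec& b) {
  const int n = x.n_elem, nz = b.n_elem - 1;
  arma::vec brev = arma::reverse(b);
  arma::vec ext(nz + n), y(n), out(n);
  two_pass_into(x, brev, ext, y, out);
  return out;
}

// Levinson-Durbin recursion on an autocovariance sequence r[0..K]:
// phi such that x(t) = sum_j phi_j x(t-j), plus reflection coefficients.
static void levinson_core(const arma::vec& r, arma::vec& a, arma::vec& refl,
                          arma::vec& scratch) {
  const int K = r.n_elem - 1;
  double E = r[0];
  a.zeros();
  for (int m = 1; m <= K; ++m) {
    double acc = r[m];
    for (int j = 1; j < m; ++j) acc -= a[j - 1] * r[m - j];
    double k = acc / E;
    refl[m - 1] = k;
    for (int j = 1; j < m; ++j) scratch[j - 1] = a[j - 1] - k * a[m - 1 - j];
    for (int j = 1; j < m; ++j) a[j - 1] = scratch[j - 1];
    a[m - 1] = k;
    E *= (1.0 - k * k);
    if (E <= 0.0) E = std::numeric_limits<double>::min();
  }
}

// [[Rcpp::export]]
List cpp_levinson(const arma::vec& r) {
  const int K = r.n_elem - 1;
  if (K < 1) stop("need autocovariances to lag >= 1");
  if (r[0] <= 0.0) stop("zero-variance (degenerate) input");
  arma::vec a(K), refl(K), scratch(K);
  levinson_core(r, a, refl, scratch);
  return List::create(_["coeffs"] = a, _["reflection"] = refl);
}

// Biased (divide-by-n) sample autocovariance to maxlag, after demeaning.
static void autocov_into(const arma::vec& x, int maxlag, arma::vec& r,
                         arma::vec& xc) {
  const int n = x.n_elem;
  const double m = arma::mean(x);
  for (int i = 0; i < n; ++i) xc[i] = x[i] - m;
  const double* p = xc.memptr();
  for (int l = 0; l <= maxlag; ++l) {
    double acc = 0.0;
    for (int i = 0; i + l < n; ++i) acc += p[i] * p[i + l];
    r[l] = acc / n;
  }
}

// [[Rcpp::export]]
arma::vec cpp_autocov(const arma::vec& x, int maxlag) {
  const int n = x.n_elem;
  if (n <= maxlag) stop("series shorter than requested lag");
  arma::vec r(maxlag + 1), xc(n);
  autocov_into(x, maxlag, r, xc);
  return r;
}

// Recursive AR forecast: x(t+1) = sum_{k=0..K-1} coef[k] x(t-k), predictions
// fed back as inputs. history is oldest-first; returns `horizon` samples.
static void forecast_into(const arma::vec& coef, const double* hist_end,
                          int horizon, arma::vec& buf, arma::vec& out) {
  const int K = coef.n_elem;
  for (int k = 0; k < K; ++k) buf[k] = hist_end[-k];  // newest first
  for (int h = 0; h < horizon; ++h) {
    double acc = 0.0;
    for (int k = 0; k < K; ++k) acc += coef[k] * buf[k];
    out[h] = acc;
    for (int k = K - 1; k > 0; --k) buf[k] = buf[k - 1];
    if (K > 0) buf[0] = acc;
  }
}

// [[Rcpp::export]]
arma::vec cpp_ar_forecast(const arma::vec& coef, const arma::vec& history,
                          int horizon) {
  const int K = coef.n_elem, n = history.n_elem;
  if (horizon < 0) stop("horizon must be non-negative");
  if (n < K) stop("history shorter than model order");
  arma::vec buf(std::max(K, 1)), out(horizon);
  forecast_into(coef, history.memptr() + n - 1, horizon, buf, out);
  return out;
}

// Discrete analytic signal: negative-frequency DFT bins zeroed, positive
// doubled, DC (and Nyquist for even n) kept once. Real part equals input.
static arma::cx_vec analytic_core(const arma::vec& x) {
  const int n = x.n_elem;
  arma::cx_vec X = arma::fft(x);
  if (n % 2 == 0) {
    for (int i = 1; i < n / 2; ++i) X[i] *= 2.0;
    for (int i = n / 2 + 1; i < n; ++i) X[i] = 0.0;
  } else {
    for (int i = 1; i <= (n - 1) / 2; ++i) X[i] *= 2.0;
    for (int i = (n + 1) / 2; i < n; ++i) X[i] = 0.0;
  }
  return arma::ifft(X);
}

// [[Rcpp::export]]
arma::cx_vec cpp_analytic(const arma::vec& x) {
  if ((int)x.n_elem < 4) stop("input too short for an analytic signal");
  return analytic_core(x);
}

// Full closed-loop run over a 500 Hz record with a 1-sample hop.
// method: 0 = Yule-Walker refit per window, 1 = adaptive LMS with persistent
// weights updated once per new valid sample (input normalised by the trimmed
// window's RMS before the update; the forecast uses the raw trimmed samples).
// The forecast horizon is `horizon + phase_extend` samples and the phase is
// read `phase_extend` samples before the end of the analytic window, i.e.
// at time-zero, keeping the estimate clear of the analytic-signal edge;
// phase_extend = 0 reads the raw endpoint.
// Returns 0-based trigger sample indices, the predicted phase at each
// trigger, optionally the per-sample predicted-phase trace (NaN before the
// buffer is full), and the final LMS weights.
// [[Rcpp::export]]
List cpp_closed_loop(const arma::vec& x, const arma::vec& taps,
                     int order, int margin, int horizon, int phase_extend,
                     int win, int method, double mu, double target,
                     int refractory_samples, int warmup_steps,
                     bool trace = false) {
  const int n = x.n_elem;
  const int L = win - 2 * margin;            // valid samples per window
  const int H = horizon + phase_extend;      // total forecast length
  const int nconc = L + H;
  const int iread = nconc - 1 - phase_extend;  // time-zero index
  if (L <= 2 * order) stop("window too short for the trim and model order");
  const int nz = taps.n_elem - 1;
  arma::vec brev = arma::reverse(taps);
  arma::vec ext(nz + win), y(win), filt(win), trimmed(L);
  arma::vec r(order + 1), xc(L), coef(order), refl(order), scratch(order);
  arma::vec buf(order), fc(H), conc(nconc);
  arma::vec weights(order, arma::fill::zeros);
  std::vector<int> ev_idx;
  std::vector<double> ev_phase;
  arma::vec phase_trace;
  if (trace) phase_trace = arma::vec(n).fill(arma::datum::nan);
  double prev = 0.0;
  bool have_prev = false;
  long valid = 0, updates = 0;
  long last_trig = -2L * refractory_samples - n;

  for (int t = win - 1; t < n; ++t) {
    arma::vec window = x.subvec(t - win + 1, t);
    window -= arma::mean(window);
    two_pass_into(window, brev, ext, y, filt);
    for (int i = 0; i < L; ++i) trimmed[i] = filt[margin + i];
    bool degenerate = false;
    if (method == 1) {
      double rms = std::sqrt(arma::mean(arma::square(trimmed)));
      if (rms > 0) {
        double inv = 1.0 / rms;
        double yhat = 0.0;
        for (int k = 0; k < order; ++k)
          yhat += weights[k] * trimmed[L - 2 - k] * inv;
        double e = trimmed[L - 1] * inv - yhat;
        const double g = 2.0 * mu * e;
        for (int k = 0; k < order; ++k)
          weights[k] += g * trimmed[L - 2 - k] * inv;
        ++updates;
      }
      coef = weights;
    } else {
      autocov_into(trimmed, order, r, xc);
      if (r[0] > 1e-300) {
        levinson_core(r, coef, refl, scratch);
      } else {
        coef.zeros();
        degenerate = true;
      }
    }
    forecast_into(coef, trimmed.memptr() + L - 1, H, buf, fc);
    conc.head(L) = trimmed;
    conc.tail(H) = fc;
    arma::cx_vec z = analytic_core(conc);
    double theta = std::arg(z[iread]);
    if (trace) phase_trace[t] = theta;
    ++valid;
    if (have_prev && !degenerate && valid > warmup_steps &&
        (long)t - last_trig >= (long)refractory_samples) {
      // forward step through the target (see detect_crossing in R)
      double delta = wrap_pi(theta - prev);
      double d = wrap_pi(target - prev);
      if (delta > 0.0 && delta < M_PI / 2.0 && d > 0.0 && d <= delta) {
        ev_idx.push_back(t);
        ev_phase.push_back(theta);
        last_trig = t;
      }
    }
    prev = theta;
    have_prev = true;
  }
  return List::create(
    _["index0"] = wrap(ev_idx),
    _["predicted_phase"] = wrap(ev_phase),
    _["phase_trace"] = trace ? wrap(phase_trace) : R_NilValue,
    _["lms_weights"] = wrap(weights),
    _["lms_updates"] = (double)updates);
}
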