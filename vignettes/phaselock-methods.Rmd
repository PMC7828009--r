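---
title: "Methods: closed-loop alpha-phase prediction and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop alpha-phase prediction and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaselock)
```

## The problem

A brain-state-dependent stimulation system must act at a chosen phase of an
ongoing EEG rhythm — here the occipital alpha band, 8–13 Hz — using only
causally available data. Zero-phase filtering and the Hilbert transform,
the standard offline tools for instantaneous phase, are both non-causal:
near the edge of the available data the filtered signal is transient and
the analytic signal is biased. The online pipeline simulated by this
package resolves that tension the way real-time rigs do: it filters a
sliding window, discards the filter's edge transients, and then *forward
predicts* the discarded interval with an autoregressive (AR) model so that
the phase can be read at "time-zero", the most recent acquired sample.

`run_closed_loop()` executes this pipeline over a whole record with a
one-sample hop, which is the faithful software analogue of a real-time
target machine evaluating continuously.

## The pipeline and its parameters

| stage | parameter | default | why |
|---|---|---|---|
| decimation | working rate | 500 Hz | alpha dynamics are fully represented; 4x cost reduction from a 2 kHz front end |
| window | length | 500 samples (1 s) | long enough for a stable order-30 AR fit on 330 samples; short enough to track nonstationarity |
| bandpass | band, order | 8–13 Hz, order 128 | two-pass (forward–backward) windowed-sinc FIR; zero net phase lag inside the window |
| trim | margin | 85 samples | discards both edges of the two-pass transient, leaving 330 valid samples |
| forecast | AR order K | 30 | fits the narrowband process well without over-parameterising 330 samples |
| forecast | horizon | 85 samples | exactly recovers the trimmed interval up to time-zero |
| phase read | `phase_extend` | 97 samples | see "Analytic-signal edge bias" below |
| LMS | step size `mu` | 0.001 | applied to RMS-normalised windows, so the value is scale-free |
| triggering | refractory | 0.5 s | the published experiments report thousands of triggers per ~8-minute condition without stating an inter-trigger policy; trigger density is a knob, not a claim |
| triggering | warm-up | 2 s | zero-initialised LMS weights predict zero; triggers are suppressed until the filter has adapted |

Two forecasters are provided. `fit_yule_walker()` refits
`x(t+1) = sum_k alpha_k x(t-k)` per window by solving the Yule–Walker
equations with the Levinson–Durbin recursion on the *biased* (divide-by-n)
sample autocovariance. The biased estimator gives a positive semidefinite
Toeplitz system, hence reflection coefficients of magnitude below one and a
forecast recursion that cannot diverge — the property the guard tests
assert. Its cost is a slight shrinkage of the fitted dynamics at high lags.
The adaptive LMS path (`lms_init()`, `lms_step()`) keeps one persistent
weight vector across windows, updated once per newly acquired valid sample;
refitting from scratch each window would erase exactly the adaptivity the
method exists to provide. The update uses the trimmed window divided by its
RMS, so `mu` does not depend on the input scale in microvolts; the forecast
itself applies the current weights to the raw trimmed samples (the AR
recursion is linear, so normalisation does not change the predicted phase).

The LMS step size, weight initialisation, and persistence across windows
are implementation choices of this package: plain (unnormalised) updates
are available by scaling `mu` yourself, and divergence is possible if `mu`
is set large — it is the classic LMS stability knob.

## Analytic-signal edge bias, and why the forecast extends past time-zero

The discrete analytic signal (`analytic_signal()`) zeroes the
negative-frequency DFT bins. At the final sample of a finite window its
phase is dominated by spectral leakage: for 415 samples of a pure 10 Hz
tone at 500 Hz the endpoint phase error is 0.595 rad, and it swings across
almost the full circle as the ending phase varies (the package's test suite
pins these values, cross-checked against an independent DFT construction).
An estimator that reads the raw endpoint therefore cannot lock triggers to
a target phase — on a noiseless sinusoid it locks, but to the wrong phase.

The pipeline therefore forecasts `phase_extend` samples *beyond* time-zero
and still reads the phase at the time-zero index, now an interior sample
where the leakage bias is negligible. The default 97 places time-zero 97
samples inside the analytic window and makes that window 330 + 85 + 97 =
512 samples, a convenient FFT length. Setting `phase_extend = 0` reproduces
the literal read-at-the-endpoint behaviour for comparison. Since the
extension consists of forecast samples only, it uses no future data and
remains causally valid.

## The synthetic signal

`synth_eeg()` generates the study conditions: a narrowband stochastic alpha
oscillation embedded in `1/f`-type noise at a configurable band-limited
SNR, emulating an occipital channel digitised at 2 kHz.

- The alpha component is white Gaussian noise shaped in the DFT domain by a
  Gaussian spectral peak at `alpha_center` (default 10 Hz) of width
  `alpha_bandwidth` (sigma, default 1 Hz — about 2.4 Hz full width at half
  maximum, a typical occipital alpha resonance), gated to the 8–13 Hz band.
  This yields an oscillation with realistic amplitude and frequency drift;
  its coherence time, hence the achievable prediction quality, is set by
  `alpha_bandwidth`.
- The noise component is white Gaussian noise shaped to a power spectral
  density proportional to `1/f^noise_exponent` (default 1), DC removed.
- `snr_db` is calibrated as the ratio of 8–13 Hz band powers of the two
  components, measured on the realisation itself, so the generated record
  meets the requested in-band SNR exactly; phase-prediction difficulty
  depends on in-band SNR, not broadband SNR.
- A deterministic pure-cosine mode (`alpha_model = "cosine"`) provides
  exact ground truth for tests.
- Identical seeds give bit-identical records; every downstream result is a
  pure function of the configuration.

Ground truth for scoring (`ground_truth_phase()`) follows the offline
convention of the modelled study: a two-pass FIR over the *full* record
plus the Hilbert transform — not the online estimator — so the closed-loop
statistics measure true targeting accuracy. The first and last
`filter_order` samples are flagged edge-unreliable, and triggers inside
that margin are excluded from the statistics. The default filter order
scales with the sampling rate (128 at 500 Hz) so the filter's time span,
not its tap count, is held constant.

What the generator does *not* model: multi-channel structure, ocular and
myogenic artifacts, visual evoked responses (the "visual task" regime of
the modelled study), amplifier-mode effects, or alpha blocking. Passing the
closed-loop benchmark therefore shows that the estimator tracks a drifting
narrowband oscillation in pink noise at the configured SNR — it does not
guarantee equal performance on any particular participant's EEG, where
alpha bandwidth and SNR vary widely and evoked components can dominate the
post-trigger interval.

## Numerical and policy details

- **Two-pass filtering** is forward–backward over the finite window with
  no padding or reflection; both edge transients are handled entirely by
  the 85-sample trim, matching the modelled pipeline's explicit step order.
  The trim exceeds the 64-sample group delay but not the full 128-sample
  settling span, so a few percent of transient remains at the trimmed
  edges; it is small, and symmetric between methods.
- **Crossing detection** fires when the wrapped phase step
  `delta = wrap(curr - prev)` is positive, smaller than pi/2, and the
  target lies inside the traversed arc. The arc test (rather than a naive
  sign change of the wrapped offset) is what excludes the wrap-around
  artifact in which a small backward slip across +/-pi masquerades as a
  crossing of the target's antipode.
- **Degenerate windows** (zero variance, e.g. an all-constant input) admit
  no AR fit; the window is skipped for triggering rather than guessed at.
- **Watson U² ties** are processed as single groups, advancing both
  cumulative counts before the difference is recorded and weighting each
  group by its size; ties have probability zero for continuous phases but
  arise in tests and when comparing a sample with itself (which correctly
  yields U² = 0).
- **Critical values** are used analytically (2.9957..., 0.18688...) and
  displayed truncated to the conventional three decimals (2.995, 0.187);
  `watson_critical()` inverts the asymptotic tail series by root finding.
- **Published reference tables** shipped with the package are reproduced
  at their printed precision by `zplf_all()` and `circular_mean()` (see
  `scripts/acceptance.R`). The printed per-participant PLF and Z values
  are not exactly self-consistent (Z differs from n·PLF² by up to a few
  percent, more than printed rounding explains), so only the group-level
  aggregations are asserted exactly.

## Problem sizes used in the test suite

The closed-loop benchmark in the test suite runs four conditions
(Yule–Walker and LMS, peak and trough) over 300 s of synthetic alpha at
10 dB — roughly 540 triggers per condition, enough that the Rayleigh
criterion and the +/-0.5 rad circular-mean band are tested with comfortable
statistical margin. Monte-Carlo checks of the two significance criteria use
10^5 replicates (Rayleigh, N = 1000) and 10^4 replicates (Watson,
n = m = 50 von Mises draws). These sizes were chosen so the whole suite
completes in a couple of minutes on one core while keeping simulation error
well inside the asserted tolerances.

## Known limitations

- Single channel, single (resting-like) regime; no evoked responses, so
  the second post-stimulus phase-locking peak reported for visual
  conditions in the modelled study has no analogue here.
- The record reader accepts single-column delimited text with a JSON
  sidecar; EDF and other binary acquisition formats are out of scope.
- No model-order selection (AIC/BIC) or alternative AR estimators (Burg,
  covariance method); the order-30 Yule–Walker/LMS pair is the modelled
  design.
- Sub-sample trigger interpolation is not attempted; trigger timing is
  quantised to the 2 ms working-rate grid.
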