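---
title: "Methods: distance-correlation quality scores for auscultation sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-correlation quality scores for auscultation sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auscultQC)
```

## The experimental model

One bench session evaluates one sensor with a set of experiments. Each
experiment is a synchronized triple: a phantom (body-sound) signal `p`
played at the fixed gain 1/40, an ambient noise `s` played at one of
the gains in `V = {1/40, 1/10, 1/2}`, and the sensor recording `r`.
Signals are peak-normalized before playback with `n_y(x) = y·x /
max|x|`. Across the experiments of a session, each of the three signal
slots can be treated as a random variable with one observation per
experiment, which is what makes the empirical distance correlation
(dCor) applicable: it is 0 exactly under statistical independence and 1
exactly under affine dependence, for observations of any dimension.

The package computes, per ambient gain `v`:

* fidelity `dcor(p-ensemble, r-ensemble)` and leakage
  `dcor(s-ensemble, r-ensemble)`, in the time domain or over Fourier
  amplitude spectra restricted to below 4 kHz;
* windowed variants where the spectra are sliced to each of the 18 Bark
  critical bands below 4 kHz.

Gain-averaged fidelity `y` and complement-of-leakage `x` combine into
the quality score `Q = x·y` (broadband), and per band into
`Q_f = x_f · y_f` with `Q_bark` their mean over the 18 bands. A
conventional spectral SNR, `10·log10(‖fft(r)‖²/‖fft(s)‖²)`, is
reported per experiment as a cross-check; unlike the dCor statistics it
uses the full band, since nothing in its definition restricts it to
4 kHz.

### Assumptions

* Playback and recording are synchronized (the simulator's latency
  defaults to 0 for this reason; a latency parameter exists to study
  violations).
* The phantom and ambient sources are statistically independent. For
  high-dimensional observations the plain V-statistic dCor of two
  independent ensembles still sits well above zero at small `n` (a
  known small-sample/high-dimension bias); the clamped bias-corrected
  U-statistic estimator is the one that reports such independence as
  zero to many decimals. Both estimators are provided; `biased_v` is
  the default, and tests cover the contrast explicitly.
* All signals of a session share one sample rate and length; the loader
  refuses to resample silently.

## Numerical and convention choices

* **Normalization denominator.** The printed form `y·x/max(x)` maps
  only non-negative signals into `[0, y]`; audio is signed. The package
  uses `max(|x|)`, giving output in `[-y, y]` with peak exactly `y`.
* **Spectra.** One un-windowed DFT of the whole signal, magnitudes
  only, bins with frequency strictly below the cutoff retained. No
  segmentation or averaging, since the statistic consumes the spectrum
  as a vector observation rather than estimating a PSD.
* **Bands.** Half-open `[start, start + bw)`; the last Bark band
  (nominally ending at 4400 Hz) is clipped at the 4 kHz analysis edge.
* **Zero-variance convention.** A constant ensemble (e.g. all-silence
  noise at one gain) makes the dCor ratio undefined; the package
  returns 0 with a warning — a constant carries no information about
  the recording.
* **Silence in the roster.** `normalize_signal` errors on an all-zero
  input by contract, but the pipeline passes silence through unchanged
  (`allow_zero = TRUE`): the silence condition is a legitimate
  experiment, and `y·0 = 0` is its only sensible normalization. Silence
  contributes to gain averages like any other noise (its leakage is 0
  by the convention above when it forms the whole ensemble; in mixed
  ensembles it is simply one observation).
* **Gain completeness.** `Q` is an average over the whole gain set, so
  a missing gain is an error, never imputed.
* **Roster size.** The roster is always the full Cartesian product
  `|P|·|S|·|V|` (6 × 9 × 3 = 162 with the default ids). The original
  experiment reports 135 experiments, a count not derivable from its
  own set sizes; the package does not emulate it.
* **Ranking ties.** Fractional (average) ranks by default, matching the
  fractional ranks conventionally printed in material-selection tables;
  a lexicographic tie-break (by material name) is available and ties
  are flagged.
* **Curve fit.** `f(x) = 1 − exp(w0(x−1) + w1)` is fitted by a damped
  Gauss–Newton (Levenberg–Marquardt) iteration from the default init
  `(1, 2)`, step tolerance `1e-10`. `stats::nls` was rejected because
  it errors on zero-residual (exact) data, which the tests exercise.
  The fitted curve's value at zero leakage, `f(0) = 1 − exp(w1 − w0)`,
  is reported explicitly as `fitted_at_zero`; no secondary "maximum
  fidelity" quantity is derived from `w1` alone, because no such
  derivation is consistent with the model form.
* **Impedance display.** `z = ρ·v` is kept at full precision; the
  display column rounds to 3 significant figures in units of 1e6,
  except below 0.01e6 (the air row) where 1 significant figure is the
  convention. The Elastic50a reference row is excluded from checks: its
  printed density × velocity does not reproduce its printed impedance.
* **Time-shift sign.** `δt` is material onset minus water-only onset,
  so materials faster than water give `δt < 0` and
  `v = h/(δt + h/v_water)` is self-consistent; the round-trip
  `v → δt → v` is tested to 1e-9 relative.

## What the simulator emulates — and what it does not

`gen_experiment_set` produces triplets with the statistical structure
the evaluation needs:

* **Phantom signals** (`lung_burst`): Gaussian noise band-limited to
  50–2500 Hz, amplitude-modulated by a 0.2–0.5 Hz breathing envelope —
  the spectral concentration and cross-experiment variability of lung
  sounds, not their physiology or diagnostic content.
* **Noises**: i.i.d. uniform on [−1, 1]; pink noise with 1/f power
  (validated at −3 ± 1 dB/octave over 100–3200 Hz); silence; and a
  babble of six band-limited, syllabically modulated voices standing in
  for hospital ambience.
* **Sensor**: `r = A∗p + λ·(B∗s) + σ·ε` with finite impulse responses
  `A`, `B`, leakage coefficient `λ`, white sensor noise `σ`, optional
  latency. Every generator is a pure function of its arguments
  including the seed.

The defaults used in tests are desk-scale — 1 s at 8 kHz rather than
5 s at 44.1 kHz — because the statistics act on ensembles across
experiments, so shorter signals preserve the structure while keeping
runtimes near a minute; the full-scale geometry is supported through
the same arguments. The simulator does not model room or gelatin
acoustics, dBA calibration (gains are dimensionless), microphone
nonlinearity, or adhesive/seam effects. Consequently a green test
establishes that the statistics behave correctly on a stated forward
model (leakage monotone in λ, quality antitone, fidelity degrading with
sensor noise) — it does not certify any physical sensor, and the bench
study's numeric tables are not reproducible without its recordings.

## Known limitations

* The V-statistic's high-dimension bias (above) means absolute fidelity
  and leakage values depend on the ensemble size `n`; comparisons
  should therefore hold `n` and geometry fixed across sensors, as the
  roster design does.
* The Bark scheme is fixed to the 18 printed bands below 4 kHz; other
  cutoffs require a custom band scheme.
* WAV I/O supports mono/averaged-to-mono PCM 16/24 and float32 only;
  float32 is the interchange default to keep round trips exact.
* RunConfig files are JSON (no YAML parser in the supported
  dependency set).
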