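# auscultQC

Quality evaluation for digital stethoscope (auscultation) sensors
recorded on an acoustic phantom in the presence of ambient noise.

## The problem

An electret-microphone stethoscope couples the skin (or a
tissue-mimicking phantom) to an internal air column through a diaphragm.
Its recordings mix the body sound we want with ambient noise we do not.
Given a bench session where, for each experiment, a known phantom sound
`p` and a known ambient noise `s` are played simultaneously and the
sensor output `r` is recorded, `auscultQC` quantifies how good the
sensor is:

- **Signal fidelity** `dcor(p, r)` — the empirical distance correlation
  between the ensemble of emitted phantom signals and the ensemble of
  recordings. 1 means the recording is an affine transform of the body
  sound; 0 means statistical independence.
- **Noise leakage** `dcor(s, r)` — the same statistic against the
  ambient-noise ensemble.
- **Quality score** `Q = x · y` with `y` the gain-averaged fidelity and
  `x` the gain-averaged complement of leakage: the area of the rectangle
  a sensor spans toward the ideal corner (fidelity 1, leakage 0).
  Computed broadband (time domain, or amplitude spectra below 4 kHz) and
  windowed over the 18 Bark critical bands of human hearing
  (`Q_bark = mean_f x_f · y_f`).
- **SNR** `10·log10(‖fft(r)‖² / ‖fft(s)‖²)` as a conventional
  cross-check.
- **Acoustic impedance** `z = ρ·v` of candidate diaphragm materials from
  through-transmission time shifts, with the water-path calibration
  `v_water(t) = 1404.3 + 4.7·t − 0.04·t²` and
  `v = h / (δt + h/v_water)`.
- An **exponential fidelity–leakage frontier**
  `f(x) = 1 − exp(w0·(x − 1) + w1)` fitted by least squares, plus Pareto
  and ranking tables for material selection.

Statistics are always computed per ambient-noise gain (default gain set
`{1/40, 1/10, 1/2}`; the phantom always plays at `1/40`) and then
averaged — experiments at different noise levels are never pooled into
one ensemble.

A seedable sound-booth simulator (lung-sound-like bursts; uniform, pink,
silence and babble noises; a convolutional sensor model with a leakage
coefficient λ and sensor noise σ) makes the whole pipeline testable
without any laboratory recordings.

## Worked example

```r
library(auscultQC)

# a 6-phantom x 9-noise x 3-gain roster (162 experiments per sensor)
roster  <- default_roster()
sensors <- list(sensor_config("TPU", 1, "hole_2mm"),
                sensor_config("TPU", 1, "no_hole"))
cfgs    <- list(simulator_config(signal_filter = c(1, 0.3, 0.1),
                                 noise_filter = c(0.8, 0.4),
                                 leakage = 0.05, sensor_noise_sd = 0.002,
                                 seed = 3),
                simulator_config(signal_filter = c(1, 0.3, 0.1),
                                 noise_filter = c(0.8, 0.4),
                                 leakage = 0.9, sensor_noise_sd = 0.002,
                                 seed = 3))
sets <- gen_experiment_set(sensors, roster, cfgs,
                           duration_s = 1, rate_hz = 8000, seed = 21)
quality_report(sets[[1]], bands = NULL)
quality_score(sets[[2]], "freq")$q
```

prints (run exactly as above):

```
<quality_report TPU_1mm_hole_2mm>
  q_freq = 0.3528 (x = 0.4449, y = 0.7929), q_time = 0.4066, q_bark = NA
  per-gain fidelity (freq):  0.025: 0.976, 0.1: 0.956, 0.5: 0.446
  per-gain leakage  (freq):  0.025: 0.305, 0.1: 0.412, 0.5: 0.949
[1] 0.006478854
```

The low-leakage sensor (λ = 0.05, emulating a diaphragm with a 2 mm
hole and good noise isolation) keeps fidelity above 0.95 at the two
quieter gains and earns `Q_freq = 0.35`; at the loudest gain (1/2) even
this sensor leaks heavily, which is exactly what pulls `x` down. The
λ = 0.9 sensor's recordings are dominated by ambient noise and its
score collapses to 0.006. Fidelity falls and leakage rises as the
ambient gain grows from 1/40 to 1/2 — the same qualitative behaviour
the bench experiment shows.

The impedance module reproduces bench arithmetic exactly:

```r
acoustic_impedance(1040, 1095)   # PDMS: 1.1388e6 kg m^-2 s^-1 -> prints 1.14e6
water_sound_speed(23.3)          # 1492.0944 m/s
```

## Command line

```sh
Rscript -e 'quit(status = auscultQC::ausc_cli(commandArgs(TRUE)))' \
  simulate --out tree --seed 7 --sensors 2
Rscript -e 'quit(status = auscultQC::ausc_cli(commandArgs(TRUE)))' \
  evaluate --roster tree/roster.csv --out reports
```

Subcommands: `simulate`, `evaluate`, `spectrum`, `rank`, `fitcurve`,
`impedance`. All outputs are WAV/CSV/JSON.

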