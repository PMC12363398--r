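#' @title Synthetic sound-booth simulator
#' @description
#' Seedable generators that emulate the phantom experiment: 5-s (by
#' default here, desk-scale 1-s) band-limited lung-sound-like bursts as
#' phantom signals; uniform, pink, silence and babble-like ambient
#' noises; and a forward sensor model `r = A * p + lambda * (B * s) +
#' sigma * eps` (convolutions, optional latency) producing recordings
#' with controllable leakage. Every generator is a pure function of its
#' arguments including the seed.
#' @name simulator
NULL

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# Mix a base seed with a string key into a stable derived seed < 2^31.
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% 1048573
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 17) %% 2147483587)
}

# zero-phase band-pass via FFT masking
fft_bandpass <- function(x, rate_hz, lo_hz, hi_hz) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) * rate_hz / n
  # mirror frequencies above Nyquist to their negative-frequency value
  f2 <- pmin(freqs, rate_hz - freqs)
  mask <- as.numeric(f2 >= lo_hz & f2 <= hi_hz)
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

#' Generate a phantom (body-sound) signal
#'
#' `"lung_burst"` emulates a respiratory recording: Gaussian noise
#' band-limited to 50-2500 Hz, amplitude-modulated by a slow breathing
#' envelope with a seeded rate in 0.2-0.5 Hz, peak-normalized to 1.
#' `"tone"` is a pure sinusoid (default 440 Hz via `tone_hz`) and
#' `"chirp"` a linear frequency sweep 100-2000 Hz; both are useful as
#' deterministic probes.
#'
#' @param kind `"lung_burst"`, `"tone"` or `"chirp"`.
#' @param duration_s,rate_hz Duration (s) and sample rate (Hz).
#' @param seed Integer seed; output is bit-identical for equal arguments.
#' @param tone_hz Frequency for `kind = "tone"`.
#' @return A [signal()] with role `"phantom"` and peak amplitude <= 1.
#' @export
gen_phantom_signal <- function(kind = c("lung_burst", "tone", "chirp"),
                               duration_s = 1, rate_hz = 8000, seed = 1,
                               tone_hz = 440) {
  kind <- match.arg(kind)
  if (duration_s <= 0 || rate_hz <= 0) {
    stop("gen_phantom_signal: duration and rate must be positive",
         call. = FALSE)
  }
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  x <- switch(kind,
    tone = sin(2 * pi * tone_hz * t),
    chirp = sin(2 * pi * (100 * t + (2000 - 100) / (2 * duration_s) * t^2)),
    lung_burst = with_seed(seed, {
      raw <- stats::rnorm(n)
      band <- fft_bandpass(raw, rate_hz, 50,
                           min(2500, rate_hz / 2 * 0.95))
      breath_hz <- stats::runif(1, 0.2, 0.5)
      phase <- stats::runif(1, 0, 2 * pi)
      env <- 0.55 + 0.45 * sin(2 * pi * breath_hz * t + phase)
      band * env^2
    })
  )
  m <- max(abs(x))
  if (m > 0) x <- x / m
  signal(x, rate_hz, "phantom")
}

#' Generate an ambient-noise signal
#'
#' `"uniform"`: i.i.d. Uniform(-1, 1). `"pink"`: power spectral density
#' proportional to 1/f (about -3 dB per octave), built by 1/sqrt(f)
#' spectral shaping of white noise. `"silence"`: all zeros. `"babble"`:
#' a sum of six independently band-limited, slowly amplitude-modulated
#' noise "voices" emulating multi-talker hospital ambience. Non-silent
#' outputs are peak-normalized to 1.
#'
#' @param kind `"uniform"`, `"pink"`, `"silence"` or `"babble"`.
#' @inheritParams gen_phantom_signal
#' @return A [signal()] with role `"noise"`.
#' @export
gen_noise_signal <- function(kind = c("uniform", "pink", "silence",
                                      "babble"),
                             duration_s = 1, rate_hz = 8000, seed = 1) {
  kind <- match.arg(kind)
  if (duration_s <= 0 || rate_hz <= 0) {
    stop("gen_noise_signal: duration and rate must be positive",
         call. = FALSE)
  }
  n <- round(duration_s * rate_hz)
  x <- switch(kind,
    silence = numeric(n),
    uniform = with_seed(seed, stats::runif(n, -1, 1)),
    pink = with_seed(seed, {
      white <- stats::rnorm(n)
      spec <- stats::fft(white)
      freqs <- (seq_len(n) - 1) * rate_hz / n
      f2 <- pmin(freqs, rate_hz - freqs)
      shape <- ifelse(f2 > 0, 1 / sqrt(f2), 0)  # drop DC
      Re(stats::fft(spec * shape, inverse = TRUE)) / n
    }),
    babble = with_seed(seed, {
      t <- (seq_len(n) - 1) / rate_hz
      voices <- lapply(seq_len(6), function(v) {
        lo <- stats::runif(1, 80, 300)
        hi <- lo + stats::runif(1, 500, 2500)
        mod_hz <- stats::runif(1, 2, 6)  # syllabic rate
        phase <- stats::runif(1, 0, 2 * pi)
        env <- pmax(0, sin(2 * pi * mod_hz * t + phase))
        fft_bandpass(stats::rnorm(n), rate_hz, lo,
                     min(hi, rate_hz / 2 * 0.95)) * env
      })
      Reduce(`+`, voices)
    })
  )
  if (kind != "silence") {
    m <- max(abs(x))
    if (m > 0) x <- x / m
  }
  signal(x, rate_hz, "noise")
}

#' Simulator (sensor forward model) configuration
#'
#' The recording of a sensor is modeled as
#' `r = A * p + lambda * (B * s) + sigma * eps`, where `A` and `B` are
#' finite impulse responses (`*` is convolution truncated to the input
#' length), `lambda` scales the ambient leakage path, `eps` is white
#' Gaussian sensor noise, and an optional integer latency delays the
#' output.
#'
#' @param signal_filter Impulse response applied to the phantom signal
#'   (default identity).
#' @param noise_filter Impulse response applied to the ambient noise.
#' @param leakage Leakage coefficient lambda >= 0.
#' @param sensor_noise_sd Additive white-noise standard deviation
#'   sigma >= 0.
#' @param latency_samples Non-negative integer output delay (default 0:
#'   playback and recording are synchronized).
#' @param seed Integer seed driving the sensor-noise draw.
#' @return A `simulator_config` object.
#' @export
simulator_config <- function(signal_filter = 1, noise_filter = 1,
                             leakage = 0, sensor_noise_sd = 0,
                             latency_samples = 0L, seed = 1L) {
  if (length(signal_filter) == 0L || length(noise_filter) == 0L) {
    stop("simulator_config: filters must be non-empty", call. = FALSE)
  }
  if (leakage < 0 || sensor_noise_sd < 0) {
    stop("simulator_config: leakage and sensor_noise_sd must be >= 0",
         call. = FALSE)
  }
  if (latency_samples < 0 || latency_samples != round(latency_samples)) {
    stop("simulator_config: latency_samples must be a non-negative integer",
         call. = FALSE)
  }
  structure(list(signal_filter = as.numeric(signal_filter),
                 noise_filter = as.numeric(noise_filter),
                 leakage = as.numeric(leakage),
                 sensor_noise_sd = as.numeric(sensor_noise_sd),
                 latency_samples = as.integer(latency_samples),
                 seed = as.integer(seed)),
            class = "simulator_config")
}

conv_trunc <- function(x, h) {
  if (length(h) == 1L) return(x * h)
  full <- stats::convolve(x, rev(h), type = "open")
  full[seq_along(x)]
}

#' Simulate one sensor recording
#'
#' Applies the forward model of [simulator_config()] to a normalized
#' phantom/noise pair. Deterministic given the config seed.
#'
#' @param p_norm,s_norm Normalized phantom and noise [signal()]s of equal
#'   length and rate.
#' @param cfg A [simulator_config()].
#' @return A [signal()] with role `"recording"`.
#' @export
simulate_recording <- function(p_norm, s_norm, cfg) {
  stopifnot_signal(p_norm, "p_norm")
  stopifnot_signal(s_norm, "s_norm")
  if (!inherits(cfg, "simulator_config")) {
    stop("simulate_recording: 'cfg' must be a simulator_config",
         call. = FALSE)
  }
  n <- length(p_norm$samples)
  if (n != length(s_norm$samples) ||
      p_norm$sample_rate_hz != s_norm$sample_rate_hz) {
    stop("simulate_recording: signals must share length and rate",
         call. = FALSE)
  }
  r <- conv_trunc(p_norm$samples, cfg$signal_filter) +
    cfg$leakage * conv_trunc(s_norm$samples, cfg$noise_filter)
  if (cfg$sensor_noise_sd > 0) {
    r <- r + with_seed(cfg$seed,
                       stats::rnorm(n, sd = cfg$sensor_noise_sd))
  }
  if (cfg$latency_samples > 0) {
    k <- min(cfg$latency_samples, n)
    r <- c(numeric(k), r)[seq_len(n)]
  }
  signal(r, p_norm$sample_rate_hz, "recording")
}

#' Default roster ids mirroring the study's source-sound mix
#'
#' Six lung-sound phantoms and nine ambient noises (six babble-like
#' hospital ambiences plus generated uniform noise, pink noise and
#' silence), crossed with the three default gains: 162 combinations.
#'
#' @param n_phantoms,n_babble Counts of lung-sound and babble ids.
#' @param gains Gain set.
#' @return A roster data.frame from [build_roster()].
#' @export
default_roster <- function(n_phantoms = 6, n_babble = 6,
                           gains = default_gains()) {
  build_roster(sprintf("lung%02d", seq_len(n_phantoms)),
               c(sprintf("babble%02d", seq_len(n_babble)),
                 "uniform", "pink", "silence"),
               gains)
}

noise_kind_for_id <- function(noise_id) {
  for (k in c("uniform", "pink", "silence", "babble")) {
    if (grepl(k, noise_id, fixed = TRUE)) return(k)
  }
  "babble"
}

#' Generate full experiment sets for a list of sensors
#'
#' Reproduces the structure of the phantom experiment: for every roster
#' row, the phantom signal is normalized at the fixed 1/40 gain, the
#' ambient noise at the roster gain (silence passes through as zeros),
#' and a recording is simulated with the sensor's forward model. Source
#' signals are generated once per id (seeded from `seed` and the id) and
#' shared across sensors and gains, as in a real sound-booth session.
#'
#' @param sensors List of [sensor_config()]s.
#' @param roster Roster data.frame (see [build_roster()],
#'   [default_roster()]).
#' @param cfg_per_sensor List of [simulator_config()]s, one per sensor.
#' @param duration_s,rate_hz Signal geometry (desk-scale default 1 s at
#'   8 kHz; the full-scale 5 s at 44.1 kHz is supported).
#' @param seed Master seed.
#' @return List of [experiment_set()]s, one per sensor; each has
#'   `nrow(roster)` experiments.
#' @export
gen_experiment_set <- function(sensors, roster, cfg_per_sensor,
                               duration_s = 1, rate_hz = 8000,
                               seed = 1) {
  if (nrow(roster) == 0L) {
    stop("gen_experiment_set: empty roster", call. = FALSE)
  }
  if (length(sensors) != length(cfg_per_sensor)) {
    stop("gen_experiment_set: need one simulator_config per sensor",
         call. = FALSE)
  }
  phantom_ids <- unique(roster$phantom_id)
  noise_ids <- unique(roster$noise_id)
  phantoms <- lapply(phantom_ids, function(id)
    gen_phantom_signal("lung_burst", duration_s, rate_hz,
                       derive_seed(seed, paste0("p:", id))))
  names(phantoms) <- phantom_ids
  noises <- lapply(noise_ids, function(id)
    gen_noise_signal(noise_kind_for_id(id), duration_s, rate_hz,
                     derive_seed(seed, paste0("s:", id))))
  names(noises) <- noise_ids
  p_norms <- lapply(phantoms, normalize_signal, y = phantom_gain())
  lapply(seq_along(sensors), function(si) {
    sensor <- sensors[[si]]
    cfg <- cfg_per_sensor[[si]]
    exps <- lapply(seq_len(nrow(roster)), function(i) {
      row <- roster[i, ]
      p_norm <- p_norms[[row$phantom_id]]
      s_norm <- normalize_signal(noises[[row$noise_id]], row$gain,
                                 allow_zero = TRUE)
      cfg_i <- cfg
      cfg_i$seed <- derive_seed(
        cfg$seed, sprintf("r:%d:%s:%s:%g", si, row$phantom_id,
                          row$noise_id, row$gain))
      r <- simulate_recording(p_norm, s_norm, cfg_i)
      experiment_triplet(sensor, row$phantom_id, row$noise_id, row$gain,
                         p_norm, s_norm, r)
    })
    experiment_set(sensor, exps)
  })
}
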