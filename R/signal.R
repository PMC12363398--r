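#' Audio signal container
#'
#' A sampled audio vector with its sample rate and a role describing which
#' side of a phantom experiment it came from: the emitted body-sound
#' (`"phantom"`), the emitted ambient noise (`"noise"`), or the sensor
#' output (`"recording"`).
#'
#' @param samples Numeric vector of dimensionless amplitudes. Must be
#'   non-empty and finite.
#' @param sample_rate_hz Positive sampling rate in Hz (default 44100).
#' @param role One of `"phantom"`, `"noise"`, `"recording"`.
#' @return An object of class `ausc_signal`.
#' @export
signal <- function(samples, sample_rate_hz = 44100,
                   role = c("phantom", "noise", "recording")) {
  role <- match.arg(role)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("signal: 'samples' must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("signal: 'samples' must be finite", call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("signal: 'sample_rate_hz' must be a positive number", call. = FALSE)
  }
  structure(
    list(samples = samples, sample_rate_hz = as.numeric(sample_rate_hz),
         role = role),
    class = "ausc_signal"
  )
}

#' @export
print.ausc_signal <- function(x, ...) {
  cat(sprintf("<ausc_signal role=%s n=%d rate=%g Hz dur=%.3f s peak=%.4g>\n",
              x$role, length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz, max(abs(x$samples))))
  invisible(x)
}

is_signal <- function(x) inherits(x, "ausc_signal")

stopifnot_signal <- function(x, what = "x") {
  if (!is_signal(x)) stop(sprintf("'%s' must be an ausc_signal", what),
                          call. = FALSE)
  invisible(x)
}

#' Default ambient-noise gain set
#'
#' The three ambient-noise playback gains used throughout:
#' 1/40, 1/10 and 1/2 (nominally 57, 68 and 79 dBA in the original sound
#' booth; here treated as dimensionless amplitude scalings). The phantom
#' signal is always played at the fixed gain 1/40.
#'
#' @return Numeric vector `c(1/40, 1/10, 1/2)`.
#' @export
default_gains <- function() c(1 / 40, 1 / 10, 1 / 2)

#' Fixed phantom playback gain
#' @return `1/40`.
#' @export
phantom_gain <- function() 1 / 40

check_gain <- function(y) {
  if (!is.numeric(y) || length(y) != 1L || !is.finite(y) ||
      y <= 0 || y > 1) {
    stop("gain must be a single number in (0, 1]", call. = FALSE)
  }
  as.numeric(y)
}

#' Peak-normalize a signal to a target gain
#'
#' Rescales a signal so its largest absolute sample equals the gain `y`:
#' `n_y(x) = y * x / max(|x|)`. Audio is signed, so the maximum is taken
#' over absolute values and the output lies in `[-y, y]` (for a
#' non-negative input this reduces to the plain `y * x / max(x)` mapping
#' into `[0, y]`).
#'
#' @param x An [signal()] object.
#' @param y Target gain in (0, 1].
#' @param allow_zero If `TRUE`, an all-zero signal is returned unchanged
#'   instead of raising an error. The evaluation pipeline uses this for the
#'   silence noise condition; the default contract is to error.
#' @return A normalized [signal()] with the same role and rate;
#'   `max(abs(samples))` equals `y` exactly (or 0 when `allow_zero`).
#' @export
normalize_signal <- function(x, y, allow_zero = FALSE) {
  stopifnot_signal(x)
  y <- check_gain(y)
  m <- max(abs(x$samples))
  if (m == 0) {
    if (allow_zero) return(x)
    stop("normalize_signal: all-zero signal, normalization undefined",
         call. = FALSE)
  }
  signal(y * x$samples / m, x$sample_rate_hz, x$role)
}

#' One-sided Fourier amplitude spectrum below a cutoff
#'
#' Computes the modulus of the discrete Fourier transform of the whole
#' signal (no windowing, no segment averaging) and retains the bins whose
#' frequency is strictly below `f_max_hz`. Phase is discarded. The
#' dependence statistics restrict spectra to 4 kHz, which is the default.
#'
#' @param x An [signal()] object.
#' @param f_max_hz Cutoff frequency in Hz; must not exceed Nyquist.
#' @return An `amplitude_spectrum` object with fields `magnitudes`,
#'   `bin_frequencies_hz` (increasing, starting at 0) and `f_max_hz`.
#' @export
amplitude_spectrum <- function(x, f_max_hz = 4000) {
  stopifnot_signal(x)
  nyq <- x$sample_rate_hz / 2
  if (!is.numeric(f_max_hz) || length(f_max_hz) != 1L || f_max_hz <= 0) {
    stop("amplitude_spectrum: 'f_max_hz' must be a positive number",
         call. = FALSE)
  }
  if (f_max_hz > nyq) {
    stop(sprintf(
      "amplitude_spectrum: f_max_hz (%g) exceeds Nyquist (%g)",
      f_max_hz, nyq), call. = FALSE)
  }
  n <- length(x$samples)
  freqs <- (seq_len(n) - 1) * x$sample_rate_hz / n
  keep <- freqs < f_max_hz
  mags <- Mod(stats::fft(x$samples))[keep]
  structure(
    list(magnitudes = mags, bin_frequencies_hz = freqs[keep],
         f_max_hz = as.numeric(f_max_hz)),
    class = "amplitude_spectrum"
  )
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf("<amplitude_spectrum %d bins, [0, %g) Hz, df=%.4g Hz>\n",
              length(x$magnitudes), x$f_max_hz,
              if (length(x$bin_frequencies_hz) > 1)
                diff(x$bin_frequencies_hz[1:2]) else NA_real_))
  invisible(x)
}

#' Frequency band descriptor
#'
#' @param start_hz Non-negative band start in Hz.
#' @param bandwidth_hz Positive bandwidth in Hz. The band covers the
#'   half-open interval `[start_hz, start_hz + bandwidth_hz)`.
#' @return A `frequency_band` object.
#' @export
frequency_band <- function(start_hz, bandwidth_hz) {
  if (!is.numeric(start_hz) || start_hz < 0) {
    stop("frequency_band: 'start_hz' must be non-negative", call. = FALSE)
  }
  if (!is.numeric(bandwidth_hz) || bandwidth_hz <= 0) {
    stop("frequency_band: 'bandwidth_hz' must be positive", call. = FALSE)
  }
  structure(list(start_hz = as.numeric(start_hz),
                 bandwidth_hz = as.numeric(bandwidth_hz)),
            class = "frequency_band")
}

#' Extract the spectrum magnitudes inside a frequency band
#'
#' Returns the magnitudes of the bins with frequency in
#' `[start_hz, start_hz + bandwidth_hz)`. Bands extending past the
#' spectrum's `f_max_hz` are clipped at `f_max_hz` (the last Bark band
#' nominally ends at 4400 Hz but the analysis stops at 4 kHz).
#'
#' @param sp An [amplitude_spectrum()].
#' @param band A [frequency_band()].
#' @return Numeric vector of magnitudes; errors if the band contains no
#'   bins at this resolution.
#' @export
band_slice <- function(sp, band) {
  if (!inherits(sp, "amplitude_spectrum")) {
    stop("band_slice: 'sp' must be an amplitude_spectrum", call. = FALSE)
  }
  if (!inherits(band, "frequency_band")) {
    stop("band_slice: 'band' must be a frequency_band", call. = FALSE)
  }
  lo <- band$start_hz
  hi <- band$start_hz + band$bandwidth_hz
  keep <- sp$bin_frequencies_hz >= lo & sp$bin_frequencies_hz < hi
  if (!any(keep)) {
    stop(sprintf(
      "band_slice: band [%g, %g) Hz contains no spectrum bins", lo, hi),
      call. = FALSE)
  }
  sp$magnitudes[keep]
}

# Critical-band edges of the Bark scale below 4 kHz.
BARK_STARTS <- c(20, 100, 200, 300, 400, 510, 630, 770, 920, 1080,
                 1270, 1480, 1720, 2000, 2320, 2700, 3150, 3700)
BARK_BANDWIDTHS <- c(80, 100, 100, 100, 110, 120, 140, 150, 160, 190,
                     210, 240, 280, 320, 380, 450, 550, 700)

#' Bark critical bands below 4 kHz
#'
#' The 18 critical bands of human hearing on the Bark scale whose start
#' frequencies lie below 4 kHz. Bands are contiguous:
#' `start[i+1] = start[i] + bandwidth[i]`. The last band nominally extends
#' to 4400 Hz; [band_slice()] clips it at the spectrum's `f_max_hz`.
#'
#' @param f_max_hz Analysis cutoff; the scheme is defined for 4000 Hz.
#' @return A list of 18 [frequency_band()] objects, named by start
#'   frequency.
#' @export
bark_bands <- function(f_max_hz = 4000) {
  if (f_max_hz != 4000) {
    stop("bark_bands: the Bark critical-band scheme is defined for f_max_hz = 4000",
         call. = FALSE)
  }
  bands <- Map(frequency_band, BARK_STARTS, BARK_BANDWIDTHS)
  names(bands) <- as.character(BARK_STARTS)
  bands
}

#' Experiment roster: Cartesian product of phantoms, noises and gains
#'
#' Enumerates every (phantom, noise, gain) playback combination in
#' deterministic phantom-major order (phantom varies slowest, then noise,
#' then gain). One sensor's experiment set plays each combination once.
#'
#' @param phantom_ids Character vector of distinct phantom-signal ids.
#' @param noise_ids Character vector of distinct ambient-noise ids.
#' @param gains Numeric vector of ambient gains (default [default_gains()]).
#' @return A data.frame with columns `phantom_id`, `noise_id`, `gain` and
#'   `nrow = |P| * |S| * |V|`.
#' @export
build_roster <- function(phantom_ids, noise_ids, gains = default_gains()) {
  phantom_ids <- as.character(phantom_ids)
  noise_ids <- as.character(noise_ids)
  if (length(phantom_ids) == 0L || length(noise_ids) == 0L ||
      length(gains) == 0L) {
    stop("build_roster: id and gain lists must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(phantom_ids)) {
    stop("build_roster: duplicate phantom ids", call. = FALSE)
  }
  if (anyDuplicated(noise_ids)) {
    stop("build_roster: duplicate noise ids", call. = FALSE)
  }
  if (anyDuplicated(gains)) {
    stop("build_roster: duplicate gains", call. = FALSE)
  }
  # phantom-major: gain varies fastest
  df <- expand.grid(gain = as.numeric(gains), noise_id = noise_ids,
                    phantom_id = phantom_ids,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("phantom_id", "noise_id", "gain")]
  rownames(df) <- NULL
  df
}

#' Sensor configuration (diaphragm material, thickness, hole)
#'
#' @param material One of `"TPU"`, `"PLA"`, `"Elastic50a"`, `"PDMS"`,
#'   `"NoDiaphragm"`.
#' @param thickness_mm Non-negative diaphragm thickness in millimetres;
#'   must be 0 exactly when `material == "NoDiaphragm"`.
#' @param hole `"no_hole"` or `"hole_2mm"` (a 2 mm through-hole in the
#'   diaphragm centre connecting the air column to the skin/phantom).
#' @return A `sensor_config` object.
#' @export
sensor_config <- function(material = c("TPU", "PLA", "Elastic50a", "PDMS",
                                       "NoDiaphragm"),
                          thickness_mm = 1,
                          hole = c("no_hole", "hole_2mm")) {
  material <- match.arg(material)
  hole <- match.arg(hole)
  if (!is.numeric(thickness_mm) || length(thickness_mm) != 1L ||
      thickness_mm < 0) {
    stop("sensor_config: 'thickness_mm' must be non-negative", call. = FALSE)
  }
  if ((thickness_mm == 0) != (material == "NoDiaphragm")) {
    stop("sensor_config: thickness_mm must be 0 iff material is NoDiaphragm",
         call. = FALSE)
  }
  structure(list(material = material,
                 thickness_mm = as.numeric(thickness_mm), hole = hole),
            class = "sensor_config")
}

sensor_label <- function(sensor) {
  sprintf("%s_%gmm_%s", sensor$material, sensor$thickness_mm, sensor$hole)
}

#' @export
print.sensor_config <- function(x, ...) {
  cat(sprintf("<sensor_config %s>\n", sensor_label(x)))
  invisible(x)
}

#' One phantom/noise/recording experiment
#'
#' Bundles the normalized phantom signal (played at the fixed 1/40 gain),
#' the normalized ambient-noise signal (played at `noise_gain`) and the
#' sensor recording of one synchronized playback event.
#'
#' @param sensor A [sensor_config()].
#' @param phantom_id,noise_id Identifiers of the source sounds.
#' @param noise_gain Ambient gain in (0, 1].
#' @param p_norm,s_norm,r The three [signal()]s; must share length and rate.
#' @return An `experiment_triplet` object.
#' @export
experiment_triplet <- function(sensor, phantom_id, noise_id, noise_gain,
                               p_norm, s_norm, r) {
  if (!inherits(sensor, "sensor_config")) {
    stop("experiment_triplet: 'sensor' must be a sensor_config",
         call. = FALSE)
  }
  noise_gain <- check_gain(noise_gain)
  for (nm in c("p_norm", "s_norm", "r")) stopifnot_signal(get(nm), nm)
  lens <- c(length(p_norm$samples), length(s_norm$samples),
            length(r$samples))
  rates <- c(p_norm$sample_rate_hz, s_norm$sample_rate_hz,
             r$sample_rate_hz)
  if (length(unique(lens)) != 1L) {
    stop("experiment_triplet: signals must share length", call. = FALSE)
  }
  if (length(unique(rates)) != 1L) {
    stop("experiment_triplet: signals must share sample rate", call. = FALSE)
  }
  structure(list(sensor = sensor, phantom_id = as.character(phantom_id),
                 noise_id = as.character(noise_id),
                 noise_gain = noise_gain, p_norm = p_norm,
                 s_norm = s_norm, r = r),
            class = "experiment_triplet")
}

#' All experiments recorded with one sensor
#'
#' @param sensor A [sensor_config()].
#' @param experiments List of [experiment_triplet()]s, all with this
#'   sensor and with signals of common length and rate.
#' @return An `experiment_set` object.
#' @export
experiment_set <- function(sensor, experiments) {
  if (!inherits(sensor, "sensor_config")) {
    stop("experiment_set: 'sensor' must be a sensor_config", call. = FALSE)
  }
  if (length(experiments) == 0L) {
    stop("experiment_set: 'experiments' must be non-empty", call. = FALSE)
  }
  ok <- vapply(experiments, inherits, logical(1), "experiment_triplet")
  if (!all(ok)) {
    stop("experiment_set: all elements must be experiment_triplet objects",
         call. = FALSE)
  }
  lab <- sensor_label(sensor)
  same <- vapply(experiments,
                 function(e) identical(sensor_label(e$sensor), lab),
                 logical(1))
  if (!all(same)) {
    stop("experiment_set: all experiments must share the same sensor",
         call. = FALSE)
  }
  lens <- vapply(experiments, function(e) length(e$r$samples), numeric(1))
  rates <- vapply(experiments, function(e) e$r$sample_rate_hz, numeric(1))
  if (length(unique(lens)) != 1L || length(unique(rates)) != 1L) {
    stop("experiment_set: all signals must share length and sample rate",
         call. = FALSE)
  }
  structure(list(sensor = sensor, experiments = experiments),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  gains <- sort(unique(vapply(x$experiments, `[[`, numeric(1),
                              "noise_gain")))
  cat(sprintf("<experiment_set %s: %d experiments, gains {%s}>\n",
              sensor_label(x$sensor), length(x$experiments),
              paste(signif(gains, 3), collapse = ", ")))
  invisible(x)
}

#' @export
length.experiment_set <- function(x) length(x$experiments)

set_gains <- function(es) {
  sort(unique(vapply(es$experiments, `[[`, numeric(1), "noise_gain")))
}

experiments_at_gain <- function(es, gain, tol = 1e-12) {
  sel <- vapply(es$experiments,
                function(e) abs(e$noise_gain - gain) <= tol, logical(1))
  es$experiments[sel]
}
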