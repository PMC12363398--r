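#' @title Fidelity, leakage and quality statistics for one sensor
#' @description
#' The headline statistics treat each signal of an experiment set as a
#' random variable with one observation per experiment: the emitted
#' phantom signal, the emitted ambient noise, and the sensor recording.
#' Signal fidelity is the distance correlation between the phantom
#' ensemble and the recording ensemble; noise leakage is the distance
#' correlation between the noise ensemble and the recording ensemble.
#' Both are computed per ambient-noise gain (never pooling gains into one
#' ensemble) in either the time domain or over Fourier amplitude spectra
#' restricted to 4 kHz.
#' @name sensor-statistics
NULL

# Stack one field of the experiments at a gain into an n x d ensemble.
# domain "time" uses raw samples; "freq" uses the <f_max amplitude
# spectrum; a frequency_band additionally slices the spectrum.
ensemble_matrix <- function(exps, field, domain, f_max_hz = 4000,
                            band = NULL) {
  rows <- lapply(exps, function(e) {
    sig <- e[[field]]
    if (domain == "time") return(sig$samples)
    sp <- amplitude_spectrum(sig, f_max_hz)
    if (is.null(band)) sp$magnitudes else band_slice(sp, band)
  })
  do.call(rbind, rows)
}

check_gain_present <- function(es, gain) {
  exps <- experiments_at_gain(es, gain)
  if (length(exps) == 0L) {
    stop(sprintf("no experiments at gain %g in this set", gain),
         call. = FALSE)
  }
  if (length(exps) < 2L) {
    stop(sprintf(
      "need >= 2 experiments at gain %g to form an ensemble (found %d)",
      gain, length(exps)), call. = FALSE)
  }
  exps
}

#' Signal fidelity of a sensor at one ambient gain
#'
#' Distance correlation between the ensemble of normalized phantom
#' signals and the ensemble of recordings, over the experiments at the
#' given ambient-noise gain. High fidelity means the recordings carry the
#' emitted body sound.
#'
#' @param es An [experiment_set()].
#' @param gain Ambient-noise gain selecting the experiments.
#' @param domain `"time"` (raw samples) or `"freq"` (amplitude spectra
#'   below `f_max_hz`).
#' @param f_max_hz Spectrum cutoff for `domain = "freq"` (default 4000).
#' @param estimator Passed to [dcor()].
#' @return A number in \[0, 1\].
#' @export
fidelity <- function(es, gain, domain = c("time", "freq"),
                     f_max_hz = 4000,
                     estimator = c("biased_v", "bias_corrected_u")) {
  domain <- match.arg(domain)
  estimator <- match.arg(estimator)
  exps <- check_gain_present(es, gain)
  P <- ensemble_matrix(exps, "p_norm", domain, f_max_hz)
  R <- ensemble_matrix(exps, "r", domain, f_max_hz)
  dcor(P, R, estimator)
}

#' Noise leakage of a sensor at one ambient gain
#'
#' As [fidelity()], with the normalized ambient-noise ensemble in place of
#' the phantom ensemble. High leakage means ambient noise reaches the
#' recording.
#'
#' @inheritParams fidelity
#' @return A number in \[0, 1\].
#' @export
leakage <- function(es, gain, domain = c("time", "freq"),
                    f_max_hz = 4000,
                    estimator = c("biased_v", "bias_corrected_u")) {
  domain <- match.arg(domain)
  estimator <- match.arg(estimator)
  exps <- check_gain_present(es, gain)
  S <- ensemble_matrix(exps, "s_norm", domain, f_max_hz)
  R <- ensemble_matrix(exps, "r", domain, f_max_hz)
  dcor(S, R, estimator)
}

#' Quality score from per-gain fidelity and leakage values
#'
#' The score rewards sensors close to the ideal corner (fidelity 1,
#' leakage 0): `y` is the gain-averaged fidelity, `x` the gain-averaged
#' complement of leakage, and `Q = x * y` is the area of the rectangle
#' they span.
#'
#' @param fidelity_per_gain,leakage_per_gain Equal-length numeric vectors
#'   in \[0, 1\], one value per ambient gain.
#' @return List with elements `x`, `y`, `q`.
#' @export
quality_from_stats <- function(fidelity_per_gain, leakage_per_gain) {
  if (length(fidelity_per_gain) != length(leakage_per_gain) ||
      length(fidelity_per_gain) == 0L) {
    stop("quality_from_stats: per-gain vectors must be non-empty and equal length",
         call. = FALSE)
  }
  x <- mean(1 - leakage_per_gain)
  y <- mean(fidelity_per_gain)
  list(x = x, y = y, q = x * y)
}

check_gains_complete <- function(es, gains) {
  have <- set_gains(es)
  missing <- gains[!vapply(gains, function(g)
    any(abs(have - g) <= 1e-12), logical(1))]
  if (length(missing) > 0L) {
    stop(sprintf("experiment set is missing gains: %s",
                 paste(signif(missing, 4), collapse = ", ")),
         call. = FALSE)
  }
  invisible(gains)
}

#' Broadband quality score of a sensor
#'
#' Computes fidelity and leakage at every gain of the gain set, averages
#' them, and returns `Q = x * y` (see [quality_from_stats()]). All gains
#' in `gains` must be present in the set: the score is defined as an
#' average over the full gain set.
#'
#' @inheritParams fidelity
#' @param gains The ambient gain set (default [default_gains()]).
#' @return List with `x`, `y`, `q`, and the per-gain vectors
#'   `fidelity_per_gain`, `leakage_per_gain` (named by gain).
#' @export
quality_score <- function(es, domain = c("time", "freq"),
                          gains = default_gains(), f_max_hz = 4000,
                          estimator = c("biased_v", "bias_corrected_u")) {
  domain <- match.arg(domain)
  estimator <- match.arg(estimator)
  check_gains_complete(es, gains)
  fid <- vapply(gains, function(g)
    fidelity(es, g, domain, f_max_hz, estimator), numeric(1))
  leak <- vapply(gains, function(g)
    leakage(es, g, domain, f_max_hz, estimator), numeric(1))
  names(fid) <- names(leak) <- as.character(signif(gains, 6))
  out <- quality_from_stats(fid, leak)
  out$fidelity_per_gain <- fid
  out$leakage_per_gain <- leak
  out
}

#' Windowed distance correlation across frequency bands
#'
#' For each band, the distance correlation between the band-sliced
#' amplitude spectra of the target ensemble (phantom or noise) and of the
#' recording ensemble, over the experiments at one gain. Plotted against
#' band start frequency this gives the per-band fidelity or leakage curve.
#'
#' @inheritParams fidelity
#' @param bands List of [frequency_band()]s (default [bark_bands()]).
#' @param target `"phantom"` (fidelity curve) or `"noise"` (leakage
#'   curve).
#' @return Named numeric vector, one \[0, 1\] value per band (names are
#'   band start frequencies).
#' @export
windowed_dcor_spectrum <- function(es, gain, bands = bark_bands(),
                                   target = c("phantom", "noise"),
                                   f_max_hz = 4000,
                                   estimator = c("biased_v",
                                                 "bias_corrected_u")) {
  target <- match.arg(target)
  estimator <- match.arg(estimator)
  exps <- check_gain_present(es, gain)
  field <- if (target == "phantom") "p_norm" else "s_norm"
  # compute full spectra once, slice per band
  sp_t <- lapply(exps, function(e) amplitude_spectrum(e[[field]], f_max_hz))
  sp_r <- lapply(exps, function(e) amplitude_spectrum(e$r, f_max_hz))
  out <- vapply(seq_along(bands), function(bi) {
    band <- bands[[bi]]
    Tm <- tryCatch(
      do.call(rbind, lapply(sp_t, band_slice, band = band)),
      error = function(e) stop(sprintf(
        "windowed_dcor_spectrum: empty slice for band starting %g Hz",
        band$start_hz), call. = FALSE))
    Rm <- do.call(rbind, lapply(sp_r, band_slice, band = band))
    dcor(Tm, Rm, estimator)
  }, numeric(1))
  names(out) <- if (!is.null(names(bands))) names(bands) else
    vapply(bands, function(b) as.character(b$start_hz), character(1))
  out
}

#' Bark-band windowed quality score
#'
#' Per Bark critical band `f`, `Q_f = x_f * y_f` where `y_f` is the
#' gain-averaged windowed fidelity and `x_f` the gain-averaged complement
#' of the windowed leakage in that band. The aggregate `Q_bark` is the
#' plain mean of `Q_f` over the `F` bands.
#'
#' @inheritParams quality_score
#' @param bands List of [frequency_band()]s (default the 18 Bark bands).
#' @return List with `q_per_band` (named vector), `q_bark`, and the
#'   per-band per-gain matrices `fidelity_bands` and `leakage_bands`
#'   (bands x gains).
#' @export
bark_quality <- function(es, bands = bark_bands(),
                         gains = default_gains(), f_max_hz = 4000,
                         estimator = c("biased_v", "bias_corrected_u")) {
  estimator <- match.arg(estimator)
  check_gains_complete(es, gains)
  fid <- sapply(gains, function(g)
    windowed_dcor_spectrum(es, g, bands, "phantom", f_max_hz, estimator))
  leak <- sapply(gains, function(g)
    windowed_dcor_spectrum(es, g, bands, "noise", f_max_hz, estimator))
  fid <- matrix(fid, nrow = length(bands),
                dimnames = list(names(bands),
                                as.character(signif(gains, 6))))
  leak <- matrix(leak, nrow = length(bands),
                 dimnames = dimnames(fid))
  y_f <- rowMeans(fid)
  x_f <- rowMeans(1 - leak)
  q_f <- x_f * y_f
  list(q_per_band = q_f, q_bark = mean(q_f),
       fidelity_bands = fid, leakage_bands = leak)
}

#' Spectral signal-to-noise ratio in decibels
#'
#' `10 * log10(||fft(r)||^2 / ||fft(s)||^2)`: the full-band spectral
#' power of the recording relative to the normalized ambient noise. Note
#' this SNR is full band, unlike the distance-correlation statistics
#' which restrict spectra to 4 kHz.
#'
#' @param r Recording [signal()].
#' @param s_norm Normalized ambient-noise [signal()] of equal length.
#' @return SNR in dB.
#' @export
snr_db <- function(r, s_norm) {
  stopifnot_signal(r, "r")
  stopifnot_signal(s_norm, "s_norm")
  if (length(r$samples) != length(s_norm$samples)) {
    stop("snr_db: signals must have equal length", call. = FALSE)
  }
  denom <- sum(Mod(stats::fft(s_norm$samples))^2)
  if (denom == 0) {
    stop("snr_db: silent noise signal, SNR undefined", call. = FALSE)
  }
  num <- sum(Mod(stats::fft(r$samples))^2)
  10 * log10(num / denom)
}

#' Full quality report for one sensor
#'
#' Runs every statistic on one sensor's experiment set: per-gain fidelity
#' and leakage in both domains, broadband quality scores `q_time` and
#' `q_freq`, Bark-band windowed quality `q_bark` with per-band curves,
#' and the spectral SNR of each experiment.
#'
#' @inheritParams quality_score
#' @param bands Band scheme for the windowed statistics (default
#'   [bark_bands()]); set `NULL` to skip the Bark section.
#' @param snr Compute per-experiment SNR (skips silent-noise experiments
#'   with `NA`).
#' @return A `quality_report` object.
#' @export
quality_report <- function(es, gains = default_gains(),
                           bands = bark_bands(), f_max_hz = 4000,
                           estimator = c("biased_v", "bias_corrected_u"),
                           snr = TRUE) {
  estimator <- match.arg(estimator)
  qs_time <- quality_score(es, "time", gains, f_max_hz, estimator)
  qs_freq <- quality_score(es, "freq", gains, f_max_hz, estimator)
  bq <- if (!is.null(bands)) {
    bark_quality(es, bands, gains, f_max_hz, estimator)
  } else NULL
  snrs <- NULL
  if (snr) {
    snrs <- vapply(es$experiments, function(e) {
      if (max(abs(e$s_norm$samples)) == 0) return(NA_real_)
      snr_db(e$r, e$s_norm)
    }, numeric(1))
    names(snrs) <- vapply(es$experiments, function(e)
      sprintf("%s|%s|%g", e$phantom_id, e$noise_id, e$noise_gain),
      character(1))
  }
  structure(
    list(sensor = es$sensor,
         gains = gains,
         per_gain_fidelity_time = qs_time$fidelity_per_gain,
         per_gain_leakage_time = qs_time$leakage_per_gain,
         per_gain_fidelity_freq = qs_freq$fidelity_per_gain,
         per_gain_leakage_freq = qs_freq$leakage_per_gain,
         mean_fidelity = qs_freq$y,
         mean_one_minus_leakage = qs_freq$x,
         q_time = qs_time$q,
         q_freq = qs_freq$q,
         q_bark_per_band = if (!is.null(bq)) bq$q_per_band else NULL,
         q_bark = if (!is.null(bq)) bq$q_bark else NA_real_,
         bark_fidelity = if (!is.null(bq)) bq$fidelity_bands else NULL,
         bark_leakage = if (!is.null(bq)) bq$leakage_bands else NULL,
         snr_db_per_experiment = snrs),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report %s>\n", sensor_label(x$sensor)))
  cat(sprintf("  q_freq = %.4f (x = %.4f, y = %.4f), q_time = %.4f, q_bark = %.4f\n",
              x$q_freq, x$mean_one_minus_leakage, x$mean_fidelity,
              x$q_time, x$q_bark))
  cat("  per-gain fidelity (freq): ",
      paste(sprintf("%s: %.3f", names(x$per_gain_fidelity_freq),
                    x$per_gain_fidelity_freq), collapse = ", "), "\n")
  cat("  per-gain leakage  (freq): ",
      paste(sprintf("%s: %.3f", names(x$per_gain_leakage_freq),
                    x$per_gain_leakage_freq), collapse = ", "), "\n")
  invisible(x)
}
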