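# Small experiment-set fixtures built in code. Signals are desk-scale
# (0.25 s at 2 kHz = 500 samples) unless a test needs otherwise: the
# statistics act on ensembles across experiments, so short signals keep
# the structure while keeping the suite fast.

fixture_rate <- 8000
fixture_dur <- 0.25

# n_per_gain (phantom, noise) pairs at each gain; the recording is
# produced by recording_fun(p_norm, s_norm, gain, index).
make_fixture_set <- function(recording_fun, n_per_gain = 6,
                             gains = default_gains(),
                             sensor = sensor_config("TPU", 1, "hole_2mm"),
                             seed = 100, noise_kind = "babble",
                             rate = fixture_rate, dur = fixture_dur) {
  exps <- list()
  for (g in gains) {
    for (i in seq_len(n_per_gain)) {
      p <- gen_phantom_signal("lung_burst", dur, rate,
                              seed = seed + i)
      s <- gen_noise_signal(noise_kind, dur, rate,
                            seed = seed + 1000 + i)
      p_norm <- normalize_signal(p, phantom_gain())
      s_norm <- normalize_signal(s, g, allow_zero = TRUE)
      r <- recording_fun(p_norm, s_norm, g, i)
      exps[[length(exps) + 1L]] <- experiment_triplet(
        sensor, sprintf("p%02d", i), sprintf("s%02d", i), g,
        p_norm, s_norm, r)
    }
  }
  experiment_set(sensor, exps)
}

# recording = phantom exactly (perfect sensor, no noise path)
perfect_set <- function(...) {
  make_fixture_set(function(p, s, g, i) signal(p$samples,
                                               p$sample_rate_hz,
                                               "recording"), ...)
}

# recording = normalized noise exactly (fully leaky sensor)
leaky_set <- function(...) {
  make_fixture_set(function(p, s, g, i) signal(s$samples,
                                               s$sample_rate_hz,
                                               "recording"), ...)
}

# A synthetic quality_report with prescribed per-gain statistics, for
# aggregation tests that do not need real signals.
stub_report <- function(material, thickness_mm, hole,
                        fid_freq, leak_freq,
                        fid_time = fid_freq, leak_time = leak_freq,
                        gains = default_gains(),
                        bark_fid = NULL, bark_leak = NULL) {
  nm <- as.character(signif(gains, 6))
  names(fid_freq) <- names(leak_freq) <- nm
  names(fid_time) <- names(leak_time) <- nm
  q <- quality_from_stats(fid_freq, leak_freq)
  qt <- quality_from_stats(fid_time, leak_time)
  if (is.null(bark_fid)) {
    bark_fid <- matrix(rep(fid_freq, each = 3), nrow = 3,
                       dimnames = list(c("20", "100", "200"), nm))
    bark_leak <- matrix(rep(leak_freq, each = 3), nrow = 3,
                        dimnames = list(c("20", "100", "200"), nm))
  }
  q_f <- rowMeans(bark_fid) * rowMeans(1 - bark_leak)
  structure(
    list(sensor = sensor_config(material, thickness_mm, hole),
         gains = gains,
         per_gain_fidelity_time = fid_time,
         per_gain_leakage_time = leak_time,
         per_gain_fidelity_freq = fid_freq,
         per_gain_leakage_freq = leak_freq,
         mean_fidelity = q$y, mean_one_minus_leakage = q$x,
         q_time = qt$q, q_freq = q$q,
         q_bark_per_band = q_f, q_bark = mean(q_f),
         bark_fidelity = bark_fid, bark_leakage = bark_leak,
         snr_db_per_experiment = NULL),
    class = "quality_report")
}

# Brute-force O(n^2) domination oracle for the Pareto front.
pareto_oracle <- function(pts) {
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    dominated <- FALSE
    for (j in seq_len(nrow(pts))) {
      if (j == i) next
      if (pts$x[j] <= pts$x[i] && pts$y[j] >= pts$y[i] &&
          (pts$x[j] < pts$x[i] || pts$y[j] > pts$y[i])) {
        dominated <- TRUE; break
      }
    }
    !dominated
  }, logical(1))
  pts[keep, , drop = FALSE]
}
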