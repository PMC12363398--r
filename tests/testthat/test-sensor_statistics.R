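test_that("perfect sensor: fidelity 1 in both domains, leakage below it", {
  es <- perfect_set(n_per_gain = 6)
  for (domain in c("time", "freq")) {
    expect_equal(fidelity(es, 1 / 10, domain), 1, tolerance = 1e-10)
  }
  # recordings carry no noise: bias-corrected leakage is near zero and
  # the V-statistic leakage stays below fidelity
  leak_u <- leakage(es, 1 / 10, "freq", estimator = "bias_corrected_u")
  expect_lt(leak_u, 0.1)
  expect_lt(leakage(es, 1 / 10, "freq"), fidelity(es, 1 / 10, "freq"))
})

test_that("fully leaky sensor: leakage 1, and errors on missing gains", {
  es <- leaky_set(n_per_gain = 6)
  expect_equal(leakage(es, 1 / 2, "time"), 1, tolerance = 1e-10)
  expect_equal(leakage(es, 1 / 2, "freq"), 1, tolerance = 1e-10)
  expect_error(fidelity(es, 0.33, "time"), "no experiments at gain")
  one <- perfect_set(n_per_gain = 1)
  expect_error(fidelity(one, 1 / 10, "time"), ">= 2 experiments")
})

test_that("recordings independent of the phantom give low fidelity at n = 54", {
  # pure-noise recordings across a 6 x 9 x 3 roster (54 experiments/gain)
  roster <- default_roster()
  cfg <- simulator_config(signal_filter = 0, noise_filter = 1,
                          leakage = 1, sensor_noise_sd = 0.01, seed = 6)
  es <- gen_experiment_set(list(sensor_config("TPU", 1, "hole_2mm")),
                           roster, list(cfg), 0.25, 8000, seed = 12)[[1]]
  expect_lt(fidelity(es, 1 / 10, "freq"), 0.3)
  expect_lt(fidelity(es, 1 / 10, "time"), 0.3)
})

test_that("quality score is the x*y rectangle area over gain averages", {
  q <- quality_from_stats(c(0.8, 0.6, 0.4), c(0.2, 0.4, 0.6))
  expect_equal(q$x, 0.6)
  expect_equal(q$y, 0.6)
  expect_equal(q$q, 0.36)
  expect_equal(quality_from_stats(c(1, 1), c(0, 0))$q, 1)
  expect_equal(quality_from_stats(c(0, 0), c(0.3, 0.7))$q, 0)
  es <- perfect_set(n_per_gain = 4)
  qs <- quality_score(es, "freq")
  expect_equal(qs$y, 1, tolerance = 1e-10)
  expect_equal(qs$q, qs$x * qs$y)
  # gain-set completeness is enforced, not imputed
  es2 <- perfect_set(n_per_gain = 4, gains = c(1 / 40, 1 / 10))
  expect_error(quality_score(es2, "freq"), "missing gains.*0\\.5")
})

test_that("Q responds monotonically to fidelity and leakage", {
  base <- quality_from_stats(c(0.5, 0.5, 0.5), c(0.3, 0.3, 0.3))$q
  up_fid <- quality_from_stats(c(0.7, 0.5, 0.5), c(0.3, 0.3, 0.3))$q
  up_leak <- quality_from_stats(c(0.5, 0.5, 0.5), c(0.5, 0.3, 0.3))$q
  expect_gt(up_fid, base)
  expect_lt(up_leak, base)
})

test_that("windowed statistics coincide with broadband on a single full band", {
  es <- make_fixture_set(function(p, s, g, i)
    signal(p$samples + 0.4 * s$samples, p$sample_rate_hz, "recording"),
    n_per_gain = 5)
  full <- list(full = frequency_band(0, 1000))
  w_fid <- windowed_dcor_spectrum(es, 1 / 10, full, "phantom",
                                  f_max_hz = 1000)
  w_leak <- windowed_dcor_spectrum(es, 1 / 10, full, "noise",
                                   f_max_hz = 1000)
  expect_equal(unname(w_fid), fidelity(es, 1 / 10, "freq",
                                       f_max_hz = 1000),
               tolerance = 1e-12)
  expect_equal(unname(w_leak), leakage(es, 1 / 10, "freq",
                                       f_max_hz = 1000),
               tolerance = 1e-12)
})

test_that("band-limited leakage shows up in the right bands", {
  # noise enters the recording only below 500 Hz
  lowpass <- function(v, rate) auscultQC:::fft_bandpass(v, rate, 0, 500)
  es <- make_fixture_set(function(p, s, g, i) {
    signal(p$samples + 2 * lowpass(s$samples, s$sample_rate_hz),
           p$sample_rate_hz, "recording")
  }, n_per_gain = 8)
  bands <- list(low = frequency_band(20, 480),
                high = frequency_band(520, 420))
  curve <- windowed_dcor_spectrum(es, 1 / 2, bands, "noise",
                                  f_max_hz = 1000)
  expect_gt(curve[["low"]], curve[["high"]])
})

test_that("an all-silence noise ensemble hits the zero-variance convention", {
  es <- make_fixture_set(function(p, s, g, i)
    signal(p$samples, p$sample_rate_hz, "recording"),
    n_per_gain = 4, noise_kind = "silence")
  expect_warning(v <- leakage(es, 1 / 10, "freq"), "constant ensemble")
  expect_equal(v, 0)
})

test_that("bark_quality averages per-band rectangle scores", {
  es <- perfect_set(n_per_gain = 4, rate = 8000, dur = 0.25)
  bands <- bark_bands()[1:4]
  bq <- bark_quality(es, bands)
  expect_length(bq$q_per_band, 4)
  expect_equal(unname(bq$q_bark), mean(bq$q_per_band))
  # perfect sensor: per-band fidelity is 1 everywhere
  expect_true(all(abs(bq$fidelity_bands - 1) < 1e-10))
  # arithmetic of the aggregate
  expect_equal(mean(c(rep(0.5, 9), rep(0, 9))), 0.25)
})

test_that("snr_db follows Parseval scaling", {
  s <- normalize_signal(gen_noise_signal("uniform", 0.1, 2000, seed = 4),
                        0.5)
  r_eq <- signal(s$samples, 2000, "recording")
  expect_equal(snr_db(r_eq, s), 0, tolerance = 1e-9)
  expect_equal(snr_db(signal(10 * s$samples, 2000, "recording"), s), 20,
               tolerance = 1e-9)
  expect_equal(snr_db(signal(0.5 * s$samples, 2000, "recording"), s),
               20 * log10(0.5), tolerance = 1e-6)
  set.seed(2)
  for (a in c(0.01, 0.3, 7)) {
    expect_equal(snr_db(signal(a * s$samples, 2000, "recording"), s),
                 20 * log10(a), tolerance = 1e-9)
  }
  silent <- signal(rep(0, length(s$samples)), 2000, "noise")
  expect_error(snr_db(r_eq, silent), "undefined")
})

test_that("quality_report assembles a consistent full report", {
  es <- make_fixture_set(function(p, s, g, i)
    signal(p$samples + 0.2 * s$samples, p$sample_rate_hz, "recording"),
    n_per_gain = 5, rate = 8000, dur = 0.25)
  rp <- quality_report(es)
  expect_s3_class(rp, "quality_report")
  expect_equal(rp$q_freq,
               rp$mean_fidelity * rp$mean_one_minus_leakage,
               tolerance = 1e-12)
  expect_equal(unname(rp$q_bark), mean(rp$q_bark_per_band))
  expect_length(rp$q_bark_per_band, 18)
  expect_length(rp$snr_db_per_experiment, length(es))
  expect_true(all(c(rp$q_freq, rp$q_time, rp$q_bark) >= 0))
  expect_true(all(c(rp$q_freq, rp$q_time, rp$q_bark) <= 1))
  expect_output(print(rp), "q_freq")
})
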