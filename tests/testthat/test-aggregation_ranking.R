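test_that("material_summary aggregates per-gain values by (hole, material)", {
  r1 <- stub_report("TPU", 0.5, "hole_2mm", c(0.4, 0.4, 0.4),
                    c(0.2, 0.2, 0.2))
  r2 <- stub_report("TPU", 1.0, "hole_2mm", c(0.6, 0.6, 0.6),
                    c(0.2, 0.2, 0.2))
  out <- material_summary(list(r1, r2))
  expect_equal(nrow(out), 1)
  expect_equal(out$fidelity_freq_mean, 0.5)
  # sd over the six flattened per-gain values {0.4 x3, 0.6 x3}
  expect_equal(out$fidelity_freq_sd, sd(rep(c(0.4, 0.6), each = 3)),
               tolerance = 1e-12)
  expect_equal(out$q_freq, 0.5 * (1 - 0.2), tolerance = 1e-12)
  expect_error(material_summary(list()), "empty")
})

test_that("material_summary ranks groups and handles ties", {
  a <- stub_report("TPU", 1, "hole_2mm", rep(0.8, 3), rep(0.3, 3))
  b <- stub_report("PLA", 1, "no_hole", rep(0.5, 3), rep(0.14, 3))
  out <- material_summary(list(a, b))
  expect_equal(out$rank_q_freq[out$material == "TPU"], 1)
  expect_equal(out$rank_q_freq[out$material == "PLA"], 2)
  # exact tie: average ranks by default, flagged
  c1 <- stub_report("TPU", 1, "hole_2mm", rep(0.6, 3), rep(0.5, 3))
  c2 <- stub_report("PLA", 1, "hole_2mm", rep(0.6, 3), rep(0.5, 3))
  tied <- material_summary(list(c1, c2))
  expect_equal(sort(tied$rank_q_freq), c(1.5, 1.5))
  expect_true(all(tied$tie))
  lex <- material_summary(list(c1, c2), ties = "lexicographic")
  expect_equal(lex$rank_q_freq[lex$material == "PLA"], 1)
  expect_equal(lex$rank_q_freq[lex$material == "TPU"], 2)
})

test_that("rank_sensors orders by the chosen metric with both rank columns", {
  rs <- list(
    stub_report("TPU", 0.5, "hole_2mm", rep(0.9, 3), rep(0, 3)),
    stub_report("PLA", 1.0, "no_hole", rep(0.5, 3), rep(0, 3)),
    stub_report("PDMS", 1.5, "no_hole", rep(0.1, 3), rep(0, 3)))
  tab <- rank_sensors(rs, "q_freq")
  expect_equal(tab$material, c("TPU", "PLA", "PDMS"))
  expect_equal(tab$rank_q_freq, c(1, 2, 3))
  expect_true(all(c("rank_q_bark", "q_bark") %in% names(tab)))
  expect_error(rank_sensors(rs, "q_peak"), "unknown metric|arg")
  # empty gain subset = full average ("any noise" table)
  expect_equal(rank_sensors(rs, "q_freq", gain_subset = NULL)$q_freq,
               tab$q_freq)
  # a single-gain subset re-averages only that gain
  r_var <- stub_report("TPU", 0.5, "hole_2mm", c(0.9, 0.5, 0.1),
                       c(0, 0, 0))
  one_gain <- rank_sensors(list(r_var), "q_freq",
                           gain_subset = 1 / 40)
  expect_equal(one_gain$q_freq, 0.9)
})

test_that("rank agreement between q_freq and q_time is a Spearman scalar", {
  set.seed(31)
  rs <- lapply(1:6, function(i) {
    fid <- runif(3, 0.2, 0.9)
    stub_report("TPU", i / 2, "hole_2mm", fid, runif(3, 0, 0.5),
                fid_time = fid * 0.7, leak_time = rep(0.3, 3))
  })
  tab <- rank_sensors(rs, "q_freq")
  rho <- cor(tab$q_freq, tab$q_time, method = "spearman")
  expect_true(is.finite(rho))
  expect_gt(rho, 0)   # time scores built as monotone transform
})

test_that("curve fit recovers generating parameters exactly without noise", {
  # generating parameters drawn once (seed 123) and recorded here
  w0_gen <- 4.4378876; w1_gen <- 0.1288305
  x <- seq(0.05, 0.9, length.out = 20)
  y <- 1 - exp(w0_gen * (x - 1) + w1_gen)
  fit <- fit_fidelity_leakage_curve(data.frame(x = x, y = y))
  expect_equal(fit$init, c(1, 2))
  expect_lt(abs(fit$w0 - w0_gen), 1e-4)
  expect_lt(abs(fit$w1 - w1_gen), 1e-4)
  expect_lt(fit$residual_sum, 1e-12)
  expect_equal(predict_fidelity(fit, x), y, tolerance = 1e-6)
  expect_equal(fit$fitted_at_zero, 1 - exp(fit$w1 - fit$w0),
               tolerance = 1e-12)
  expect_error(fit_fidelity_leakage_curve(data.frame(x = 0.5, y = 0.5)),
               "at least 2")
  expect_error(fit_fidelity_leakage_curve(data.frame(x = c(0, 2),
                                                     y = c(0, 1))),
               "\\[0, 1\\]")
})

test_that("curve-fit recovery error shrinks with per-point noise", {
  w0_gen <- 4.4378876; w1_gen <- 0.1288305
  x <- seq(0.05, 0.9, length.out = 20)
  y <- 1 - exp(w0_gen * (x - 1) + w1_gen)
  errs <- vapply(c(0.05, 0.01, 0), function(s) {
    set.seed(7)
    yn <- pmin(1, pmax(0, y + rnorm(20, sd = s)))
    f <- fit_fidelity_leakage_curve(data.frame(x = x, y = yn))
    sqrt((f$w0 - w0_gen)^2 + (f$w1 - w1_gen)^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("pareto_front equals the brute-force domination oracle", {
  pts <- data.frame(x = c(0.1, 0.5, 0.2), y = c(0.9, 0.5, 0.95))
  front <- pareto_front(pts)
  expect_equal(nrow(front), 2)
  expect_true(all(c(0.1, 0.2) %in% front$x))
  single <- pareto_front(data.frame(x = 0.4, y = 0.4))
  expect_equal(nrow(single), 1)
  set.seed(77)
  big <- data.frame(x = runif(50), y = runif(50))
  got <- pareto_front(big)
  want <- pareto_oracle(big)
  key <- function(df) sort(paste(df$x, df$y))
  expect_equal(key(got), key(want))
  # duplicates of a frontier point are both kept (neither dominates)
  dup <- data.frame(x = c(0.1, 0.1, 0.6), y = c(0.9, 0.9, 0.2))
  expect_equal(nrow(pareto_front(dup)), 2)
  expect_equal(key(pareto_front(dup)), key(pareto_oracle(dup)))
})
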