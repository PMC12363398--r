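#' Material-selection summary across thicknesses and gains
#'
#' Groups quality reports by (hole, material) and reports the mean and
#' sample standard deviation of the per-gain, per-thickness fidelity and
#' leakage statistics (frequency and time domains), the quality scores
#' recomputed from the group means, and descending-quality ranks.
#'
#' @param reports List of [quality_report()] objects.
#' @param ties `"average"` (fractional ranks on ties, the default) or
#'   `"lexicographic"` (ties broken by material name and flagged in the
#'   `tie` column).
#' @return A data.frame with one row per (hole, material) group.
#' @export
material_summary <- function(reports, ties = c("average", "lexicographic")) {
  ties <- match.arg(ties)
  if (length(reports) == 0L) {
    stop("material_summary: empty input", call. = FALSE)
  }
  flat <- do.call(rbind, lapply(reports, function(rp) {
    data.frame(hole = rp$sensor$hole, material = rp$sensor$material,
               fid_freq = as.numeric(rp$per_gain_fidelity_freq),
               leak_freq = as.numeric(rp$per_gain_leakage_freq),
               fid_time = as.numeric(rp$per_gain_fidelity_time),
               leak_time = as.numeric(rp$per_gain_leakage_time),
               stringsAsFactors = FALSE)
  }))
  keys <- unique(flat[, c("hole", "material")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    g <- flat[flat$hole == keys$hole[i] & flat$material == keys$material[i], ]
    sdv <- function(v) if (length(v) > 1) stats::sd(v) else NA_real_
    data.frame(
      hole = keys$hole[i], material = keys$material[i],
      n_values = nrow(g),
      fidelity_freq_mean = mean(g$fid_freq),
      fidelity_freq_sd = sdv(g$fid_freq),
      fidelity_time_mean = mean(g$fid_time),
      fidelity_time_sd = sdv(g$fid_time),
      leakage_freq_mean = mean(g$leak_freq),
      leakage_freq_sd = sdv(g$leak_freq),
      leakage_time_mean = mean(g$leak_time),
      leakage_time_sd = sdv(g$leak_time),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_freq <- out$fidelity_freq_mean * (1 - out$leakage_freq_mean)
  out$q_time <- out$fidelity_time_mean * (1 - out$leakage_time_mean)
  out$rank_q_freq <- rank_desc(out$q_freq, out$material, ties)
  out$rank_q_time <- rank_desc(out$q_time, out$material, ties)
  out$tie <- duplicated(out$q_freq) | duplicated(out$q_freq, fromLast = TRUE)
  out[order(out$rank_q_freq), , drop = FALSE]
}

# Descending ranks; ties either fractional (average) or broken
# lexicographically by the supplied key.
rank_desc <- function(q, key, ties = c("average", "lexicographic")) {
  ties <- match.arg(ties)
  if (ties == "average") {
    rank(-q, ties.method = "average")
  } else {
    ord <- order(-q, as.character(key))
    rk <- integer(length(q))
    rk[ord] <- seq_along(q)
    rk
  }
}

report_q_on_gains <- function(rp, metric, gain_subset = NULL) {
  pick <- function(v) {
    if (is.null(gain_subset) || length(gain_subset) == 0L) return(v)
    idx <- vapply(gain_subset, function(g)
      which(abs(rp$gains - g) <= 1e-12)[1], integer(1))
    if (anyNA(idx)) {
      stop("rank_sensors: gain_subset contains gains absent from a report",
           call. = FALSE)
    }
    v[idx]
  }
  if (metric == "q_freq") {
    quality_from_stats(pick(rp$per_gain_fidelity_freq),
                       pick(rp$per_gain_leakage_freq))$q
  } else if (metric == "q_time") {
    quality_from_stats(pick(rp$per_gain_fidelity_time),
                       pick(rp$per_gain_leakage_time))$q
  } else {  # q_bark
    if (is.null(rp$bark_fidelity)) return(NA_real_)
    fid <- rp$bark_fidelity
    leak <- rp$bark_leakage
    if (!is.null(gain_subset) && length(gain_subset) > 0L) {
      idx <- vapply(gain_subset, function(g)
        which(abs(rp$gains - g) <= 1e-12)[1], integer(1))
      fid <- fid[, idx, drop = FALSE]
      leak <- leak[, idx, drop = FALSE]
    }
    mean(rowMeans(fid) * rowMeans(1 - leak))
  }
}

#' Rank sensors by a quality metric
#'
#' Sorts sensors by broadband (`q_freq`, `q_time`) or Bark-band windowed
#' (`q_bark`) quality, optionally restricted to a subset of ambient
#' gains. An empty `gain_subset` uses the full gain average (the "any
#' noise" ranking). Both `q_bark` and `q_freq` ranks are reported so
#' their agreement can be inspected.
#'
#' @param reports List of [quality_report()]s.
#' @param metric Sort key: `"q_freq"`, `"q_bark"` or `"q_time"`.
#' @param gain_subset Optional numeric vector of gains to average over.
#' @return data.frame sorted by `metric` descending with columns
#'   `material`, `thickness_mm`, `hole`, `q_bark`, `q_freq`, `q_time`,
#'   `rank_q_bark`, `rank_q_freq`.
#' @export
rank_sensors <- function(reports, metric = c("q_freq", "q_bark", "q_time"),
                         gain_subset = NULL) {
  if (length(reports) == 0L) stop("rank_sensors: empty input", call. = FALSE)
  if (is.character(metric) && length(metric) == 1L &&
      !metric %in% c("q_freq", "q_bark", "q_time")) {
    stop(sprintf("rank_sensors: unknown metric '%s'", metric), call. = FALSE)
  }
  metric <- match.arg(metric)
  if (metric == "q_bark" &&
      any(vapply(reports, function(rp) is.null(rp$bark_fidelity),
                 logical(1)))) {
    stop("rank_sensors: reports lack Bark-band curves for q_bark",
         call. = FALSE)
  }
  tab <- do.call(rbind, lapply(reports, function(rp) {
    data.frame(
      material = rp$sensor$material,
      thickness_mm = rp$sensor$thickness_mm,
      hole = rp$sensor$hole,
      q_bark = report_q_on_gains(rp, "q_bark", gain_subset),
      q_freq = report_q_on_gains(rp, "q_freq", gain_subset),
      q_time = report_q_on_gains(rp, "q_time", gain_subset),
      stringsAsFactors = FALSE)
  }))
  tab$rank_q_bark <- rank(-tab$q_bark, ties.method = "average")
  tab$rank_q_freq <- rank(-tab$q_freq, ties.method = "average")
  tab <- tab[order(-tab[[metric]]), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Fit the exponential fidelity-leakage curve
#'
#' Sensors plotted as (leakage x, fidelity y) points fall along an
#' exponential frontier modeled as `f(x) = 1 - exp(w0 * (x - 1) + w1)`.
#' The fit minimizes the least-squares objective
#' `sum |(1 - exp(w0 (x - 1) + w1)) - y|^2` by Levenberg-Marquardt from
#' the given initialization (default `(1, 2)`), with a 1e-10 tolerance on
#' the parameter step.
#'
#' @param points data.frame or matrix with columns `x` (leakage) and `y`
#'   (fidelity), both in \[0, 1\]; at least 2 points.
#' @param init Length-2 numeric start `(w0, w1)`.
#' @param max_iter Iteration cap before a non-convergence error.
#' @return List of class `curve_fit_result`: `w0`, `w1`, `residual_sum`,
#'   `init`, `iterations`, `fitted_at_zero` (= `f(0) = 1 - exp(w1 - w0)`,
#'   the curve's modeled fidelity at zero leakage).
#' @export
fit_fidelity_leakage_curve <- function(points, init = c(1, 2),
                                       max_iter = 500L) {
  pts <- as.data.frame(points)
  if (!all(c("x", "y") %in% names(pts))) {
    if (ncol(pts) >= 2) names(pts)[1:2] <- c("x", "y")
    else stop("fit_fidelity_leakage_curve: need columns x and y",
              call. = FALSE)
  }
  x <- as.numeric(pts$x); y <- as.numeric(pts$y)
  if (length(x) < 2L) {
    stop("fit_fidelity_leakage_curve: need at least 2 points",
         call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y)) ||
      any(x < 0 | x > 1) || any(y < 0 | y > 1)) {
    stop("fit_fidelity_leakage_curve: x and y must be finite and in [0, 1]",
         call. = FALSE)
  }
  if (length(init) != 2L || any(!is.finite(init))) {
    stop("fit_fidelity_leakage_curve: 'init' must be two finite numbers",
         call. = FALSE)
  }
  resid_fun <- function(w) y - (1 - exp(w[1] * (x - 1) + w[2]))
  jac_fun <- function(w) {
    e <- exp(w[1] * (x - 1) + w[2])
    cbind(e * (x - 1), e)  # d resid / d w
  }
  w <- as.numeric(init)
  lambda <- 1e-3
  r <- resid_fun(w)
  sse <- sum(r^2)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- jac_fun(w)
    g <- crossprod(J, r)
    H <- crossprod(J)
    step <- tryCatch(
      solve(H + lambda * diag(diag(H) + 1e-12, 2), g),
      error = function(e) NULL)
    if (is.null(step)) { lambda <- lambda * 10; next }
    w_new <- w - as.numeric(step)
    r_new <- resid_fun(w_new)
    sse_new <- sum(r_new^2)
    if (is.finite(sse_new) && sse_new <= sse) {
      moved <- sqrt(sum((w_new - w)^2))
      w <- w_new; r <- r_new; sse <- sse_new
      lambda <- max(lambda / 10, 1e-12)
      if (moved < 1e-10) { converged <- TRUE; break }
    } else {
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
  }
  if (!converged && sse > 1e-20) {
    # accept gradient-flat optima even if the last step was not tiny
    if (sqrt(sum(crossprod(jac_fun(w), resid_fun(w))^2)) > 1e-8) {
      stop(sprintf(
        "fit_fidelity_leakage_curve: no convergence after %d iterations (sse=%.3g, lambda=%.3g)",
        iter, sse, lambda), call. = FALSE)
    }
  }
  structure(list(w0 = w[1], w1 = w[2], residual_sum = sse,
                 init = as.numeric(init), iterations = iter,
                 fitted_at_zero = 1 - exp(w[2] - w[1])),
            class = "curve_fit_result")
}

#' @export
print.curve_fit_result <- function(x, ...) {
  cat(sprintf(
    "<curve_fit f(x) = 1 - exp(%.4g (x - 1) + %.4g); SSE = %.4g; f(0) = %.4g>\n",
    x$w0, x$w1, x$residual_sum, x$fitted_at_zero))
  invisible(x)
}

#' Evaluate the fitted fidelity-leakage curve
#' @param fit A `curve_fit_result`.
#' @param x Leakage values.
#' @return Modeled fidelity `1 - exp(w0 (x - 1) + w1)`.
#' @export
predict_fidelity <- function(fit, x) {
  1 - exp(fit$w0 * (x - 1) + fit$w1)
}

#' Pareto front of (leakage, fidelity) points
#'
#' A sensor is on the front if no other sensor has lower-or-equal leakage
#' and higher-or-equal fidelity with at least one strict. Implemented as
#' a sort-and-sweep (sort by leakage ascending, fidelity descending,
#' keep points exceeding the running fidelity maximum).
#'
#' @param points data.frame/matrix with columns `x` (leakage) and `y`
#'   (fidelity).
#' @return The non-dominated subset, rows in increasing leakage order.
#' @export
pareto_front <- function(points) {
  pts <- as.data.frame(points)
  if (!all(c("x", "y") %in% names(pts)) && ncol(pts) >= 2) {
    names(pts)[1:2] <- c("x", "y")
  }
  if (nrow(pts) == 0L) return(pts)
  ord <- order(pts$x, -pts$y)
  sorted <- pts[ord, , drop = FALSE]
  best_y <- -Inf
  best_x <- NA_real_
  keep <- logical(nrow(sorted))
  for (i in seq_len(nrow(sorted))) {
    yi <- sorted$y[i]; xi <- sorted$x[i]
    if (yi > best_y || (yi == best_y && xi == best_x)) {
      keep[i] <- TRUE
      if (yi > best_y) { best_y <- yi; best_x <- xi }
    }
  }
  out <- sorted[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
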