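#' @title WAV and tabular input/output
#' @description
#' Minimal RIFF/WAVE reader and writer (PCM 16/24-bit and IEEE float32;
#' float32 is the default interchange encoding so round trips are exact),
#' roster CSV loading into experiment sets, and JSON/CSV serialization of
#' quality reports. No WAV-capable R package is available in the target
#' environment, so the codec is implemented here.
#' @name wav-io
NULL

#' Write a signal to a WAV file
#'
#' @param x An [signal()] object (mono).
#' @param path Output path.
#' @param encoding `"float32"` (default; lossless for doubles truncated
#'   to single precision), `"pcm16"` or `"pcm24"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, encoding = c("float32", "pcm16", "pcm24")) {
  stopifnot_signal(x)
  encoding <- match.arg(encoding)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x$samples)
  rate <- as.integer(round(x$sample_rate_hz))
  bits <- switch(encoding, float32 = 32L, pcm16 = 16L, pcm24 = 24L)
  fmt_code <- if (encoding == "float32") 3L else 1L
  block <- bits %/% 8L
  data_size <- n * block
  has_fact <- encoding == "float32"
  riff_size <- 4L + (8L + 16L) + (if (has_fact) 12L else 0L) +
    (8L + data_size)
  w_u32 <- function(v) writeBin(as.integer(v), con, size = 4,
                                endian = "little")
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2,
                                endian = "little")
  writeChar("RIFF", con, eos = NULL); w_u32(riff_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_u32(16L)
  w_u16(fmt_code); w_u16(1L)          # mono
  w_u32(rate); w_u32(rate * block)    # byte rate
  w_u16(block); w_u16(bits)
  if (has_fact) {
    writeChar("fact", con, eos = NULL); w_u32(4L); w_u32(n)
  }
  writeChar("data", con, eos = NULL); w_u32(data_size)
  if (encoding == "float32") {
    writeBin(x$samples, con, size = 4, endian = "little")
  } else {
    full <- if (encoding == "pcm16") 32768 else 8388608
    q <- as.integer(pmin(full - 1,
                         round(pmax(-1, pmin(1, x$samples)) * full)))
    if (encoding == "pcm16") {
      writeBin(q, con, size = 2, endian = "little")
    } else {
      b <- integer(3L * n)
      u <- ifelse(q < 0, q + 16777216L, q)  # two's complement, 24 bit
      writeBin(as.raw(c(rbind(u %% 256L, (u %/% 256L) %% 256L,
                              (u %/% 65536L) %% 256L))), con)
    }
  }
  invisible(path)
}

#' Read a WAV file into a signal
#'
#' Supports mono/multichannel PCM 16/24-bit and IEEE float32; multichannel
#' input is averaged to mono.
#'
#' @param path Input path.
#' @param role Role to assign to the loaded [signal()].
#' @return A [signal()].
#' @export
read_wav <- function(path, role = c("recording", "phantom", "noise")) {
  role <- match.arg(role)
  if (!file.exists(path)) {
    stop(sprintf("read_wav: missing file '%s'", path), call. = FALSE)
  }
  raw <- readBin(path, "raw", n = file.info(path)$size)
  fail <- function(why) stop(sprintf("read_wav: corrupt WAV '%s' (%s)",
                                     path, why), call. = FALSE)
  if (length(raw) < 44L) fail("too short")
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * 256^(0:1))
  tag <- function(off) rawToChar(raw[off + 1:4])
  if (tag(0) != "RIFF" || tag(8) != "WAVE") fail("not RIFF/WAVE")
  pos <- 12L
  fmt <- NULL; data_off <- NA_integer_; data_len <- NA_integer_
  while (pos + 8L <= length(raw)) {
    id <- tag(pos); sz <- u32(pos + 4L)
    body <- pos + 8L
    if (id == "fmt ") {
      if (sz < 16L) fail("short fmt chunk")
      fmt <- list(code = u16(body), channels = u16(body + 2L),
                  rate = u32(body + 4L), bits = u16(body + 14L))
    } else if (id == "data") {
      data_off <- body; data_len <- sz
    }
    pos <- body + sz + (sz %% 2L)  # chunks are word-aligned
  }
  if (is.null(fmt) || is.na(data_off)) fail("missing fmt or data chunk")
  if (data_off + data_len > length(raw)) fail("truncated data chunk")
  block <- fmt$bits %/% 8L
  n_total <- data_len %/% (block * fmt$channels)
  if (n_total < 1L) fail("empty data chunk")
  bytes <- raw[data_off + seq_len(n_total * fmt$channels * block)]
  vals <-
    if (fmt$code == 3L && fmt$bits == 32L) {
      readBin(bytes, "double", n = n_total * fmt$channels, size = 4,
              endian = "little")
    } else if (fmt$code == 1L && fmt$bits == 16L) {
      readBin(bytes, "integer", n = n_total * fmt$channels, size = 2,
              signed = TRUE, endian = "little") / 32768
    } else if (fmt$code == 1L && fmt$bits == 24L) {
      m <- matrix(as.integer(bytes), nrow = 3L)
      u <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
      ifelse(u >= 8388608, u - 16777216, u) / 8388608
    } else {
      fail(sprintf("unsupported format code %d / %d bits",
                   fmt$code, fmt$bits))
    }
  if (fmt$channels > 1L) {
    vals <- rowMeans(matrix(vals, ncol = fmt$channels, byrow = TRUE))
  }
  signal(vals, fmt$rate, role)
}

roster_csv_columns <- c("sensor_material", "thickness_mm", "hole",
                        "phantom_id", "noise_id", "gain",
                        "p_wav", "s_wav", "r_wav")

#' Write experiment sets as a WAV tree plus roster CSV
#'
#' Shared normalized phantom and noise signals go under `shared/`, one
#' recording per experiment under a per-sensor directory, and a roster
#' CSV at `dir/roster.csv` references every file with paths relative to
#' `dir`, readable back with [load_experiment_set()].
#'
#' @param sets List of [experiment_set()]s.
#' @param dir Output directory (created if needed).
#' @param encoding WAV encoding (default float32, lossless round trip).
#' @return Path of the roster CSV, invisibly.
#' @export
write_experiment_tree <- function(sets, dir,
                                  encoding = c("float32", "pcm16",
                                               "pcm24")) {
  encoding <- match.arg(encoding)
  dir.create(file.path(dir, "shared"), recursive = TRUE,
             showWarnings = FALSE)
  written <- character(0)
  rows <- list()
  for (es in sets) {
    slab <- sensor_label(es$sensor)
    dir.create(file.path(dir, slab), showWarnings = FALSE)
    for (i in seq_along(es$experiments)) {
      e <- es$experiments[[i]]
      p_rel <- file.path("shared", sprintf("p_%s.wav", e$phantom_id))
      s_rel <- file.path("shared", sprintf("s_%s_g%s.wav", e$noise_id,
                                           gsub("[^0-9a-zA-Z.]", "_",
                                                format(e$noise_gain))))
      r_rel <- file.path(slab, sprintf("r_%04d.wav", i))
      for (pair in list(list(p_rel, e$p_norm), list(s_rel, e$s_norm),
                        list(r_rel, e$r))) {
        if (!(pair[[1]] %in% written)) {
          write_wav(pair[[2]], file.path(dir, pair[[1]]), encoding)
          written <- c(written, pair[[1]])
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sensor_material = es$sensor$material,
        thickness_mm = es$sensor$thickness_mm,
        hole = es$sensor$hole,
        phantom_id = e$phantom_id, noise_id = e$noise_id,
        gain = e$noise_gain, p_wav = p_rel, s_wav = s_rel, r_wav = r_rel,
        stringsAsFactors = FALSE)
    }
  }
  roster <- do.call(rbind, rows)
  path <- file.path(dir, "roster.csv")
  utils::write.csv(roster, path, row.names = FALSE)
  invisible(path)
}

#' Load experiment sets from a roster CSV and WAV tree
#'
#' Reads each roster row's three WAV files, validates that all signals in
#' the tree share one sample rate and one length (no silent resampling),
#' and groups the experiments by sensor.
#'
#' @param roster_csv Path to a roster CSV with columns
#'   `sensor_material, thickness_mm, hole, phantom_id, noise_id, gain,
#'   p_wav, s_wav, r_wav`.
#' @param wav_root Root directory the WAV paths are relative to
#'   (default: the roster's directory).
#' @return List of [experiment_set()]s.
#' @export
load_experiment_set <- function(roster_csv, wav_root = dirname(roster_csv)) {
  if (!file.exists(roster_csv)) {
    stop(sprintf("load_experiment_set: missing roster '%s'", roster_csv),
         call. = FALSE)
  }
  roster <- utils::read.csv(roster_csv, stringsAsFactors = FALSE)
  missing_cols <- setdiff(roster_csv_columns, names(roster))
  if (length(missing_cols) > 0L) {
    stop(sprintf("load_experiment_set: roster schema error, missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  cache <- new.env(parent = emptyenv())
  get_sig <- function(rel, role) {
    key <- paste0(role, "|", rel)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- file.path(wav_root, rel)
    if (!file.exists(p)) {
      stop(sprintf("load_experiment_set: missing WAV file '%s'", p),
           call. = FALSE)
    }
    sig <- read_wav(p, role)
    cache[[key]] <- sig
    sig
  }
  triplets <- lapply(seq_len(nrow(roster)), function(i) {
    row <- roster[i, ]
    sensor <- sensor_config(row$sensor_material, row$thickness_mm,
                            row$hole)
    p <- get_sig(row$p_wav, "phantom")
    s <- get_sig(row$s_wav, "noise")
    r <- get_sig(row$r_wav, "recording")
    rates <- c(p$sample_rate_hz, s$sample_rate_hz, r$sample_rate_hz)
    if (length(unique(rates)) != 1L) {
      stop(sprintf(
        "load_experiment_set: sample-rate mismatch in roster row %d (%s); resampling is not performed",
        i, paste(rates, collapse = "/")), call. = FALSE)
    }
    lens <- c(length(p$samples), length(s$samples), length(r$samples))
    if (length(unique(lens)) != 1L) {
      stop(sprintf(
        "load_experiment_set: length mismatch in roster row %d (%s)",
        i, paste(lens, collapse = "/")), call. = FALSE)
    }
    experiment_triplet(sensor, row$phantom_id, row$noise_id, row$gain,
                       p, s, r)
  })
  labels <- vapply(triplets, function(tr) sensor_label(tr$sensor),
                   character(1))
  lapply(unique(labels), function(lab) {
    sel <- triplets[labels == lab]
    experiment_set(sel[[1]]$sensor, sel)
  })
}

report_meta <- function(seed = NULL) {
  list(package = "auscultQC",
       version = as.character(utils::packageVersion("auscultQC")),
       r_version = as.character(getRversion()),
       seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Serialize quality reports to JSON
#'
#' @param reports A [quality_report()] or list of them.
#' @param path Output JSON path.
#' @param seed Optional seed recorded in the metadata block for
#'   reproducibility.
#' @return `path`, invisibly.
#' @export
reports_to_json <- function(reports, path, seed = NULL) {
  if (inherits(reports, "quality_report")) reports <- list(reports)
  payload <- list(
    meta = report_meta(seed),
    reports = lapply(reports, function(rp) {
      list(sensor = unclass(rp$sensor),
           gains = rp$gains,
           per_gain_fidelity_time = as.list(rp$per_gain_fidelity_time),
           per_gain_leakage_time = as.list(rp$per_gain_leakage_time),
           per_gain_fidelity_freq = as.list(rp$per_gain_fidelity_freq),
           per_gain_leakage_freq = as.list(rp$per_gain_leakage_freq),
           mean_fidelity = rp$mean_fidelity,
           mean_one_minus_leakage = rp$mean_one_minus_leakage,
           q_time = rp$q_time, q_freq = rp$q_freq, q_bark = rp$q_bark,
           q_bark_per_band = as.list(rp$q_bark_per_band),
           snr_db_per_experiment = as.list(rp$snr_db_per_experiment))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Flatten quality reports to a one-row-per-sensor CSV
#'
#' @param reports List of [quality_report()]s.
#' @param path Output CSV path.
#' @return The data.frame written, invisibly.
#' @export
reports_to_csv <- function(reports, path) {
  if (inherits(reports, "quality_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(rp) {
    row <- data.frame(material = rp$sensor$material,
                      thickness_mm = rp$sensor$thickness_mm,
                      hole = rp$sensor$hole,
                      q_freq = rp$q_freq, q_time = rp$q_time,
                      q_bark = rp$q_bark,
                      mean_fidelity = rp$mean_fidelity,
                      mean_one_minus_leakage = rp$mean_one_minus_leakage,
                      stringsAsFactors = FALSE)
    for (g in names(rp$per_gain_fidelity_freq)) {
      row[[paste0("fidelity_freq_g", g)]] <- rp$per_gain_fidelity_freq[[g]]
      row[[paste0("leakage_freq_g", g)]] <- rp$per_gain_leakage_freq[[g]]
    }
    row
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Long-format per-band curve CSV (fidelity/leakage vs band start)
#'
#' One row per (sensor, gain, band): band start frequency, windowed
#' fidelity, windowed leakage — the plot-ready data behind a windowed
#' distance-correlation spectrum figure.
#'
#' @param reports List of [quality_report()]s with Bark curves.
#' @param path Output CSV path.
#' @return The data.frame written, invisibly.
#' @export
band_curves_to_csv <- function(reports, path) {
  if (inherits(reports, "quality_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(rp) {
    if (is.null(rp$bark_fidelity)) return(NULL)
    gains <- colnames(rp$bark_fidelity)
    do.call(rbind, lapply(gains, function(g) {
      data.frame(material = rp$sensor$material,
                 thickness_mm = rp$sensor$thickness_mm,
                 hole = rp$sensor$hole, gain = as.numeric(g),
                 band_start_hz = as.numeric(rownames(rp$bark_fidelity)),
                 fidelity = rp$bark_fidelity[, g],
                 leakage = rp$bark_leakage[, g],
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Load a run configuration from JSON
#'
#' Fields (all optional unless noted): `roster` (path, required for
#' evaluation runs), `wav_root`, `gains`, `f_max_hz`, `bands` (`"bark"`,
#' `"single"`, or a CSV path with `start_hz,bandwidth_hz` columns),
#' `estimator`, `output_dir`, `seed`, `log_level`.
#'
#' @param path JSON file.
#' @return A validated list of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("load_run_config: missing config '%s'", path),
         call. = FALSE)
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(gains = default_gains(), f_max_hz = 4000,
                   bands = "bark", estimator = "biased_v",
                   output_dir = ".", seed = 1L, log_level = "info")
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (!is.null(cfg$roster) && !file.exists(cfg$roster)) {
    stop(sprintf("load_run_config: roster path '%s' does not exist",
                 cfg$roster), call. = FALSE)
  }
  if (length(cfg$gains) == 0L) {
    stop("load_run_config: gain set must be non-empty", call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

resolve_bands <- function(spec, f_max_hz = 4000) {
  if (is.character(spec) && spec == "bark") return(bark_bands())
  if (is.character(spec) && spec == "single") {
    return(list(full = frequency_band(0, f_max_hz)))
  }
  if (is.character(spec) && file.exists(spec)) {
    df <- utils::read.csv(spec)
    bands <- Map(frequency_band, df$start_hz, df$bandwidth_hz)
    names(bands) <- as.character(df$start_hz)
    return(bands)
  }
  stop(sprintf("unknown band scheme '%s'", spec), call. = FALSE)
}
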