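#' Sliding RMS envelope
#'
#' Centred sliding root-mean-square of a signal — the smooth, non-negative
#' amplitude trace (TOCO-like curve) from which contractions are recognised.
#' Edges are reflection-padded, so the output has the same length as the
#' input. Computed with cumulative sums in O(n).
#'
#' @param x Numeric signal (e.g. the ZCR-modulated EHG).
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (default 10 s, i.e. N = 2500
#'   samples at 250 Hz).
#' @return Non-negative numeric vector, same length as `x`.
#' @export
rms_envelope <- function(x, fs, window_s = 10) {
  validate_signal(x, fs)
  n_w <- round(window_s * fs)
  if (n_w < 1) stop("RMS window must span at least 1 sample", call. = FALSE)
  if (length(x) < n_w)
    stop("signal (", length(x), " samples) shorter than the RMS window (",
         n_w, " samples)", call. = FALSE)
  sqrt(pmax(running_mean(x^2, n_w), 0))
}

# Centred running mean over n_w samples with reflection padding, O(n).
running_mean <- function(x, n_w) {
  if (n_w == 1) return(x)
  off <- window_offsets(n_w)
  padded <- reflect_pad(x, off$left, off$right)
  cs <- cumsum(c(0, padded))
  n <- length(x)
  (cs[seq_len(n) + n_w] - cs[seq_len(n)]) / n_w
}

#' Smooth a TOCO trace by moving average
#'
#' Centred moving average with reflection padding (length-preserving); 40 s
#' of averaging flattens transducer noise while keeping the slow contraction
#' bumps.
#'
#' @param x Raw TOCO signal.
#' @param fs Sampling rate in Hz.
#' @param window_s Averaging window in seconds.
#' @return Smoothed numeric vector, same length as `x`.
#' @export
smooth_toco <- function(x, fs, window_s = 40) {
  validate_signal(x, fs)
  n_w <- round(window_s * fs)
  if (n_w < 1) stop("smoothing window must span at least 1 sample",
                    call. = FALSE)
  if (length(x) < n_w)
    stop("signal (", length(x), " samples) shorter than the smoothing ",
         "window (", n_w, " samples)", call. = FALSE)
  running_mean(x, n_w)
}

#' Half-wave width of an envelope peak
#'
#' Duration of a contraction, defined as the width of the envelope at half
#' the peak amplitude: walk outward from the peak to the first sample below
#' half-maximum on each side, locate the crossing by linear interpolation
#' between the bracketing samples, and clip to the candidate region. A
#' degenerate flat region returns the region width.
#'
#' @param envelope Numeric envelope.
#' @param fs Sampling rate in Hz.
#' @param peak_index Index (1-based) of the peak inside the region.
#' @param region Integer vector `c(start, end)` of the candidate region
#'   (1-based, inclusive).
#' @return Width in seconds.
#' @export
half_wave_width <- function(envelope, fs, peak_index, region) {
  validate_signal(envelope, fs)
  stopifnot(length(region) == 2, region[1] <= peak_index,
            peak_index <= region[2], region[1] >= 1,
            region[2] <= length(envelope))
  half <- envelope[peak_index] / 2

  # left crossing: time (in samples, 0-based) where envelope drops below half
  left <- region[1]
  i <- peak_index
  while (i > region[1] && envelope[i - 1] >= half) i <- i - 1
  t_left <- if (i == region[1] || envelope[i - 1] >= half) {
    region[1] - 1
  } else {
    # interpolate between samples i-1 (below) and i (at/above)
    y0 <- envelope[i - 1]; y1 <- envelope[i]
    (i - 1) - 1 + (half - y0) / (y1 - y0)
  }

  i <- peak_index
  while (i < region[2] && envelope[i + 1] >= half) i <- i + 1
  t_right <- if (i == region[2] || envelope[i + 1] >= half) {
    region[2] - 1
  } else {
    y0 <- envelope[i]; y1 <- envelope[i + 1]
    (i - 1) + (half - y0) / (y1 - y0)
  }

  (t_right - t_left) / fs
}

#' Detect contractions in an envelope by amplitude and duration thresholds
#'
#' A contraction is a maximal run of samples where the envelope strictly
#' exceeds the amplitude threshold Tha (the mean of the envelope by default)
#' and whose run length strictly exceeds the duration threshold Thd
#' (default 30 s). For each accepted run the peak is the earliest maximum,
#' and the reported duration is the half-wave width of the envelope around
#' that peak. Runs separated by a dip shorter than `merge_gap_s` can
#' optionally be merged first.
#'
#' @param envelope Non-negative numeric envelope.
#' @param fs Sampling rate in Hz.
#' @param config A [detection_config()].
#' @param source Label stored in the `source` column (`"EHG"` or `"TOCO"`).
#' @return A tibble of events ordered by time, with columns `source`,
#'   `onset_s`, `peak_s`, `end_s`, `peak_amplitude`, `duration_s`. Zero rows
#'   when nothing qualifies.
#' @export
detect_ucs <- function(envelope, fs, config = detection_config(),
                       source = "EHG") {
  stopifnot(inherits(config, "detection_config"))
  validate_signal(envelope, fs)
  tha <- if (config$tha_mode == "mean") mean(envelope) else config$tha_value

  above <- envelope > tha
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values
  regions <- cbind(starts[keep], ends[keep])

  if (nrow(regions) > 1 && config$merge_gap_s > 0) {
    gap_max <- config$merge_gap_s * fs
    merged <- regions[1, , drop = FALSE]
    for (r in 2:nrow(regions)) {
      if (regions[r, 1] - merged[nrow(merged), 2] - 1 <= gap_max) {
        merged[nrow(merged), 2] <- regions[r, 2]
      } else {
        merged <- rbind(merged, regions[r, ])
      }
    }
    regions <- merged
  }

  empty <- tibble::tibble(source = character(0), onset_s = numeric(0),
                          peak_s = numeric(0), end_s = numeric(0),
                          peak_amplitude = numeric(0), duration_s = numeric(0))
  if (nrow(regions) == 0) return(empty)

  # duration gate: strictly longer than thd_s, measured on the run itself
  run_s <- (regions[, 2] - regions[, 1]) / fs
  regions <- regions[run_s > config$thd_s, , drop = FALSE]
  if (nrow(regions) == 0) return(empty)

  rows <- lapply(seq_len(nrow(regions)), function(r) {
    a <- regions[r, 1]; b <- regions[r, 2]
    peak <- a + which.max(envelope[a:b]) - 1  # which.max: earliest on ties
    tibble::tibble(
      source = source,
      onset_s = (a - 1) / fs,
      peak_s = (peak - 1) / fs,
      end_s = (b - 1) / fs,
      peak_amplitude = envelope[peak],
      duration_s = half_wave_width(envelope, fs, peak, c(a, b))
    )
  })
  dplyr::bind_rows(rows)
}

#' Detect uterine contractions in a multichannel recording
#'
#' Runs the full recognition workflow on both measurement paths. The EHG
#' path averages the EHG channels, low-pass and median filters them,
#' applies the ZCR modulation, extracts the RMS envelope, and thresholds it;
#' the TOCO path smooths the TOCO channel with a moving average and applies
#' the same amplitude-plus-duration rule.
#'
#' @param rec A recording tibble with EHG channels and (optionally) a channel
#'   labelled `toco`.
#' @param config A [uc_config()] bundling the stage configurations.
#' @param keep_signals Keep the intermediate envelopes in the result (needed
#'   for plotting; default `TRUE`).
#' @return An object of class `uc_detection`: a list with `events` (tibble of
#'   EHG and TOCO events), `envelopes` (tibble of `time_s`, `ehg_envelope`,
#'   `toco_envelope` when `keep_signals`), `fs`, `duration_s`, and `config`.
#'   Use [tidy()][generics::tidy] to pull the event table and
#'   [autoplot()][ggplot2::autoplot] to visualise.
#' @export
detect_contractions <- function(rec, config = uc_config(),
                                keep_signals = TRUE) {
  stopifnot(inherits(config, "uc_config"))
  fs <- recording_fs(rec)

  pre <- preprocess(rec, config$preprocess)
  modulated <- zcr_modulate(pre$ehg, fs, config$zcr)
  ehg_env <- rms_envelope(modulated, fs, config$detection$rms_window_s)
  ehg_events <- detect_ucs(ehg_env, fs, config$detection, source = "EHG")

  toco <- toco_label(rec)
  if (!is.null(toco)) {
    toco_env <- smooth_toco(channel_vector(rec, toco), fs,
                            config$detection$toco_smooth_s)
    toco_events <- detect_ucs(toco_env, fs, config$detection, source = "TOCO")
  } else {
    toco_env <- NULL
    toco_events <- tibble::tibble(
      source = character(0), onset_s = numeric(0), peak_s = numeric(0),
      end_s = numeric(0), peak_amplitude = numeric(0), duration_s = numeric(0))
  }

  envelopes <- if (keep_signals) {
    env_tbl <- tibble::tibble(time_s = rec$time_s, ehg_envelope = ehg_env)
    if (!is.null(toco_env)) env_tbl$toco_envelope <- toco_env
    env_tbl
  } else {
    NULL
  }

  structure(
    list(events = dplyr::bind_rows(ehg_events, toco_events),
         envelopes = envelopes, fs = fs,
         duration_s = recording_duration_s(rec), config = config),
    class = "uc_detection"
  )
}

#' @export
print.uc_detection <- function(x, ...) {
  n_ehg <- sum(x$events$source == "EHG")
  n_toco <- sum(x$events$source == "TOCO")
  cat("<uc_detection> ", format(x$duration_s / 60, digits = 3),
      " min recording at ", x$fs, " Hz\n", sep = "")
  cat("  EHG events:  ", n_ehg, "\n", sep = "")
  cat("  TOCO events: ", n_toco, "\n", sep = "")
  invisible(x)
}
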