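# Reflection padding without repeating the edge sample; pad lengths must be
# < length(x). Used by every sliding-window stage so that outputs stay
# length-preserving with centred alignment.
reflect_pad <- function(x, left, right = left) {
  n <- length(x)
  if (left >= n || right >= n)
    stop("signal too short for the requested window", call. = FALSE)
  c(if (left > 0) x[(left + 1):2] else numeric(0),
    x,
    if (right > 0) x[(n - 1):(n - right)] else numeric(0))
}

# Centred window offsets for a window of w samples.
window_offsets <- function(w) {
  off_l <- floor((w - 1) / 2)
  list(left = off_l, right = w - 1 - off_l)
}

#' Average a subset of channels into one signal
#'
#' Pointwise arithmetic mean of the selected channels — the first
#' preprocessing stage, which reinforces the uterine activity common to all
#' abdominal electrodes while averaging down uncorrelated noise.
#'
#' @param rec A recording tibble (see [as_recording()]).
#' @param channels Channel labels to average; default all EHG channels
#'   (every channel except TOCO).
#' @return Numeric vector of the averaged signal (same length as the
#'   recording).
#' @export
average_channels <- function(rec, channels = NULL) {
  if (is.null(channels)) channels <- ehg_labels(rec)
  if (length(channels) == 0)
    stop("no channels to average", call. = FALSE)
  missing <- setdiff(channels, channel_labels(rec))
  if (length(missing) > 0)
    stop("unknown channel label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rowMeans(as.matrix(rec[channels]))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth low-pass, so the effective
#' attenuation is twice `order` and event timing is not shifted — the peak
#' positions feed a 20 s matching rule downstream, so phase distortion would
#' bias the evaluation. Edges are handled by reflection extension with
#' constant-history initial conditions on each pass: DC levels pass through
#' exactly and start-up transients settle inside the discarded extension.
#' As with any zero-phase filter on a finite signal, samples within roughly
#' one settling length (`fs / cutoff_hz`) of either edge remain
#' boundary-condition approximations. Output length equals input length.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz Cut-off frequency (must be below `fs / 2`).
#' @param order Filter order (>= 1).
#' @return Filtered numeric vector, same length as `x`.
#' @export
lowpass_butterworth <- function(x, fs, cutoff_hz = 3, order = 4) {
  validate_signal(x, fs)
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("cutoff_hz must lie in (0, fs/2)", call. = FALSE)
  if (length(x) < 3 * (order + 1))
    stop("signal shorter than the filter warm-up (need >= ",
         3 * (order + 1), " samples)", call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # pad with ~6 settling lengths of the cut-off, capped by signal length
  pad <- min(length(x) - 1, ceiling(6 * fs / cutoff_hz))
  filtfilt_ss(bf$b, bf$a, x, pad)
}

# Zero-phase filtering with reflection extension and steady-state initial
# conditions: each pass starts as if its input had been constant at its
# first sample forever (so DC passes exactly), and the reflected extension
# gives the transient a full settling length before the retained region.
# Reflection (unlike odd extension) adds no DC offset when the edge sample
# of an oscillating signal is far from zero.
filtfilt_ss <- function(b, a, x, pad) {
  n <- length(x)
  p <- max(1L, min(n - 1L, pad))
  ext <- c(x[(p + 1):2], x, x[(n - 1):(n - p)])
  dc_gain <- sum(b) / sum(a)
  run <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1], length(b) - 1),
                              init.y = rep(z[1] * dc_gain, length(a) - 1)))
  }
  y <- rev(run(rev(run(ext))))
  y[(p + 1):(p + n)]
}

#' Running median filter
#'
#' Short running median used after the low-pass stage to knock out residual
#' spikes (maternal ECG, movement artifacts) that survive linear filtering.
#' The kernel length in samples is rounded to the nearest odd integer >= 3;
#' edges are handled by reflection so output length equals input length.
#'
#' @inheritParams lowpass_butterworth
#' @param kernel_s Kernel length in seconds.
#' @return Filtered numeric vector, same length as `x`.
#' @export
median_smooth <- function(x, fs, kernel_s = 0.2) {
  validate_signal(x, fs)
  k <- round(kernel_s * fs)
  if (k %% 2 == 0) k <- k + 1
  k <- max(k, 3)
  if (k > length(x))
    stop("median kernel (", k, " samples) longer than the signal",
         call. = FALSE)
  half <- (k - 1) / 2
  padded <- reflect_pad(x, half)
  y <- stats::runmed(padded, k, endrule = "keep")
  y[(half + 1):(half + length(x))]
}

#' Preprocess a raw multichannel recording into one clean EHG signal
#'
#' Runs the three preprocessing stages in order: channel averaging,
#' zero-phase Butterworth low-pass (default 4th order, 3 Hz), and a running
#' median. Every stage preserves signal length and sampling rate.
#'
#' @param rec A recording tibble.
#' @param config A [preprocess_config()].
#' @param channels Channels to average (default: all EHG channels).
#' @return A tibble with columns `time_s` and `ehg` (the preprocessed
#'   signal), carrying the sampling rate as attribute `fs`.
#' @export
preprocess <- function(rec, config = preprocess_config(), channels = NULL) {
  stopifnot(inherits(config, "preprocess_config"))
  fs <- recording_fs(rec)
  x <- average_channels(rec, channels)
  x <- lowpass_butterworth(x, fs, config$lpf_cutoff_hz, config$lpf_order)
  x <- median_smooth(x, fs, config$median_kernel_s)
  out <- tibble::tibble(time_s = rec$time_s, ehg = x)
  attr(out, "fs") <- fs
  out
}
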