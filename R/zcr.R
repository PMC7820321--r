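#' Mean amplitude of a signal
#'
#' The reference level E used by the elevation stage. By default this is the
#' mean of the absolute sample values: after zero-phase low-pass filtering
#' the plain signed mean is essentially zero, which would make the elevation
#' offset vanish and leave the zero-crossing rate blind to amplitude. The
#' signed arithmetic mean is available via `mode = "signed"`.
#'
#' @param x Numeric signal (non-empty, finite).
#' @param mode `"abs"` (default) or `"signed"`.
#' @return A single number, the mean amplitude E.
#' @export
mean_amplitude <- function(x, mode = c("abs", "signed")) {
  mode <- match.arg(mode)
  validate_signal(x)
  if (mode == "abs") mean(abs(x)) else mean(x)
}

#' Elevate a signal by a constant offset
#'
#' Shifts every sample up by `alpha * E`. Oscillations whose amplitude stays
#' below the offset no longer cross zero, so after elevation the
#' zero-crossing rate responds only to high-amplitude (contraction) activity.
#'
#' @param x Numeric signal.
#' @param alpha Offset coefficient in \[0, 5\].
#' @param E Mean amplitude (>= 0), typically from [mean_amplitude()].
#' @return `x + alpha * E`.
#' @export
elevate <- function(x, alpha, E) {
  validate_signal(x)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0,
            is.numeric(E), length(E) == 1, E >= 0)
  x + alpha * E
}

# Indicator of sign changes between consecutive samples with zeros treated as
# transparent: element k is 1 when sample k is nonzero and the most recent
# nonzero sample before it has the opposite sign. Element 1 is always 0.
# A run +,0,- therefore counts one crossing at the '-', and +,0,+ counts none.
sign_change_indicator <- function(x) {
  s <- sign(x)
  nz <- s != 0
  idx <- cumsum(nz)                       # index of last nonzero at/before k
  carried <- c(0, s[nz])[idx + 1]         # 0 until the first nonzero sample
  prev <- c(0, carried[-length(carried)]) # last nonzero sign strictly before k
  as.integer(nz & prev != 0 & s * prev < 0)
}

#' Count zero crossings in a window
#'
#' Number of transitions between strictly positive and strictly negative
#' regimes, scanning left to right. Exact zeros are transparent: they carry
#' the previous regime until a sample of genuinely opposite sign appears, so
#' `+1, 0, -1` counts one crossing and `+1, 0, +1` counts none. Zeros before
#' the first nonzero sample contribute nothing.
#'
#' @param window Numeric vector, length >= 2.
#' @return Integer count of crossings m (at most `length(window) - 1`).
#' @export
count_sign_changes <- function(window) {
  if (!is.numeric(window) || length(window) < 2)
    stop("window must be numeric with length >= 2", call. = FALSE)
  if (!all(is.finite(window)))
    stop("window contains non-finite values", call. = FALSE)
  sum(sign_change_indicator(window))
}

#' Sliding-window zero-crossing rate
#'
#' For every sample position, the zero-crossing rate Z = m / W x 100 (in
#' percent), where m is the number of sign changes inside the W-sample window
#' centred at that position and the window advances one sample at a time.
#' The signal is reflection-padded so the output has the same length as the
#' input. Computed in O(n) by box-summing the per-gap sign-change indicator.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param window_s Window length in seconds (W = `round(window_s * fs)`
#'   samples; the signal must be at least that long).
#' @return Numeric vector of Z values in \[0, 100\], same length as `x`.
#' @export
sliding_zcr <- function(x, fs, window_s = 40) {
  validate_signal(x, fs)
  w <- round(window_s * fs)
  if (w < 2) stop("window must span at least 2 samples", call. = FALSE)
  if (length(x) < w)
    stop("signal (", length(x), " samples) shorter than the ZCR window (",
         w, " samples)", call. = FALSE)
  off <- window_offsets(w)
  padded <- reflect_pad(x, off$left, off$right)
  d <- sign_change_indicator(padded)
  # window at output t covers padded indices t .. t+w-1; crossings are
  # counted at gaps strictly inside the window, i.e. indicator t+1 .. t+w-1
  cs <- cumsum(d)
  n <- length(x)
  m <- cs[seq_len(n) + w - 1] - cs[seq_len(n)]
  100 * m / w
}

#' Min-max normalisation to \[0, 1\]
#'
#' Rescales a signal to the unit interval over the whole recording,
#' removing between-subject differences in absolute zero-crossing rate.
#' A constant signal maps to all zeros.
#'
#' @param z Numeric signal.
#' @return Numeric vector in \[0, 1\], same length.
#' @export
normalize_unit <- function(z) {
  validate_signal(z)
  lo <- min(z); hi <- max(z)
  if (hi == lo) return(rep(0, length(z)))
  (z - lo) / (hi - lo)
}

#' Power weighting of the normalised zero-crossing rate
#'
#' Raises the normalised ZCR pointwise to the power `gamma` (> 1). On \[0, 1\]
#' this strengthens values near 1 relative to values near 0, sharpening the
#' contrast between contraction and quiescent segments; the output never
#' exceeds the input.
#'
#' @param z_norm Numeric signal with all values in \[0, 1\].
#' @param gamma Exponent, > 1.
#' @return `z_norm ^ gamma`, same length, values in \[0, 1\].
#' @export
zcr_power <- function(z_norm, gamma) {
  validate_signal(z_norm)
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma > 1)
  if (min(z_norm) < 0 || max(z_norm) > 1)
    stop("z_norm must lie in [0, 1]; run normalize_unit() first",
         call. = FALSE)
  z_norm^gamma
}

#' Pointwise modulation of a signal by a weight trace
#'
#' @param x Numeric signal (e.g. the preprocessed EHG).
#' @param weight Numeric weight of the same length (e.g. the powered ZCR).
#' @return `x * weight`.
#' @export
modulate <- function(x, weight) {
  validate_signal(x)
  validate_signal(weight, what = "weight")
  if (length(x) != length(weight))
    stop("signal and weight lengths differ (", length(x), " vs ",
         length(weight), ")", call. = FALSE)
  x * weight
}

#' ZCR modulation of a preprocessed EHG signal
#'
#' The central transform: compute the mean amplitude E, elevate the signal by
#' `alpha * E`, take the sliding-window zero-crossing rate of the elevated
#' signal, min-max normalise it, raise it to the power `gamma`, and multiply
#' the original (un-elevated) preprocessed signal by the resulting weight.
#' Contraction bursts — whose amplitude rides above the elevation offset and
#' keeps crossing zero — receive weights near 1; quiescent segments are
#' pushed towards 0.
#'
#' @param x Preprocessed EHG signal (numeric vector).
#' @param fs Sampling rate in Hz.
#' @param config A [zcr_config()].
#' @return The modulated signal, same length as `x`.
#' @export
zcr_modulate <- function(x, fs, config = zcr_config()) {
  stopifnot(inherits(config, "zcr_config"))
  E <- mean_amplitude(x, mode = config$mean_mode)
  elevated <- elevate(x, config$alpha, max(E, 0))
  z <- sliding_zcr(elevated, fs, config$window_s)
  weight <- zcr_power(normalize_unit(z), config$gamma)
  modulate(x, weight)
}
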