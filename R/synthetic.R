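#' Configuration for the synthetic recording generator
#'
#' The generator emulates the signal model underlying abdominal EHG: each
#' contraction is a burst of band-limited fast-wave activity whose amplitude
#' is modulated by a smooth slow-wave (raised-cosine) envelope, superimposed
#' on per-electrode background noise; a co-registered TOCO channel carries a
#' bump at each contraction over a noisy baseline tone; and the
#' maternal-perception track marks jittered burst centres with occasional
#' missed presses.
#'
#' @param duration_s Recording length in seconds (default 1800, ~30 min).
#' @param fs Sampling rate in Hz (default 250).
#' @param n_ucs Number of planted contractions (default 8, the typical count
#'   per 30-minute recording).
#' @param uc_duration_range_s Range (low, high) of contraction durations in
#'   seconds; 30-60 s is the clinically reported range.
#' @param fast_wave_band_hz Pass band (low, high) in Hz of the fast-wave
#'   oscillation; must lie within (0, 3) Hz to survive the low-pass stage.
#' @param burst_amplitude RMS amplitude of a burst at its envelope peak
#'   (arbitrary units).
#' @param noise_amplitude Standard deviation of the per-channel background
#'   noise (same units).
#' @param perception_jitter_s Uniform jitter half-width applied to each
#'   perception label around its burst centre (default 10 s).
#' @param perception_dropout Probability that a contraction goes unlabelled
#'   (default 0.1).
#' @param n_channels Number of EHG channels (default 8).
#' @param seed Integer seed; the whole fixture is reproducible from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(duration_s = 1800, fs = 250, n_ucs = 8,
                       uc_duration_range_s = c(30, 60),
                       fast_wave_band_hz = c(0.3, 1.0),
                       burst_amplitude = 10, noise_amplitude = 2,
                       perception_jitter_s = 10, perception_dropout = 0.1,
                       n_channels = 8, seed = 1L) {
  stopifnot(duration_s > 0, fs > 0, n_ucs >= 0, n_ucs == round(n_ucs))
  stopifnot(length(uc_duration_range_s) == 2,
            uc_duration_range_s[1] > 0,
            uc_duration_range_s[1] <= uc_duration_range_s[2])
  stopifnot(length(fast_wave_band_hz) == 2,
            fast_wave_band_hz[1] > 0,
            fast_wave_band_hz[1] < fast_wave_band_hz[2],
            fast_wave_band_hz[2] < 3, fast_wave_band_hz[2] < fs / 2)
  stopifnot(burst_amplitude > 0, noise_amplitude >= 0,
            perception_jitter_s >= 0,
            perception_dropout >= 0, perception_dropout <= 1)
  stopifnot(n_channels >= 1, n_channels == round(n_channels))
  stopifnot(is.numeric(seed), length(seed) == 1, seed == round(seed))
  structure(
    list(duration_s = duration_s, fs = fs, n_ucs = as.integer(n_ucs),
         uc_duration_range_s = as.numeric(uc_duration_range_s),
         fast_wave_band_hz = as.numeric(fast_wave_band_hz),
         burst_amplitude = burst_amplitude,
         noise_amplitude = noise_amplitude,
         perception_jitter_s = perception_jitter_s,
         perception_dropout = perception_dropout,
         n_channels = as.integer(n_channels), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Draw n sorted centre times in [lo, hi] with all gaps >= min_gap, uniformly
# over the constrained set (gap construction, no rejection).
place_centers <- function(n, lo, hi, min_gap) {
  if (n == 0) return(numeric(0))
  slack <- (hi - lo) - (n - 1) * min_gap
  if (slack < 0)
    stop("cannot place ", n, " contractions ", min_gap,
         " s apart in the recording", call. = FALSE)
  u <- sort(stats::runif(n, 0, slack))
  lo + u + min_gap * (seq_len(n) - 1)
}

# Hann (raised-cosine) bump of unit height over `dur_s`, centred at
# `center_s`, evaluated on the time grid.
hann_bump <- function(time_s, center_s, dur_s) {
  rel <- (time_s - center_s) / dur_s
  ifelse(abs(rel) <= 0.5, cos(pi * rel)^2, 0)
}

#' Simulate a multichannel EHG + TOCO recording with known ground truth
#'
#' Builds a seeded fixture: `n_channels` EHG channels sharing a common burst
#' train (per-burst band-passed Gaussian fast wave scaled to unit RMS, times
#' a Hann slow-wave envelope of the drawn duration, times `burst_amplitude`)
#' plus independent white background noise per channel; a TOCO channel with a
#' Hann bump per contraction over a noisy baseline tone; and a perception
#' track of jittered, possibly dropped burst centres. A planted duration is
#' the contraction's duration under the clinical definition (the half-wave
#' width of its envelope), so the Hann bump spans twice that duration at its
#' base. Burst centres are placed uniformly at random subject to a minimum
#' separation that keeps whole bump bases from overlapping (twice the
#' maximum contraction duration, plus 10 s of quiescence). Global RNG state is left untouched.
#'
#' @param config A [sim_config()].
#' @return A list of class `uc_fixture`: `recording` (tibble with `time_s`,
#'   `ehg1..ehgK`, `toco`), `annotations` (tibble, `time_s`), `truth`
#'   (tibble, `center_s`, `duration_s`), and `config`.
#' @export
simulate_recording <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_recording_impl(config))
}

simulate_recording_impl <- function(cfg) {
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  time_s <- (seq_len(n) - 1) / fs
  max_dur <- cfg$uc_duration_range_s[2]
  margin <- max_dur / 2 + 5
  # bumps span twice their FWHM duration at the base; keep whole bases from
  # overlapping, plus 10 s of quiescence
  min_gap <- 2 * max_dur + 10

  centers <- place_centers(cfg$n_ucs, margin, cfg$duration_s - margin,
                           min_gap)
  durations <- stats::runif(cfg$n_ucs, cfg$uc_duration_range_s[1],
                            cfg$uc_duration_range_s[2])

  # shared burst train: band-limited fast wave, unit RMS, scaled by the Hann
  # slow-wave envelope and the burst amplitude. The fast wave is band-passed
  # Gaussian noise synthesised at a decimated rate (a 0.3-1 Hz band is a
  # vanishing fraction of Nyquist at 250 Hz, where an IIR band-pass is
  # numerically degenerate) and spline-interpolated back to fs.
  burst_train <- numeric(n)
  fs_lo <- min(fs, max(10, 8 * cfg$fast_wave_band_hz[2]))
  bf <- signal::butter(4, cfg$fast_wave_band_hz / (fs_lo / 2), type = "pass")
  for (k in seq_along(centers)) {
    base_s <- 2 * durations[k]  # Hann FWHM = half its base = planted duration
    a <- max(1L, round((centers[k] - base_s / 2) * fs) + 1L)
    b <- min(n, round((centers[k] + base_s / 2) * fs) + 1L)
    pad_s <- 4 / cfg$fast_wave_band_hz[1]
    t0 <- (a - 1) / fs - pad_s
    t1 <- (b - 1) / fs + pad_s
    m <- ceiling((t1 - t0) * fs_lo) + 1L
    raw <- stats::rnorm(m)
    filt <- signal::filtfilt(bf, raw)
    fast <- stats::spline(t0 + (seq_len(m) - 1) / fs_lo, filt,
                          xout = time_s[a:b])$y
    fast <- fast / max(stats::sd(fast), .Machine$double.eps)
    env <- hann_bump(time_s[a:b], centers[k], base_s)
    burst_train[a:b] <- burst_train[a:b] +
      cfg$burst_amplitude * env * fast
  }

  channels <- stats::setNames(
    lapply(seq_len(cfg$n_channels), function(j)
      burst_train + stats::rnorm(n, sd = cfg$noise_amplitude)),
    paste0("ehg", seq_len(cfg$n_channels))
  )

  # TOCO: baseline tone ~10 units, bumps of ~40 units, mild transducer noise
  toco <- 10 + stats::rnorm(n, sd = 1)
  for (k in seq_along(centers))
    toco <- toco + 40 * hann_bump(time_s, centers[k], 2 * durations[k])
  channels$toco <- toco

  labels <- centers +
    stats::runif(length(centers), -cfg$perception_jitter_s,
                 cfg$perception_jitter_s)
  kept <- stats::runif(length(centers)) >= cfg$perception_dropout
  labels <- pmin(pmax(labels[kept], 0), cfg$duration_s)

  structure(
    list(
      recording = as_recording(channels, fs = fs),
      annotations = tibble::tibble(time_s = sort(unique(labels))),
      truth = tibble::tibble(center_s = centers, duration_s = durations),
      config = cfg
    ),
    class = "uc_fixture"
  )
}

#' Generate a cohort of synthetic recordings
#'
#' Derives one reproducible seed per recording from `master_seed`, draws each
#' recording's contraction count from a Poisson distribution with mean
#' `mean_ucs` (truncated below at 1 and above at the most contractions the
#' recording geometry can hold without overlap), and simulates each fixture. The
#' default mean of 8.35 contractions per 30-minute recording matches the
#' typical labelled count per subject.
#'
#' @param n_recordings Number of recordings (>= 1).
#' @param base_config A [sim_config()] whose `n_ucs` and `seed` are
#'   overridden per recording.
#' @param master_seed Integer master seed.
#' @param mean_ucs Mean planted contractions per recording.
#' @return A list of `uc_fixture` objects (see [simulate_recording()]).
#' @export
make_cohort <- function(n_recordings, base_config = sim_config(),
                        master_seed = 1L, mean_ucs = 8.35) {
  stopifnot(n_recordings >= 1, n_recordings == round(n_recordings))
  stopifnot(inherits(base_config, "sim_config"))
  # most contractions that fit the recording under the non-overlap rule
  max_dur <- base_config$uc_duration_range_s[2]
  span <- base_config$duration_s - 2 * (max_dur / 2 + 5)
  n_max <- max(1, floor(span / (2 * max_dur + 10)) + 1)
  draws <- withr::with_seed(master_seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, n_recordings),
         n_ucs = pmin(n_max, pmax(1L, stats::rpois(n_recordings, mean_ucs))))
  })
  purrr::map(seq_len(n_recordings), function(i) {
    args <- unclass(base_config)
    args$n_ucs <- draws$n_ucs[i]
    args$seed <- draws$seeds[i]
    simulate_recording(do.call(sim_config, args))
  })
}
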