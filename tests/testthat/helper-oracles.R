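# Independent brute-force oracles. These deliberately re-derive every
# quantity with naive scans and explicit index arithmetic; they share no code
# with the implementation.

# Mirror-reflected sample lookup (edge sample not repeated): index j may lie
# outside 1..n.
reflect_at <- function(x, j) {
  n <- length(x)
  if (j < 1) return(x[2 - j])
  if (j > n) return(x[2 * n - j])
  x[j]
}

# The w-sample window centred at output position t, under the same centring
# convention as the sliding stages: offsets floor((w-1)/2) left,
# w-1-floor((w-1)/2) right.
oracle_window <- function(x, t, w) {
  off_l <- floor((w - 1) / 2)
  vapply((t - off_l):(t - off_l + w - 1), function(j) reflect_at(x, j),
         numeric(1))
}

# Regime-tracking zero-crossing count: scan left to right, carrying the last
# nonzero sign; count a crossing when a strictly opposite sign appears.
oracle_sign_changes <- function(w) {
  last <- 0
  m <- 0L
  for (v in w) {
    s <- sign(v)
    if (s != 0) {
      if (last != 0 && s != last) m <- m + 1L
      last <- s
    }
  }
  m
}

oracle_zcr_at <- function(x, t, w) {
  100 * oracle_sign_changes(oracle_window(x, t, w)) / w
}

oracle_rms_at <- function(x, t, w) {
  win <- oracle_window(x, t, w)
  sqrt(sum(win^2) / w)
}

oracle_mean_at <- function(x, t, w) {
  mean(oracle_window(x, t, w))
}

oracle_median_at <- function(x, t, k) {
  sort(oracle_window(x, t, k))[(k + 1) / 2]
}

# Maximum-cardinality matching between peaks and labels under a tolerance,
# by exhaustive branch-and-bound over label assignments (small inputs only).
oracle_max_matching <- function(peaks, labels, tol) {
  if (length(peaks) == 0 || length(labels) == 0) return(0L)
  best <- oracle_max_matching(peaks, labels[-1], tol)
  for (i in seq_along(peaks)) {
    if (abs(peaks[i] - labels[1]) <= tol)
      best <- max(best, 1L + oracle_max_matching(peaks[-i], labels[-1], tol))
  }
  best
}

# Small recording fixture: a couple of channels of seeded noise plus a toco
# channel, used by IO and preprocessing tests.
tiny_recording <- function(n = 400, fs = 20, n_ehg = 3, seed = 99) {
  withr::with_seed(seed, {
    chans <- stats::setNames(
      lapply(seq_len(n_ehg), function(j) stats::rnorm(n)),
      paste0("ehg", seq_len(n_ehg)))
    chans$toco <- 10 + stats::rnorm(n)
    as_recording(chans, fs = fs)
  })
}

# Small YAML run-config pointing the simulator at a light fixture (used by
# the CLI tests).
write_mini_config <- function(dir) {
  path <- file.path(dir, "mini-config.yaml")
  if (!file.exists(path))
    writeLines(c("sim:",
                 "  fs: 50",
                 "  duration_s: 900",
                 "  n_ucs: 4"), path)
  path
}
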