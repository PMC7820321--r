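#' Match detected peaks to reference labels within a tolerance
#'
#' One-to-one matching between detected contraction peaks and reference
#' (maternal-perception) labels: all pairs within `tol_s` seconds are ranked
#' by increasing absolute time difference (ties broken by the earlier peak,
#' then the earlier label) and accepted greedily, never reusing a peak or a
#' label. One perception press marks one contraction, so a label can never
#' validate two detections.
#'
#' @param detected_s Numeric vector of detected peak times (seconds).
#' @param labels_s Numeric vector of reference label times (seconds).
#' @param tol_s Matching tolerance in seconds, inclusive (default 20).
#' @return A list with integer counts `tp`, `fp`, `fn` and a tibble `pairs`
#'   (`peak_s`, `label_s`, `delta_s`) of the accepted matches.
#' @export
match_events <- function(detected_s, labels_s, tol_s = 20) {
  stopifnot(is.numeric(tol_s), length(tol_s) == 1, tol_s > 0)
  detected_s <- sort(as.numeric(detected_s))
  labels_s <- sort(as.numeric(labels_s))
  nd <- length(detected_s)
  nl <- length(labels_s)

  pairs <- tibble::tibble(peak_s = numeric(0), label_s = numeric(0),
                          delta_s = numeric(0))
  if (nd > 0 && nl > 0) {
    grid <- tidyr::expand_grid(di = seq_len(nd), li = seq_len(nl))
    grid$delta <- abs(detected_s[grid$di] - labels_s[grid$li])
    grid <- grid[grid$delta <= tol_s, , drop = FALSE]
    grid <- grid[order(grid$delta, detected_s[grid$di], labels_s[grid$li]), ,
                 drop = FALSE]
    used_d <- logical(nd)
    used_l <- logical(nl)
    keep <- logical(nrow(grid))
    for (r in seq_len(nrow(grid))) {
      di <- grid$di[r]; li <- grid$li[r]
      if (!used_d[di] && !used_l[li]) {
        used_d[di] <- TRUE
        used_l[li] <- TRUE
        keep[r] <- TRUE
      }
    }
    acc <- grid[keep, , drop = FALSE]
    pairs <- tibble::tibble(peak_s = detected_s[acc$di],
                            label_s = labels_s[acc$li],
                            delta_s = acc$delta)
    pairs <- pairs[order(pairs$peak_s), ]
  }

  tp <- nrow(pairs)
  list(tp = tp, fp = nd - tp, fn = nl - tp, pairs = pairs)
}

#' Sensitivity and positive predictive value from match counts
#'
#' Sensitivity = TP / (TP + FN), PPV = TP / (TP + FP). A zero denominator
#' yields 0 and is flagged in the result.
#'
#' @param tp,fp,fn Non-negative integer counts of true positives, false
#'   positives and false negatives.
#' @return An object of class `uc_evaluation` with fields `tp`, `fp`, `fn`,
#'   `sensitivity`, `ppv` (both in \[0, 1\]) and `undefined` (character
#'   vector naming any rate whose denominator was 0). Use
#'   [tidy()][generics::tidy] / [glance()][generics::glance] for tibbles.
#' @examples
#' sensitivity_ppv(tp = 396, fp = 29, fn = 55)
#' @export
sensitivity_ppv <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0,
            tp == round(tp), fp == round(fp), fn == round(fn))
  undefined <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "sensitivity"); 0
  }
  ppv <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "ppv"); 0
  }
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         sensitivity = sens, ppv = ppv, undefined = undefined),
    class = "uc_evaluation"
  )
}

#' @export
print.uc_evaluation <- function(x, ...) {
  cat("<uc_evaluation> TP=", x$tp, " FP=", x$fp, " FN=", x$fn, "\n", sep = "")
  cat(sprintf("  sensitivity: %.2f%%\n", 100 * x$sensitivity))
  cat(sprintf("  PPV:         %.2f%%\n", 100 * x$ppv))
  if (length(x$undefined) > 0)
    cat("  undefined (0 denominator): ",
        paste(x$undefined, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate a detection result against perception labels
#'
#' Convenience wrapper: pulls the peaks of one source from a detection (or an
#' event tibble), matches them to the annotation track, and returns the
#' counts and rates.
#'
#' @param detection A `uc_detection` object or an event tibble.
#' @param annotations Annotation tibble (`time_s` column) or numeric vector
#'   of label times in seconds.
#' @param source Which detector to evaluate: `"EHG"` or `"TOCO"`.
#' @param tol_s Matching tolerance in seconds.
#' @return A `uc_evaluation` (see [sensitivity_ppv()]).
#' @export
evaluate_detection <- function(detection, annotations, source = "EHG",
                               tol_s = 20) {
  events <- if (inherits(detection, "uc_detection")) detection$events
            else detection
  peaks <- events$peak_s[events$source == source]
  m <- match_events(peaks, annotation_times(annotations), tol_s)
  sensitivity_ppv(m$tp, m$fp, m$fn)
}

#' Clinical contraction parameters
#'
#' Summarises an event list into the quantities tracked clinically: the
#' contraction count, the frequency per 10 minutes, the half-wave-width
#' durations, and the intervals between adjacent peaks.
#'
#' @param events Event tibble (one detector's events, sorted by peak).
#' @param recording_len_s Recording length in seconds (> 0).
#' @return An object of class `uc_parameters`: list with `count`,
#'   `freq_per_10min`, `durations_s`, `intervals_s` and their means/SDs
#'   (`NA` where fewer than 1 or 2 values exist). [tidy()][generics::tidy]
#'   returns the one-row summary.
#' @export
uc_parameters <- function(events, recording_len_s) {
  if (!is.numeric(recording_len_s) || length(recording_len_s) != 1 ||
      recording_len_s <= 0)
    stop("recording_len_s must be a single positive number", call. = FALSE)
  peaks <- sort(events$peak_s)
  durations <- events$duration_s[order(events$peak_s)]
  count <- length(peaks)
  intervals <- if (count >= 2) diff(peaks) else numeric(0)
  msd <- function(v) {
    c(mean = if (length(v) >= 1) mean(v) else NA_real_,
      sd = if (length(v) >= 2) stats::sd(v) else NA_real_)
  }
  dur_ms <- msd(durations)
  int_ms <- msd(intervals)
  structure(
    list(count = count,
         freq_per_10min = count * 600 / recording_len_s,
         durations_s = durations, intervals_s = intervals,
         mean_duration_s = unname(dur_ms["mean"]),
         sd_duration_s = unname(dur_ms["sd"]),
         mean_interval_s = unname(int_ms["mean"]),
         sd_interval_s = unname(int_ms["sd"]),
         recording_len_s = recording_len_s),
    class = "uc_parameters"
  )
}

#' @export
print.uc_parameters <- function(x, ...) {
  cat("<uc_parameters> ", x$count, " contractions in ",
      format(x$recording_len_s / 60, digits = 3), " min (",
      format(x$freq_per_10min, digits = 3), " per 10 min)\n", sep = "")
  if (x$count > 0)
    cat(sprintf("  duration: %.1f +/- %.1f s\n", x$mean_duration_s,
                if (is.na(x$sd_duration_s)) 0 else x$sd_duration_s))
  if (length(x$intervals_s) > 0)
    cat(sprintf("  interval: %.1f +/- %.1f s\n", x$mean_interval_s,
                if (is.na(x$sd_interval_s)) 0 else x$sd_interval_s))
  invisible(x)
}

#' Compare contraction parameters between two event sets
#'
#' Convenience report: Mann-Whitney U (Wilcoxon rank-sum) tests of the
#' duration and interval distributions between two detectors or two groups,
#' via [stats::wilcox.test()].
#'
#' @param a,b `uc_parameters` objects.
#' @return A tibble with one row per parameter: `parameter`, `statistic`
#'   (the U statistic), `p_value`.
#' @export
compare_uc_parameters <- function(a, b) {
  stopifnot(inherits(a, "uc_parameters"), inherits(b, "uc_parameters"))
  one <- function(name, va, vb) {
    if (length(va) < 1 || length(vb) < 1)
      return(tibble::tibble(parameter = name, statistic = NA_real_,
                            p_value = NA_real_))
    wt <- stats::wilcox.test(va, vb, exact = FALSE)
    tibble::tibble(parameter = name, statistic = unname(wt$statistic),
                   p_value = wt$p.value)
  }
  dplyr::bind_rows(
    one("duration_s", a$durations_s, b$durations_s),
    one("interval_s", a$intervals_s, b$intervals_s)
  )
}

#' Sweep a ZCR parameter over a grid and score the detections
#'
#' Re-runs the EHG detection pipeline over a cohort of fixtures for every
#' value of `alpha` or `gamma` on a grid, pooling TP/FP/FN across recordings
#' (micro-averaging), and reports sensitivity, PPV and their average (the
#' score). The preprocessing stage does not depend on the swept parameter, so
#' each recording is preprocessed once.
#'
#' @param fixtures A list of fixtures, each a list with elements `recording`
#'   (a recording tibble) and `annotations` (tibble or numeric vector of
#'   label times) — e.g. the output of [make_cohort()].
#' @param param `"alpha"` or `"gamma"`.
#' @param grid Numeric vector of parameter values.
#' @param config Base [uc_config()]; the swept field is overridden per row.
#' @return A tibble of class `uc_sweep` with columns `param`, `param_value`,
#'   `tp`, `fp`, `fn`, `sensitivity`, `ppv`, `score`.
#' @export
sweep_parameter <- function(fixtures, param = c("alpha", "gamma"), grid,
                            config = uc_config()) {
  param <- match.arg(param)
  stopifnot(is.numeric(grid), length(grid) >= 1)
  stopifnot(inherits(config, "uc_config"))
  if (length(fixtures) == 0) stop("need at least one fixture", call. = FALSE)

  prepped <- purrr::map(fixtures, function(fx) {
    fs <- recording_fs(fx$recording)
    list(ehg = preprocess(fx$recording, config$preprocess)$ehg, fs = fs,
         labels = annotation_times(fx$annotations))
  })

  rows <- purrr::map(grid, function(value) {
    zcfg_args <- list(alpha = config$zcr$alpha, gamma = config$zcr$gamma,
                      window_s = config$zcr$window_s,
                      mean_mode = config$zcr$mean_mode)
    zcfg_args[[param]] <- value
    zcfg <- do.call(zcr_config, zcfg_args)
    tp <- fp <- fn <- 0L
    for (p in prepped) {
      modulated <- zcr_modulate(p$ehg, p$fs, zcfg)
      env <- rms_envelope(modulated, p$fs, config$detection$rms_window_s)
      ev <- detect_ucs(env, p$fs, config$detection, source = "EHG")
      m <- match_events(ev$peak_s, p$labels, config$match_tol_s)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    res <- sensitivity_ppv(tp, fp, fn)
    tibble::tibble(param = param, param_value = value, tp = tp, fp = fp,
                   fn = fn, sensitivity = res$sensitivity, ppv = res$ppv,
                   score = (res$sensitivity + res$ppv) / 2)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("uc_sweep", class(out))
  out
}
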