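#' Recording containers
#'
#' A recording is an ordinary tibble with one `time_s` column and one column
#' per channel, carrying the sampling rate as an `fs` attribute. All channels
#' share the same length and sampling rate, all samples must be finite.
#'
#' @param channels A data frame, matrix or named list of equal-length numeric
#'   channels (no `time_s` column; it is derived from `fs`).
#' @param fs Sampling rate in Hz (> 0).
#' @return A tibble of class `uc_recording` with columns `time_s` and one per
#'   channel; sample `i` (1-based) is at time `(i - 1) / fs`.
#' @examples
#' rec <- as_recording(list(ehg1 = sin(1:100), toco = cos(1:100)), fs = 10)
#' recording_fs(rec)
#' @export
as_recording <- function(channels, fs) {
  stopifnot(is.numeric(fs), length(fs) == 1, is.finite(fs), fs > 0)
  if (is.matrix(channels)) channels <- as.data.frame(channels)
  channels <- tibble::as_tibble(channels)
  channels$time_s <- NULL
  if (ncol(channels) < 1) stop("recording needs at least one channel",
                               call. = FALSE)
  n <- nrow(channels)
  if (n < 1) stop("recording needs at least one sample", call. = FALSE)
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (!is.numeric(v)) stop("channel '", nm, "' is not numeric",
                             call. = FALSE)
    if (!all(is.finite(v))) stop("channel '", nm,
                                 "' contains non-finite samples",
                                 call. = FALSE)
  }
  out <- dplyr::bind_cols(tibble::tibble(time_s = (seq_len(n) - 1) / fs),
                          channels)
  attr(out, "fs") <- fs
  class(out) <- c("uc_recording", class(out))
  out
}

#' @rdname as_recording
#' @param rec A recording tibble created by [as_recording()] or
#'   [read_recording()].
#' @export
recording_fs <- function(rec) {
  fs <- attr(rec, "fs", exact = TRUE)
  if (is.null(fs)) stop("recording has no `fs` attribute; build it with ",
                        "as_recording() or read_recording()", call. = FALSE)
  fs
}

#' @rdname as_recording
#' @export
channel_labels <- function(rec) setdiff(names(rec), "time_s")

#' @rdname as_recording
#' @export
recording_duration_s <- function(rec) {
  nrow(rec) / recording_fs(rec)
}

# Pull one channel as a plain numeric vector.
channel_vector <- function(rec, label) {
  if (!label %in% names(rec))
    stop("unknown channel label: ", label, call. = FALSE)
  rec[[label]]
}

# EHG channels = everything except TOCO (case-insensitive) and time_s.
ehg_labels <- function(rec) {
  labs <- channel_labels(rec)
  labs[tolower(labs) != "toco"]
}

toco_label <- function(rec) {
  labs <- channel_labels(rec)
  hit <- labs[tolower(labs) == "toco"]
  if (length(hit) == 0) return(NULL)
  hit[[1]]
}

validate_signal <- function(x, fs, what = "signal") {
  if (!is.numeric(x) || length(x) < 1)
    stop(what, " must be a non-empty numeric vector", call. = FALSE)
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  if (!missing(fs)) {
    if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
      stop("fs must be a single positive number", call. = FALSE)
  }
  invisible(x)
}

#' Read and write recordings
#'
#' Two on-disk formats are supported. The delimited format is CSV with a
#' leading `# fs=<Hz>` comment line and a header row of channel labels; the
#' EDF format is the standard 16-bit European Data Format (one data record
#' spanning the recording). Format is inferred from the file extension when
#' `format = "auto"`.
#'
#' @param path File path.
#' @param format `"auto"`, `"delimited"` or `"edf"`.
#' @return `read_recording()` returns a recording tibble (see
#'   [as_recording()]); `write_recording()` invisibly returns `path`.
#' @export
read_recording <- function(path, format = c("auto", "delimited", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  if (format == "edf") return(read_edf(path))

  lines <- readLines(path, n = 50L)
  if (length(lines) == 0 || !nzchar(paste(lines, collapse = "")))
    stop("empty recording file: ", path, call. = FALSE)
  fs_line <- grep("^#\\s*fs\\s*=", lines, value = TRUE)
  if (length(fs_line) == 0)
    stop("delimited recording is missing its '# fs=<Hz>' header line: ",
         path, call. = FALSE)
  fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", fs_line[[1]]))
  if (!is.finite(fs) || fs <= 0)
    stop("invalid fs in header of ", path, call. = FALSE)
  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(dat) == 0) stop("recording file has no samples: ", path,
                           call. = FALSE)
  as_recording(dat, fs = fs)
}

#' @rdname read_recording
#' @param rec A recording tibble.
#' @export
write_recording <- function(rec, path, format = c("auto", "delimited", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  fs <- recording_fs(rec)
  if (format == "edf") {
    write_edf(rec, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# fs=%.10g", fs), con)
    labs <- channel_labels(rec)
    dat <- as.data.frame(lapply(rec[labs], function(v) sprintf("%.10g", v)))
    names(dat) <- labs
    utils::write.table(dat, con, sep = ",", row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
  }
  invisible(path)
}

#' Read and write maternal-perception annotations
#'
#' Annotations are event times in seconds from the start of the recording,
#' one per line (lines beginning with `#` are ignored). Times are sorted and
#' duplicates collapsed on read: one button press marks one contraction.
#'
#' @param path File path.
#' @return `read_annotations()` returns a tibble with one column `time_s`,
#'   strictly increasing. An empty file yields zero rows (a recording may
#'   contain no perceived contractions).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines <- lines[tolower(lines) != "time_s"]
  if (length(lines) == 0) return(tibble::tibble(time_s = numeric(0)))
  times <- suppressWarnings(as.numeric(lines))
  if (anyNA(times))
    stop("non-numeric annotation time(s) in ", path, call. = FALSE)
  if (any(times < 0))
    stop("negative annotation time(s) in ", path, call. = FALSE)
  tibble::tibble(time_s = sort(unique(times)))
}

#' @rdname read_annotations
#' @param annotations A tibble with a `time_s` column, or a numeric vector of
#'   event times in seconds.
#' @export
write_annotations <- function(annotations, path) {
  times <- annotation_times(annotations)
  writeLines(c("time_s", sprintf("%.6f", times)), path)
  invisible(path)
}

annotation_times <- function(annotations) {
  if (is.null(annotations)) return(numeric(0))
  times <- if (is.data.frame(annotations)) {
    if (!"time_s" %in% names(annotations))
      stop("annotations need a `time_s` column", call. = FALSE)
    annotations$time_s
  } else {
    as.numeric(annotations)
  }
  if (anyNA(times) || any(!is.finite(times)))
    stop("annotation times must be finite", call. = FALSE)
  if (any(times < 0)) stop("annotation times must be >= 0", call. = FALSE)
  sort(unique(times))
}

#' Read and write detected contraction events
#'
#' Events are written as CSV with columns `source`, `onset_s`, `peak_s`,
#' `end_s`, `peak_amplitude`, `duration_s` (times in seconds, microsecond
#' precision). An empty event table writes a header-only file.
#'
#' @param events An event tibble as returned by [detect_ucs()] or
#'   [detect_contractions()].
#' @param path File path.
#' @export
write_events <- function(events, path) {
  cols <- c("source", "onset_s", "peak_s", "end_s", "peak_amplitude",
            "duration_s")
  missing <- setdiff(cols, names(events))
  if (length(missing) > 0)
    stop("event table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- events[cols]
  num <- setdiff(cols, "source")
  out[num] <- lapply(out[num], function(v) sprintf("%.6f", v))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      source = readr::col_character(),
      .default = readr::col_double()
    )
  )
  tibble::as_tibble(dat)
}
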