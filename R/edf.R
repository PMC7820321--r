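# Minimal European Data Format (EDF) reader/writer.
#
# Implements the plain 16-bit EDF layout: a 256-byte fixed header, 256 bytes
# of header per signal (field-major), then data records of little-endian
# int16 samples scaled between per-channel physical and digital ranges.
# The writer emits a single data record spanning the whole recording, which
# keeps arbitrary lengths exactly representable; the reader accepts any
# record structure. Quantisation to 16 bits bounds the round-trip error at
# (physical range) / (digital range).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

write_edf <- function(rec, path) {
  fs <- recording_fs(rec)
  labs <- channel_labels(rec)
  ns <- length(labs)
  n <- nrow(rec)
  dig_min <- -32767
  dig_max <- 32767

  phys_min <- phys_max <- numeric(ns)
  digital <- matrix(0L, nrow = n, ncol = ns)
  for (j in seq_len(ns)) {
    v <- rec[[labs[j]]]
    lo <- min(v); hi <- max(v)
    if (hi == lo) hi <- lo + 1  # flat channel: any span works, zero error
    phys_min[j] <- lo; phys_max[j] <- hi
    digital[, j] <- as.integer(round(
      dig_min + (v - lo) * (dig_max - dig_min) / (hi - lo)))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)

  header_bytes <- 256L + 256L * ns
  wr(edf_pad("0", 8))                       # version
  wr(edf_pad("X X X X", 80))                # patient id (anonymous)
  wr(edf_pad("Startdate X X X X", 80))      # recording id
  wr(edf_pad("01.01.00", 8))                # start date (placeholder)
  wr(edf_pad("00.00.00", 8))                # start time
  wr(edf_pad(header_bytes, 8))
  wr(edf_pad("", 44))
  wr(edf_pad(1, 8))                         # one data record
  wr(edf_num(n / fs, 8))                    # record duration (s)
  wr(edf_pad(ns, 4))

  for (l in labs) wr(edf_pad(l, 16))
  for (l in labs) wr(edf_pad("", 80))       # transducer
  for (l in labs) wr(edf_pad("uV", 8))      # physical dimension
  for (j in seq_len(ns)) wr(edf_num(phys_min[j], 8))
  for (j in seq_len(ns)) wr(edf_num(phys_max[j], 8))
  for (j in seq_len(ns)) wr(edf_pad(dig_min, 8))
  for (j in seq_len(ns)) wr(edf_pad(dig_max, 8))
  for (l in labs) wr(edf_pad("", 80))       # prefiltering
  for (j in seq_len(ns)) wr(edf_pad(n, 8))  # samples per record
  for (l in labs) wr(edf_pad("", 32))

  for (j in seq_len(ns))
    writeBin(digital[, j], con, size = 2, endian = "little")
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    raw <- readChar(con, nchars = width, useBytes = TRUE)
    if (length(raw) == 0 || nchar(raw, type = "bytes") < width)
      stop("truncated EDF header: ", path, call. = FALSE)
    trimws(raw)
  }
  rd(8)                                      # version
  rd(80); rd(80); rd(8); rd(8)               # ids, date, time
  rd(8)                                      # header bytes
  rd(44)
  n_records <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (!isTRUE(ns >= 1)) stop("invalid EDF: no signals in ", path,
                             call. = FALSE)

  labs <- vapply(seq_len(ns), function(j) rd(16), character(1))
  for (j in seq_len(ns)) rd(80)
  for (j in seq_len(ns)) rd(8)
  phys_min <- vapply(seq_len(ns), function(j) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(j) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(j) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(j) as.numeric(rd(8)), numeric(1))
  for (j in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(j) as.integer(rd(8)), integer(1))
  for (j in seq_len(ns)) rd(32)

  if (any(!is.finite(c(phys_min, phys_max, dig_min, dig_max))) ||
      anyNA(spr) || !is.finite(rec_dur) || rec_dur <= 0)
    stop("invalid EDF header fields in ", path, call. = FALSE)

  chans <- lapply(seq_len(ns), function(j) numeric(0))
  for (r in seq_len(n_records)) {
    for (j in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[j], size = 2, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[j])
        stop("truncated EDF data record in ", path, call. = FALSE)
      chans[[j]] <- c(chans[[j]], phys_min[j] +
        (dig - dig_min[j]) * (phys_max[j] - phys_min[j]) /
          (dig_max[j] - dig_min[j]))
    }
  }

  fs <- spr[1] / rec_dur
  names(chans) <- labs
  as_recording(chans, fs = fs)
}
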