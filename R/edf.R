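# Minimal European Data Format (EDF) support, base-R binary I/O.
# Covers continuous recordings with one common sampling rate: the standard
# 256-byte header, 256 bytes per signal, and 16-bit little-endian samples
# stored record by record.  Amplitudes are quantized to 16 bits on write.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("EDF header field too long: ", s)
  formatC(s, width = -width)  # left-justified, space padded
}

edf_num <- function(x, width = 8) {
  for (d in 7:1) {
    s <- sprintf("%.*g", d, x)
    if (nchar(s) <= width) return(edf_field(s, width))
  }
  stop("cannot format ", x, " in ", width, " characters")
}

#' Write a recording to a European Data Format (EDF) file
#'
#' Writes a continuous EDF file with 1-second data records.  The sampling
#' rate must be a whole number; if the duration is not a whole number of
#' seconds the tail is zero-padded to complete the final record (with a
#' warning).  Samples are scaled to the per-channel physical range and
#' quantized to 16 bits, so the round trip is exact only up to quantization
#' (relative error about 3e-5 of the channel range).
#'
#' @param rec a \code{\link{recording}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  x <- rec$data
  ns <- nrow(x)
  n_rec <- as.integer(ceiling(ncol(x) / fs))
  if (ncol(x) < n_rec * fs) {
    warning("zero-padding final EDF record")
    x <- cbind(x, matrix(0, ns, n_rec * fs - ncol(x)))
  }
  plo <- apply(x, 1, min); phi <- apply(x, 1, max)
  flat <- phi - plo < 1e-12
  phi[flat] <- plo[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb"); on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(edf_field("0", 8))
  wr(edf_field(rec$subject_id, 80))
  wr(edf_field(rec$condition_label, 80))
  wr(edf_field("01.01.00", 8)); wr(edf_field("00.00.00", 8))
  wr(edf_field(256L * (1L + ns), 8))
  wr(edf_field("", 44))
  wr(edf_field(n_rec, 8)); wr(edf_field(1L, 8)); wr(edf_field(ns, 4))
  for (i in seq_len(ns)) wr(edf_field(rec$channel_labels[i], 16))
  for (i in seq_len(ns)) wr(edf_field("", 80))        # transducer
  for (i in seq_len(ns)) wr(edf_field("uV", 8))       # physical dimension
  for (i in seq_len(ns)) wr(edf_num(plo[i]))
  for (i in seq_len(ns)) wr(edf_num(phi[i]))
  for (i in seq_len(ns)) wr(edf_field(dmin, 8))
  for (i in seq_len(ns)) wr(edf_field(dmax, 8))
  for (i in seq_len(ns)) wr(edf_field("", 80))        # prefiltering
  for (i in seq_len(ns)) wr(edf_field(fs, 8))
  for (i in seq_len(ns)) wr(edf_field("", 32))

  scale <- (dmax - dmin) / (phi - plo)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- as.integer(round((x[i, cols] - plo[i]) * scale[i] + dmin))
      writeBin(as.integer(base::pmin(base::pmax(dig, dmin), dmax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a European Data Format (EDF) file
#'
#' Supports continuous EDF with a common sampling rate across signals (the
#' layout \code{\link{write_edf}} produces, and the common case for cleaned
#' EEG exports).  Signals whose per-record sample count differs from the
#' first signal's are rejected.
#'
#' @param path input file.
#' @return a \code{\link{recording}} with the header sampling rate.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  ver <- rd(8)
  subject <- rd(80); rec_id <- rd(80)
  rd(8); rd(8)                        # date, time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header in '", path, "'")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  plo <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phi <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (any(spr != spr[1L]))
    stop("EDF with per-signal sampling rates is not supported")
  fs <- spr[1L] / rec_dur

  data <- matrix(0, ns, n_rec * spr[1L])
  gain <- (phi - plo) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[i]) stop("truncated EDF data in '", path, "'")
      data[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        plo[i] + (dig - dmin[i]) * gain[i]
    }
  }
  recording(data, fs = fs, channel_labels = labels,
            subject_id = subject, condition_label = rec_id)
}
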