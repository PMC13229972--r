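#' Multichannel EEG recording container
#'
#' Thin container for a channels x samples numeric matrix with its sampling
#' rate and channel labels.  Inputs are assumed artifact-cleaned.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per channel; defaults
#'   to existing rownames or \code{"ch1"}, \code{"ch2"}, ...
#' @param subject_id,condition_label optional metadata strings.
#' @return object of class \code{"recording"}: a list with elements
#'   \code{data}, \code{fs}, \code{channel_labels}, \code{subject_id},
#'   \code{condition_label}.
#' @export
recording <- function(data, fs, channel_labels = NULL,
                      subject_id = "", condition_label = "") {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L || ncol(data) < 1L)
    stop("'data' must be a numeric matrix with >= 1 channel and >= 1 sample")
  if (!all(is.finite(data))) stop("'data' contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number")
  if (is.null(channel_labels))
    channel_labels <- rownames(data) %||% paste0("ch", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("one channel label per row required")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 subject_id = subject_id, condition_label = condition_label),
            class = "recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (nzchar(x$subject_id))
    cat("  subject:", x$subject_id, " condition:", x$condition_label, "\n")
  invisible(x)
}

#' Drop channels from a recording
#'
#' Channel exclusion is always explicit (a list of labels or indices), never
#' auto-detected, so analyses are reproducible.
#'
#' @param rec a \code{\link{recording}}.
#' @param channels character labels or integer indices to drop.
#' @return the recording without the excluded channels.
#' @export
exclude_channels <- function(rec, channels) {
  stopifnot(inherits(rec, "recording"))
  if (length(channels) == 0L) return(rec)
  idx <- if (is.character(channels)) {
    miss <- setdiff(channels, rec$channel_labels)
    if (length(miss)) stop("unknown channel(s): ", paste(miss, collapse = ", "))
    match(channels, rec$channel_labels)
  } else as.integer(channels)
  if (length(idx) >= nrow(rec$data)) stop("cannot exclude every channel")
  recording(rec$data[-idx, , drop = FALSE], rec$fs,
            rec$channel_labels[-idx], rec$subject_id, rec$condition_label)
}

#' Read a recording from file
#'
#' Recognizes European Data Format (extension \code{.edf}) and delimited
#' numeric matrices (channels x samples, no header).  Delimited input needs
#' an explicit sampling rate; for EDF the header rate is used unless
#' overridden.
#'
#' @param path input file.
#' @param fs sampling rate in Hz; required for delimited input, overrides
#'   the header for EDF.
#' @param sep field separator for delimited input.
#' @return a \code{\link{recording}}.
#' @export
read_recording <- function(path, fs = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    rec <- read_edf(path)
    if (!is.null(fs)) rec$fs <- fs
    return(rec)
  }
  if (is.null(fs))
    stop("delimited input requires an explicit sampling rate 'fs'")
  m <- tryCatch(
    as.matrix(utils::read.table(path, sep = sep, header = FALSE)),
    error = function(e) stop("malformed delimited matrix in '", path,
                             "': ", conditionMessage(e)))
  if (!is.numeric(m)) stop("non-numeric entries in '", path, "'")
  recording(m, fs = fs)
}

#' Write a recording as a delimited matrix (channels x samples)
#'
#' @param rec a \code{\link{recording}}.
#' @param path output file.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "recording"))
  utils::write.table(rec$data, path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
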