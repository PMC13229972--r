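#' Number of complete non-overlapping windows
#'
#' \code{floor(T / L)}: only complete windows count; any trailing remainder
#' is discarded downstream.
#'
#' @param n_samples total number of samples (>= 0).
#' @param window_samples window length in samples (>= 1).
#' @return integer window count.
#' @examples
#' count_windows(90000, 1000)  # 180 s at 500 Hz, 2-s windows -> 90
#' @export
count_windows <- function(n_samples, window_samples) {
  if (window_samples < 1) stop("'window_samples' must be >= 1")
  if (n_samples < 0) stop("'n_samples' must be >= 0")
  as.integer(n_samples %/% window_samples)
}

#' Z-score every channel of a recording
#'
#' Each channel is centred and scaled to sample standard deviation 1 over
#' the full recording segment (i.e. per condition segment being analysed).
#'
#' @param rec a \code{\link{recording}}.
#' @return the z-scored recording.
#' @export
zscore_channels <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  sds <- apply(rec$data, 1, stats::sd)
  bad <- which(sds < .Machine$double.eps)
  if (length(bad))
    stop("constant channel(s) cannot be z-scored: ",
         paste(rec$channel_labels[bad], collapse = ", "))
  z <- (rec$data - rowMeans(rec$data)) / sds
  recording(z, rec$fs, rec$channel_labels, rec$subject_id, rec$condition_label)
}

#' Zero-phase alpha-band band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass, order 4 per pass,
#' applied channel-wise.  The default band is the EEG alpha band, 8-13 Hz.
#' Zero-phase filtering avoids phase distortion of the amplitude envelopes
#' whose temporal correlations are analysed downstream.
#'
#' @param rec a \code{\link{recording}}.
#' @param low,high band edges in Hz; \code{fs > 2 * high} is required.
#' @return the filtered recording.
#' @export
bandpass_alpha <- function(rec, low = 8, high = 13) {
  stopifnot(inherits(rec, "recording"))
  if (low >= high) stop("'low' must be below 'high'")
  if (rec$fs <= 2 * high)
    stop("sampling rate ", rec$fs, " Hz too low for a ", high, " Hz band edge")
  bf <- signal::butter(4, c(low, high) / (rec$fs / 2), type = "pass")
  filt <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  recording(filt, rec$fs, rec$channel_labels, rec$subject_id,
            rec$condition_label)
}

#' Band power of one window
#'
#' Integral of the one-sided power spectral density over \code{band}.  The
#' PSD is a modified periodogram of the whole window with a Hamming taper
#' (the single-segment form of Welch's estimate); band integration is
#' trapezoidal over the frequency bins falling inside the band, inclusive.
#'
#' @param x numeric vector, one window of one channel.
#' @param fs sampling rate in Hz.
#' @param band numeric length-2, band edges in Hz within \code{[0, fs/2]}.
#' @return nonnegative band power.
#' @examples
#' t <- seq(0, 2, by = 1/500)[-1]
#' band_power(sin(2*pi*10*t), 500)  # ~0.5 (unit sinusoid: power A^2/2)
#' @export
band_power <- function(x, fs, band = c(8, 13)) {
  n <- length(x)
  if (n == 0L) stop("empty window")
  if (band[1] < 0 || band[2] > fs / 2 || band[1] >= band[2])
    stop("'band' must lie inside [0, fs/2]")
  if (n < 2 * fs / (band[2] - band[1]))
    stop("window too short to resolve the band")
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))  # Hamming
  X <- stats::fft(x * w)
  nf <- n %/% 2 + 1L
  psd <- Mod(X[seq_len(nf)])^2 / (fs * sum(w^2))
  # one-sided: double the interior bins (not DC; not Nyquist when n even)
  last_double <- if (n %% 2 == 0) nf - 1L else nf
  if (last_double >= 2L) psd[2:last_double] <- 2 * psd[2:last_double]
  f <- (seq_len(nf) - 1L) * fs / n
  sel <- which(f >= band[1] & f <= band[2])
  if (length(sel) < 2L) return(sum(psd[sel]) * fs / n)
  sum(diff(f[sel]) * (psd[sel][-1] + psd[sel][-length(sel)]) / 2)
}

#' Windowed alpha-band power feature matrix
#'
#' Segments a (z-scored, band-passed) recording into non-overlapping
#' windows of \code{window_length_s} seconds and computes per-window,
#' per-channel band power.  Row i, column c is the band power of channel c
#' in window i.  A 2-s window gives 0.5 Hz frequency resolution, enough to
#' resolve the 8-13 Hz alpha band.
#'
#' The pipeline order is fixed: z-score, band-pass, window, band power (see
#' \code{\link{lrtc}}); this function does not re-check the first two steps.
#'
#' @param rec a \code{\link{recording}}.
#' @param window_length_s window length in seconds (default 2).
#' @param band band edges in Hz.
#' @return a numeric matrix of class \code{"feature_matrix"}, n windows x
#'   N channels, with attributes \code{window_length_s}, \code{band},
#'   \code{fs}; columns named by channel.
#' @export
build_feature_matrix <- function(rec, window_length_s = 2, band = c(8, 13)) {
  stopifnot(inherits(rec, "recording"))
  L <- as.integer(round(window_length_s * rec$fs))
  n <- count_windows(ncol(rec$data), L)
  if (n == 0L) stop("recording shorter than one window")
  nc <- nrow(rec$data)
  out <- matrix(0, n, nc, dimnames = list(NULL, rec$channel_labels))
  for (i in seq_len(n)) {
    cols <- ((i - 1L) * L + 1L):(i * L)
    for (c in seq_len(nc))
      out[i, c] <- band_power(rec$data[c, cols], rec$fs, band)
  }
  structure(out, window_length_s = window_length_s, band = band, fs = rec$fs,
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "Band-power feature matrix: %d windows x %d channels (%g-%g Hz, %g-s windows)\n",
    nrow(x), ncol(x), attr(x, "band")[1], attr(x, "band")[2],
    attr(x, "window_length_s")))
  invisible(x)
}

#' Write / read a feature matrix as delimited text
#'
#' Comma-separated with a header row of channel labels.
#'
#' @param X a feature matrix (or plain numeric matrix).
#' @param path file path.
#' @return \code{write_feature_matrix}: \code{path}, invisibly.
#'   \code{read_feature_matrix}: a numeric matrix.
#' @export
write_feature_matrix <- function(X, path) {
  utils::write.csv(as.data.frame(unclass(X)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as.matrix(utils::read.csv(path, check.names = FALSE))
}
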