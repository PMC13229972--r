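#' Theoretical autocovariance of fractional Gaussian noise
#'
#' Autocovariance of unit-variance fGn with Hurst exponent \code{hurst} at
#' integer lags: \eqn{\gamma(k) = \frac{1}{2}(|k+1|^{2H} - 2|k|^{2H} +
#' |k-1|^{2H})}.
#'
#' @param hurst Hurst exponent, in (0, 1).
#' @param lags integer vector of nonnegative lags.
#' @return numeric vector of autocovariances, same length as \code{lags}.
#' @export
fgn_autocovariance <- function(hurst, lags) {
  stopifnot(hurst > 0, hurst < 1, all(lags >= 0))
  h2 <- 2 * hurst
  0.5 * (abs(lags + 1)^h2 - 2 * abs(lags)^h2 + abs(lags - 1)^h2)
}

#' Generate fractional Gaussian noise by exact circulant embedding
#'
#' Draws a length-\code{n} sample of stationary, unit-variance fractional
#' Gaussian noise (the increment process of fractional Brownian motion) with
#' Hurst exponent \code{hurst}.  The target autocovariance is embedded in a
#' circulant matrix of order \code{2n - 2} whose eigenvalues are obtained by
#' FFT; a complex Gaussian vector is coloured in the spectral domain, so the
#' sample has exactly the fGn autocovariance (Davies-Harte construction).
#' If the embedding is not nonnegative definite (which does not occur for
#' the fGn covariance but is guarded against numerically), small negative
#' eigenvalues are clipped at zero, which is equivalent to approximate
#' spectral synthesis.
#'
#' fGn with Hurst exponent H has DFA scaling exponent alpha approximately H:
#' H = 0.5 is white noise, H in (0.5, 1) is persistent.  This makes the
#' generator the ground-truth oracle for the DFA estimator.
#'
#' @param hurst Hurst exponent, strictly in (0, 1).
#' @param n series length, at least 16.
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @return object of class \code{"fgn"}: numeric vector of length \code{n}
#'   with attributes \code{hurst} and \code{seed}.
#' @examples
#' x <- fgn(0.8, 1024, seed = 1)
#' var(x)      # ~1
#' @export
fgn <- function(hurst, n, seed = NULL) {
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1)
    stop("'hurst' must be a single number strictly inside (0, 1)")
  if (!is.numeric(n) || length(n) != 1L || n < 16)
    stop("'n' must be a single integer >= 16")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- fgn_autocovariance(hurst, 0:(n - 1L))
  # first row of the circulant embedding: gamma(0..n-1, n-2..1)
  r <- c(g, g[(n - 1L):2L])
  m <- length(r)
  lam <- Re(stats::fft(r))
  # the fGn embedding is nonnegative definite; clip round-off negatives
  lam[lam < 0] <- 0
  z <- stats::rnorm(m) + 1i * stats::rnorm(m)
  x <- Re(stats::fft(sqrt(lam / m) * z))[seq_len(n)]
  structure(x, hurst = hurst, seed = seed, class = "fgn")
}

#' @export
print.fgn <- function(x, ...) {
  cat(sprintf("Fractional Gaussian noise: n = %d, Hurst = %.3f\n",
              length(x), attr(x, "hurst")))
  invisible(x)
}
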