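#' Heuristic moving-block bootstrap block length
#'
#' \code{max(2, round(sqrt(n)))}: proportional to the square root of the
#' number of windows, rounded to the nearest integer, with a minimum of 2.
#'
#' @param n series length (>= 2).
#' @return integer block length.
#' @examples
#' block_length(90)  # 9
#' @export
block_length <- function(n) {
  if (n < 2) stop("'n' must be >= 2")
  max(2L, as.integer(round(sqrt(n))))
}

resample_rows <- function(n, L) {
  starts <- sample.int(n - L + 1L, ceiling(n / L), replace = TRUE)
  idx <- as.vector(outer(0:(L - 1L), starts, `+`))
  idx[seq_len(n)]
}

#' Moving-block bootstrap of the DFA scaling exponent
#'
#' Resamples contiguous blocks (length \code{\link{block_length}}) of the
#' windowed feature trajectory with replacement, recomputes DFA on each
#' resample, and summarizes the alpha distribution with a percentile 95\%
#' confidence interval.  By default the rows of the low-dimensional
#' embedding are resampled, preserving cross-dimension structure so both
#' DFA approaches apply to one resampling scheme; for a plain numeric
#' series the 1-D series itself is block-resampled.  A resample on which
#' DFA fails (e.g. a zero fluctuation) is redrawn, at most 10 times each.
#'
#' @param x an \code{"embedding"} or a numeric series (length >= 16).
#' @param approach DFA variant for embeddings: \code{"mean"} or
#'   \code{"norm"}.
#' @param n_resamples number of bootstrap resamples (>= 1); default 1000.
#' @param seed integer seed (required for reproducibility).
#' @param order DFA detrending order.
#' @param ci confidence level (default 0.95, percentile interval).
#' @return object of class \code{"dfa_boot"}: list with \code{alpha_mean},
#'   \code{ci_low}, \code{ci_high}, \code{alphas} (all resample estimates),
#'   \code{alpha_hat} (point estimate on the original data),
#'   \code{n_resamples}, \code{block_length}, \code{seed}.
#' @export
dfa_bootstrap <- function(x, approach = c("mean", "norm"),
                          n_resamples = 1000, seed = 1L, order = 1,
                          ci = 0.95) {
  approach <- match.arg(approach)
  is_emb <- inherits(x, "embedding")
  n <- if (is_emb) nrow(x$coords) else length(x)
  if (n < 16) stop("need at least 16 windows")
  if (n_resamples < 1) stop("'n_resamples' must be >= 1")
  L <- block_length(n)
  set.seed(as.integer(seed))

  point <- if (is_emb) dfa(x, order = order, approach = approach)
           else dfa(as.numeric(x), order = order)

  one <- function() {
    for (try in 1:10) {
      idx <- resample_rows(n, L)
      fit <- tryCatch({
        if (is_emb) {
          emb <- x; emb$coords <- x$coords[idx, , drop = FALSE]
          dfa(emb, order = order, approach = approach)
        } else dfa(as.numeric(x)[idx], order = order)
      }, error = function(e) NULL)
      if (!is.null(fit)) return(fit$alpha)
    }
    stop("a bootstrap resample failed DFA 10 times in a row")
  }
  alphas <- vapply(seq_len(n_resamples), function(i) one(), 0)
  qs <- stats::quantile(alphas, c((1 - ci) / 2, 1 - (1 - ci) / 2),
                        names = FALSE, type = 7)
  structure(list(alpha_mean = mean(alphas), ci_low = qs[1], ci_high = qs[2],
                 alphas = alphas, alpha_hat = point$alpha,
                 n_resamples = as.integer(n_resamples),
                 block_length = L, seed = as.integer(seed),
                 approach = point$approach, ci_level = ci),
            class = "dfa_boot")
}

#' @export
print.dfa_boot <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Moving-block bootstrap (%d resamples, block length %d, %s approach)\n",
    x$n_resamples, x$block_length, x$approach))
  cat(sprintf("  alpha = %.*f, bootstrap mean %.*f, %g%% CI [%.*f, %.*f]\n",
              digits, x$alpha_hat, digits, x$alpha_mean, 100 * x$ci_level,
              digits, x$ci_low, digits, x$ci_high))
  invisible(x)
}

#' @export
confint.dfa_boot <- function(object, parm = "alpha", level = NULL, ...) {
  if (!is.null(level) && level != object$ci_level)
    stop("interval was computed at level ", object$ci_level)
  m <- matrix(c(object$ci_low, object$ci_high), 1,
              dimnames = list("alpha", c("lower", "upper")))
  m
}
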