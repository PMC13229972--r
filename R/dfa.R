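#' Collapse an embedding to its Euclidean norm series
#'
#' Element i is the Euclidean norm of row i of the embedding coordinates;
#' for d = 1 this is the absolute value.
#'
#' @param Y an \code{"embedding"} or an n x d numeric matrix.
#' @return numeric vector of length n.
#' @export
norm_collapse <- function(Y) {
  if (inherits(Y, "embedding")) Y <- Y$coords
  Y <- as.matrix(Y)
  sqrt(rowSums(Y^2))
}

#' Mean-removed cumulative sum (DFA profile)
#'
#' \eqn{Z(k) = \sum_{i \le k} (y_i - \bar y)}; by construction
#' \eqn{Z(n) = 0}.
#'
#' @param y numeric vector, length >= 2.
#' @return the profile, same length as \code{y}.
#' @export
dfa_profile <- function(y) {
  if (length(y) < 2L) stop("need at least 2 samples")
  cumsum(y - mean(y))
}

# QR bases of the per-segment polynomial design are cached per (p, order):
# bootstrap and simulation loops re-detrend at the same scales thousands of
# times.
.qr_cache <- new.env(parent = emptyenv())

segment_basis <- function(p, order) {
  key <- paste0(p, ".", order)
  Q <- .qr_cache[[key]]
  if (is.null(Q)) {
    Q <- qr.Q(qr(outer(seq_len(p), 0:order, `^`)))
    .qr_cache[[key]] <- Q
  }
  Q
}

#' Root-mean-square fluctuation at one scale
#'
#' The profile is split into \code{floor(n/p)} non-overlapping segments of
#' length p from the start (the trailing remainder is excluded at that
#' scale); a least-squares polynomial of degree \code{order} is fitted per
#' segment and the RMS of the residuals over all covered samples is
#' returned.  With \code{both_ends = TRUE} the segmentation is repeated
#' from the end of the series and the two mean squares are averaged -- a
#' common variant, off by default.
#'
#' @param Z profile from \code{\link{dfa_profile}}.
#' @param p segment length (scale), \code{4 <= p <= floor(n/4)}.
#' @param order detrending polynomial degree (default 1, i.e. DFA-1).
#' @param both_ends also segment backwards from the end and average.
#' @return nonnegative RMS fluctuation F(p).
#' @export
fluctuation_at_scale <- function(Z, p, order = 1, both_ends = FALSE) {
  n <- length(Z)
  if (p < 4 || p > n %/% 4) stop("'p' must be in [4, floor(n/4)]")
  p <- as.integer(p)
  Q <- segment_basis(p, order)
  # explicit residuals (not the ||Z||^2 - ||Q'Z||^2 shortcut, which loses
  # precision exactly when the residual is near zero)
  msq <- function(z) {
    m <- (length(z) %/% p) * p
    Zm <- matrix(z[seq_len(m)], p)
    R <- Zm - Q %*% crossprod(Q, Zm)
    sum(R * R) / m
  }
  v <- msq(Z)
  if (both_ends) v <- (v + msq(rev(Z))) / 2
  sqrt(v)
}

#' Detrended fluctuation analysis
#'
#' Estimates the scaling exponent alpha of a series (or of a
#' low-dimensional embedding) from the power law \eqn{F(p) \propto
#' p^\alpha}: the profile (mean-removed cumulative sum) is locally
#' detrended in non-overlapping segments at every integer scale p in
#' \code{[4, floor(n/4)]}, and alpha is the ordinary-least-squares slope of
#' \eqn{\log_{10} F} on \eqn{\log_{10} p}, with goodness of fit R^2.
#' alpha = 0.5 indicates uncorrelated (white) noise, 0.5 < alpha < 1
#' persistent long-range temporal correlations; above 1 the power-law
#' regime is left.
#'
#' For an \code{"embedding"}, \code{approach = "norm"} analyses the
#' Euclidean norm of the coordinates (\code{\link{norm_collapse}}) and
#' \code{approach = "mean"} runs DFA on each dimension separately and
#' averages the exponents (and R^2) -- the more stable variant.
#'
#' @param x numeric series, or an \code{"embedding"}.
#' @param order detrending polynomial degree (DFA-n); default 1.
#' @param approach for embeddings: \code{"mean"} or \code{"norm"}.
#' @param scales optional integer vector of scales; default all integers in
#'   \code{[4, floor(n/4)]}.
#' @param both_ends see \code{\link{fluctuation_at_scale}}.
#' @param ... passed between methods.
#' @return object of class \code{"dfa"}: list with \code{alpha},
#'   \code{r_squared}, \code{scales}, \code{fluctuations}, \code{approach}
#'   (\code{"raw"}, \code{"norm"} or \code{"mean"}),
#'   \code{per_dimension_alphas} (mean-based only), \code{detrend_order},
#'   \code{n}, \code{intercept}, \code{short_series} flag.
#' @examples
#' set.seed(1)
#' fit <- dfa(rnorm(2048))
#' coef(fit)          # ~0.5 for white noise
#' @export
dfa <- function(x, ...) UseMethod("dfa")

#' @rdname dfa
#' @export
dfa.default <- function(x, order = 1, scales = NULL, both_ends = FALSE,
                        approach = "raw", ...) {
  y <- as.numeric(x)
  n <- length(y)
  if (n < 16) stop("series too short for DFA: need n >= 16, got ", n)
  if (is.null(scales)) scales <- 4:(n %/% 4)
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 2L)
    stop("need at least 2 scales to fit a slope (n >= 20)")
  Z <- dfa_profile(y)
  Fp <- vapply(scales, function(p)
    fluctuation_at_scale(Z, p, order, both_ends), 0)
  fit <- fit_scaling(scales, Fp)
  short <- length(scales) < 4L
  if (short)
    warning("fewer than 4 scales available; alpha estimate is unreliable")
  structure(list(alpha = fit$alpha,
                 r_squared = fit$r_squared,
                 scales = scales, fluctuations = Fp,
                 approach = approach,
                 per_dimension_alphas = NULL,
                 per_dimension_r_squared = NULL,
                 detrend_order = as.integer(order), n = n,
                 intercept = fit$intercept,
                 short_series = short),
            class = "dfa")
}

# OLS of log10 F on log10 p; slope is the scaling exponent, with the
# coefficient of determination of that line.  Base-10 logs: the slope and
# R^2 are base-invariant.
fit_scaling <- function(scales, fluctuations) {
  if (any(fluctuations == 0))
    stop("zero fluctuation at scale ",
         scales[which(fluctuations == 0)[1L]], "; log-log fit undefined")
  lp <- log10(scales); lf <- log10(fluctuations)
  fit <- stats::lm.fit(cbind(1, lp), lf)
  ss_tot <- sum((lf - mean(lf))^2)
  list(alpha = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       r_squared = if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1)
}

#' @rdname dfa
#' @export
dfa.embedding <- function(x, order = 1, approach = c("mean", "norm"),
                          scales = NULL, both_ends = FALSE, ...) {
  approach <- match.arg(approach)
  if (approach == "norm") {
    res <- dfa.default(norm_collapse(x), order = order, scales = scales,
                       both_ends = both_ends, approach = "norm")
    return(res)
  }
  fits <- lapply(seq_len(ncol(x$coords)), function(j)
    dfa.default(x$coords[, j], order = order, scales = scales,
                both_ends = both_ends, approach = "raw"))
  alphas <- vapply(fits, `[[`, 0, "alpha")
  r2s <- vapply(fits, `[[`, 0, "r_squared")
  res <- fits[[1L]]
  res$alpha <- mean(alphas)
  res$r_squared <- mean(r2s)
  # pooled fluctuation summary for plotting: RMS across dimensions
  res$fluctuations <- sqrt(Reduce(`+`, lapply(fits, function(f)
    f$fluctuations^2)) / length(fits))
  res$intercept <- NA_real_
  res$approach <- "mean"
  res$per_dimension_alphas <- alphas
  res$per_dimension_r_squared <- r2s
  res
}

#' @export
print.dfa <- function(x, digits = 3, ...) {
  cat(sprintf("DFA-%d (%s approach): alpha = %.*f, R^2 = %.*f\n",
              x$detrend_order, x$approach, digits, x$alpha, digits,
              x$r_squared))
  cat(sprintf("  n = %d, scales %d..%d (%d points)\n", x$n,
              min(x$scales), max(x$scales), length(x$scales)))
  if (!is.null(x$per_dimension_alphas))
    cat("  per-dimension alpha:",
        paste(sprintf("%.*f", digits, x$per_dimension_alphas),
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.dfa <- function(object, ...) {
  out <- c(alpha = object$alpha, r_squared = object$r_squared,
           n = object$n, n_scales = length(object$scales),
           detrend_order = object$detrend_order)
  cat("Detrended fluctuation analysis (", object$approach,
      " approach)\n\n", sep = "")
  print(round(out, 4))
  regime <- if (object$alpha > 1) "outside the power-law/LRTC regime"
            else if (object$alpha > 0.55) "persistent (LRTC)"
            else if (object$alpha >= 0.45) "uncorrelated (white-noise-like)"
            else "anti-persistent"
  cat("\nInterpretation: alpha =", round(object$alpha, 3), "->", regime, "\n")
  invisible(out)
}

#' @export
coef.dfa <- function(object, ...) c(alpha = object$alpha)

#' @export
predict.dfa <- function(object, scales = object$scales, ...) {
  if (is.na(object$intercept))
    stop("no single log-log fit for the mean-based approach; ",
         "predict per dimension instead")
  10^(object$intercept + object$alpha * log10(scales))
}

#' @export
residuals.dfa <- function(object, ...) {
  if (is.na(object$intercept))
    stop("no single log-log fit for the mean-based approach")
  log10(object$fluctuations) -
    (object$intercept + object$alpha * log10(object$scales))
}

#' @export
plot.dfa <- function(x, ...) {
  graphics::plot(log10(x$scales), log10(x$fluctuations),
                 xlab = "log10 scale p", ylab = "log10 F(p)",
                 main = sprintf("DFA: alpha = %.3f, R^2 = %.3f",
                                x$alpha, x$r_squared), ...)
  if (!is.na(x$intercept))
    graphics::abline(x$intercept, x$alpha, col = "red3")
  invisible(x)
}

#' Simulate surrogate series with the fitted scaling exponent
#'
#' Generates fractional-Gaussian-noise surrogates whose Hurst exponent
#' equals the fitted alpha (valid when alpha is inside (0, 1), the fGn
#' regime).
#'
#' @param object a \code{"dfa"} fit with alpha in (0, 1).
#' @param nsim number of surrogate series.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of \code{nsim} numeric vectors of length \code{object$n}.
#' @export
simulate.dfa <- function(object, nsim = 1, seed = NULL, ...) {
  a <- object$alpha
  if (a <= 0 || a >= 1)
    stop("surrogates via fGn require alpha inside (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) as.numeric(fgn(a, object$n)))
}
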