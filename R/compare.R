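#' Paired comparison of two scaling-exponent vectors
#'
#' Two-sided paired-samples t-test (df = n - 1), Bonferroni-corrected p
#' (\code{min(1, correction_factor * p)}), two-sided Wilcoxon signed-rank
#' test, and paired Cohen's d (mean of the differences divided by their
#' sample standard deviation, n - 1 denominator).  If every difference is
#' zero the t statistic is undefined; the report then carries t = 0, p = 1,
#' d = 0 and a \code{degenerate} flag.
#'
#' @param a,b numeric vectors of equal length (>= 2), paired by position.
#' @param correction_factor Bonferroni family size (default 4: two ragas x
#'   two conditions).
#' @param zero_policy Wilcoxon handling of zero differences:
#'   \code{"discard"} (classical signed-rank, the default) or
#'   \code{"pratt"} (rank with zeros included, then drop their ranks;
#'   normal approximation).
#' @return object of class \code{"paired_comparison"}: list with
#'   \code{t_stat}, \code{p_value}, \code{p_bonferroni}, \code{wilcoxon_p},
#'   \code{cohens_d}, \code{n_pairs}, \code{correction_factor},
#'   \code{degenerate}.
#' @examples
#' tabs <- alpha_tables()
#' paired_comparison(tabs$isomap$mean_yaman_during, tabs$pca$mean_yaman_during)
#' @export
paired_comparison <- function(a, b, correction_factor = 4,
                              zero_policy = c("discard", "pratt")) {
  zero_policy <- match.arg(zero_policy)
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  if (all(d == 0)) {
    res <- list(t_stat = 0, p_value = 1, p_bonferroni = 1, wilcoxon_p = 1,
                cohens_d = 0, n_pairs = n,
                correction_factor = as.integer(correction_factor),
                degenerate = TRUE)
    return(structure(res, class = "paired_comparison"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  cohens_d <- mean(d) / stats::sd(d)
  wp <- if (zero_policy == "discard") {
    suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))$p.value
  } else wilcoxon_pratt_p(d)
  structure(list(t_stat = unname(tt$statistic),
                 p_value = tt$p.value,
                 p_bonferroni = min(1, correction_factor * tt$p.value),
                 wilcoxon_p = wp,
                 cohens_d = cohens_d, n_pairs = n,
                 correction_factor = as.integer(correction_factor),
                 degenerate = FALSE),
            class = "paired_comparison")
}

# Pratt zero handling: rank |d| with zeros included, discard the zeros'
# ranks, normal approximation with tie/zero-corrected variance.
wilcoxon_pratt_p <- function(d) {
  r <- rank(abs(d))
  nz <- d != 0
  Wplus <- sum(r[nz][d[nz] > 0])
  n <- length(d)
  n0 <- sum(!nz)
  mu <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  ties <- table(r[nz])
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    n0 * (n0 + 1) * (2 * n0 + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- (Wplus - mu) / sqrt(sig2)
  2 * stats::pnorm(-abs(z))
}

#' @export
print.paired_comparison <- function(x, digits = 3, ...) {
  cat("Paired comparison, n =", x$n_pairs, "pairs\n")
  if (x$degenerate) cat("  all differences zero (degenerate)\n")
  cat(sprintf("  t = %.*f, p = %.*f, Bonferroni (x%d) p = %.*f\n",
              digits, x$t_stat, digits + 1, x$p_value, x$correction_factor,
              digits + 1, x$p_bonferroni))
  cat(sprintf("  Wilcoxon signed-rank p = %.*f\n", digits + 1, x$wilcoxon_p))
  cat(sprintf("  paired Cohen's d = %.*f\n", digits, x$cohens_d))
  invisible(x)
}

#' Printed per-subject scaling-exponent tables
#'
#' Loads the per-subject alpha tables shipped with the package: 13 subjects
#' by eight columns (approach x raga x condition) for the Isomap and the
#' PCA embedding.  Column names follow
#' \code{<approach>_<raga>_<condition>} with approach \code{norm}/\code{mean},
#' raga \code{yaman}/\code{pd} (Puriya Dhanashree) and condition
#' \code{during}/\code{after} (music vs relaxation).
#'
#' @return list with data frames \code{isomap} and \code{pca}.
#' @export
alpha_tables <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "isodfa", mustWork = TRUE))
  list(isomap = rd("isomap_alpha_by_subject.csv"),
       pca = rd("pca_alpha_by_subject.csv"))
}
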