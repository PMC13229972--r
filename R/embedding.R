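#' Pairwise Euclidean distances between time windows
#'
#' @param X numeric matrix, rows are observations (time windows).
#' @return symmetric n x n distance matrix with zero diagonal.
#' @export
pairwise_euclidean <- function(X) {
  X <- as.matrix(unclass(X))
  if (nrow(X) < 2L) stop("need at least 2 rows")
  as.matrix(stats::dist(X))
}

#' k-nearest-neighbour adjacency with OR symmetrization
#'
#' Edge (i, j) is present iff j is among the k nearest neighbours of i
#' \emph{or} i is among the k nearest neighbours of j; present edges carry
#' the Euclidean distance, absent ones \code{Inf}.  A point is never its
#' own neighbour.  Distance ties are broken by lowest index (stable order),
#' so the graph is deterministic.
#'
#' @param D symmetric distance matrix.
#' @param k neighbourhood size, \code{1 <= k <= n - 1}.
#' @return n x n matrix of class \code{"neighbor_graph"} with attribute
#'   \code{k}; finite entries are graph edges.
#' @export
knn_adjacency <- function(D, k) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k < 1 || k > n - 1) stop("'k' must be in [1, n-1]")
  k <- as.integer(k)
  W <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf                       # self excluded
    nb <- order(d)[seq_len(k)]        # stable: ties -> lowest index
    W[i, nb] <- D[i, nb]
  }
  W <- base::pmin(W, t(W))            # OR rule: keep edge if either found it
  diag(W) <- Inf
  structure(W, k = k, class = c("neighbor_graph", "matrix", "array"))
}

as_igraph <- function(W) {
  A <- ifelse(is.finite(unclass(W)), unclass(W), 0)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Smallest neighbourhood size giving a connected graph
#'
#' Starts at \eqn{k_0 = \lceil\sqrt{n}\rceil} and increments k by 1 until
#' the OR-symmetrized k-NN graph is connected; returns that smallest k.
#' The search is upward only; k = n - 1 always connects, so the loop
#' terminates.
#'
#' @param D symmetric distance matrix.
#' @return the selected integer k.
#' @export
select_k <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 points")
  k0 <- as.integer(ceiling(sqrt(n)))
  for (k in k0:(n - 1L)) {
    if (igraph::is_connected(as_igraph(knn_adjacency(D, k)))) return(k)
  }
  n - 1L
}

#' All-pairs geodesic (graph shortest-path) distances
#'
#' Dijkstra shortest paths over the finite edges of the neighbourhood
#' graph.  Errors on a disconnected graph, with the advice to raise k.
#'
#' @param W a \code{\link{knn_adjacency}} graph.
#' @return symmetric n x n matrix of geodesic distances.
#' @export
geodesic_distances <- function(W) {
  g <- as_igraph(W)
  G <- igraph::distances(g, algorithm = "dijkstra")
  if (any(!is.finite(G)))
    stop("neighbourhood graph is disconnected; raise k")
  dimnames(G) <- NULL
  G
}

# deterministic sign convention: largest-magnitude component positive
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Classical multidimensional scaling of a (geodesic) distance matrix
#'
#' Double-centres the squared distances, \eqn{B = -\frac{1}{2} H G^2 H}
#' with \eqn{H = I - \frac{1}{n}\mathbf{1}\mathbf{1}^\top}, symmetrizes B
#' against floating-point asymmetry, eigendecomposes it, and returns
#' coordinates \eqn{Y = V_d \Lambda_d^{1/2}} on the d largest eigenvalues.
#' Geodesic matrices are generally non-Euclidean, so some eigenvalues may
#' be negative: they are kept in the reported spectrum but excluded from
#' coordinates (and from explained-variance denominators).
#'
#' @param G symmetric nonnegative distance matrix (zero diagonal).
#' @param d embedding dimension, at most the number of positive eigenvalues.
#' @return an object of class \code{"embedding"}: list with \code{coords}
#'   (n x d), \code{eigenvalues} (full descending spectrum), \code{method},
#'   \code{k_used} (NA here), \code{d}.
#' @export
classical_mds <- function(G, d) {
  G <- as.matrix(G)
  n <- nrow(G)
  if (d < 1) stop("'d' must be >= 1")
  B <- -0.5 * scale(t(scale(t(G^2), scale = FALSE)), scale = FALSE)
  B <- (B + t(B)) / 2
  attr(B, "scaled:center") <- NULL
  eig <- eigen(B, symmetric = TRUE)
  lam <- eig$values
  pos <- which(lam > max(abs(lam)) * 1e-12)
  if (d > length(pos))
    stop("'d' exceeds the number of positive eigenvalues; maximum usable d is ",
         length(pos))
  V <- fix_signs(eig$vectors[, seq_len(d), drop = FALSE])
  Y <- V %*% diag(sqrt(lam[seq_len(d)]), d)
  new_embedding(Y, lam, method = "mds", k_used = NA_integer_, d = d)
}

new_embedding <- function(coords, eigenvalues, method, k_used, d,
                          extra = list()) {
  structure(c(list(coords = coords, eigenvalues = eigenvalues,
                   method = method, k_used = k_used, d = as.integer(d)),
              extra),
            class = "embedding")
}

#' Isomap embedding of a feature matrix
#'
#' The three Isomap steps: (i) OR-symmetrized k-NN graph on pairwise
#' Euclidean distances, with k chosen adaptively as the smallest value at
#' or above \eqn{\lceil\sqrt{n}\rceil} that connects the graph; (ii)
#' geodesic distances by Dijkstra shortest paths; (iii) classical MDS of
#' the geodesic matrix.
#'
#' @param X feature matrix (n windows x N channels) or any numeric matrix
#'   of observations in rows.
#' @param d embedding dimension, or \code{"auto"} to use
#'   \code{\link{elbow_dimension}} on the MDS eigenvalue spectrum.
#' @param k neighbourhood size, or \code{"auto"} for \code{\link{select_k}}.
#' @return an \code{"embedding"} (see \code{\link{classical_mds}}) with
#'   \code{method = "isomap"} and \code{k_used} set.
#' @examples
#' X <- matrix(rnorm(200), 50, 4)
#' emb <- isomap_embed(X, d = 2)
#' @export
isomap_embed <- function(X, d = "auto", k = "auto") {
  D <- pairwise_euclidean(X)
  k_used <- if (identical(k, "auto")) select_k(D) else as.integer(k)
  G <- geodesic_distances(knn_adjacency(D, k_used))
  full <- classical_mds(G, d = 1L)      # spectrum first, then pick d
  d_used <- if (identical(d, "auto")) elbow_dimension(full$eigenvalues)
            else as.integer(d)
  emb <- classical_mds(G, d = d_used)
  emb$method <- "isomap"
  emb$k_used <- k_used
  emb
}

#' PCA embedding of a feature matrix
#'
#' Principal component analysis on the covariance of the column-centred
#' (not standardized) feature matrix; scores on the top d components.  The
#' eigenvalue spectrum (component variances) is returned in full.
#'
#' @param X numeric matrix, observations in rows.
#' @param d embedding dimension, or \code{"auto"} for the elbow rule.
#' @return an \code{"embedding"} with \code{method = "pca"}.
#' @export
pca_embed <- function(X, d = "auto") {
  X <- as.matrix(unclass(X))
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  lam <- p$sdev^2
  d_used <- if (identical(d, "auto")) elbow_dimension(lam) else as.integer(d)
  if (d_used > ncol(X)) stop("'d' exceeds the number of channels")
  rot <- fix_signs(p$rotation[, seq_len(d_used), drop = FALSE])
  Y <- scale(X, center = p$center, scale = FALSE) %*% rot
  new_embedding(unname(Y), lam, method = "pca", k_used = NA_integer_,
                d = d_used)
}

#' Elbow of a descending eigenvalue spectrum
#'
#' Automates the visual elbow rule: the spectrum is max-normalized
#' (positive part), log10-transformed, and the discrete curvature (central
#' second difference) is evaluated at indices 2..min(10, len - 1); the
#' elbow is the index just before the curvature maximum -- the last
#' dimension before the spectrum flattens.  A strictly geometric decay has
#' zero curvature everywhere on the log scale; if the maximum curvature is
#' below \code{floor} the result falls back to \code{default_d} and carries
#' the attribute \code{no_clear_elbow = TRUE}.
#'
#' @param eigenvalues numeric vector, descending; at least 3 values.
#' @param default_d fallback dimension when no clear elbow exists.
#' @param floor minimum log10 curvature regarded as a real elbow.
#' @return integer dimension, possibly with attribute \code{no_clear_elbow}.
#' @examples
#' elbow_dimension(c(10, 5, 2, 0.50, 0.45, 0.40))  # 3
#' elbow_dimension(c(10, 0.1, 0.09, 0.08))         # 1
#' @export
elbow_dimension <- function(eigenvalues, default_d = 3L, floor = 0.1) {
  lam <- eigenvalues[eigenvalues > 0]
  if (length(lam) < 3L) stop("need at least 3 positive eigenvalues")
  s <- log10(lam / lam[1L])
  hi <- min(10L, length(s) - 1L)
  j <- 2:hi
  curv <- s[j - 1L] - 2 * s[j] + s[j + 1L]
  if (max(curv) < floor) {
    res <- as.integer(default_d)
    attr(res, "no_clear_elbow") <- TRUE
    return(res)
  }
  as.integer(j[which.max(curv)] - 1L)
}

#' Trustworthiness of an embedding
#'
#' Rank-based neighbourhood-preservation score in [0, 1].  For each point,
#' embedding-space neighbours (among the \code{k_t} nearest) that were not
#' original-space neighbours are penalized by how far down the original
#' ranking they sit:
#' \deqn{T = 1 - \frac{2}{n k (2n - 3k - 1)} \sum_i \sum_{j \in U_k(i)}
#'   (r(i,j) - k).}
#'
#' @param X original data matrix (n x N).
#' @param Y embedded coordinates (n x d) or an \code{"embedding"}.
#' @param k_t neighbourhood size, \code{k_t < n / 2}.
#' @return trustworthiness in [0, 1].
#' @export
trustworthiness <- function(X, Y, k_t = 5) {
  if (inherits(Y, "embedding")) Y <- Y$coords
  X <- as.matrix(unclass(X))
  n <- nrow(X)
  k <- as.integer(k_t)
  if (k >= n / 2) stop("'k_t' must be below n/2")
  DX <- pairwise_euclidean(X)
  DY <- pairwise_euclidean(Y)
  total <- 0
  for (i in seq_len(n)) {
    ox <- order(DX[i, -i])                  # ranks among the other points
    rank_x <- integer(n - 1L); rank_x[ox] <- seq_len(n - 1L)
    nx <- which(rank_x <= k)                # original-space neighbours
    oy <- order(DY[i, -i])
    ny <- oy[seq_len(k)]                    # embedding-space neighbours
    u <- setdiff(ny, nx)
    total <- total + sum(rank_x[u] - k)
  }
  1 - 2 * total / (n * k * (2 * n - 3 * k - 1))
}

#' Cumulative explained variance of the leading dimensions
#'
#' \code{100 * sum(lambda[1:d]) / sum(lambda[lambda > 0])}; negative
#' eigenvalues (possible for geodesic MDS) are excluded from the
#' denominator.
#'
#' @param eigenvalues descending numeric vector.
#' @param d number of leading dimensions (>= 1).
#' @return percentage in [0, 100].
#' @export
explained_variance <- function(eigenvalues, d) {
  if (d < 1) stop("'d' must be >= 1")
  pos <- eigenvalues[eigenvalues > 0]
  if (!length(pos)) stop("no positive eigenvalues")
  d <- min(as.integer(d), length(pos))
  100 * sum(pos[seq_len(d)]) / sum(pos)
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("%s embedding: n = %d, d = %d%s\n",
              toupper(x$method), nrow(x$coords), x$d,
              if (!is.na(x$k_used)) sprintf(", k = %d", x$k_used) else ""))
  cat(sprintf("  explained variance (top %d): %.1f%%\n", x$d,
              explained_variance(x$eigenvalues, x$d)))
  invisible(x)
}

#' @export
plot.embedding <- function(x, which = c("coords", "spectrum"), ...) {
  which <- match.arg(which)
  if (which == "spectrum" || x$d < 2L) {
    lam <- x$eigenvalues[x$eigenvalues > 0]
    graphics::plot(seq_along(lam), lam, type = "b", xlab = "dimension",
                   ylab = "eigenvalue", main = "Eigenvalue spectrum", ...)
    graphics::abline(v = x$d, lty = 2)
  } else {
    graphics::plot(x$coords[, 1], x$coords[, 2], xlab = "dim 1",
                   ylab = "dim 2",
                   main = sprintf("%s embedding", toupper(x$method)), ...)
  }
  invisible(x)
}
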