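test_that("pairwise Euclidean distances are exact, symmetric, zero-diagonal", {
  D <- pairwise_euclidean(rbind(c(0, 0), c(3, 4), c(3, 4)))
  expect_equal(D[1, 2], 5)
  expect_equal(D[2, 3], 0)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_error(pairwise_euclidean(matrix(1, 1, 3)), "2 rows")
})

test_that("k-NN adjacency applies the OR rule with ties broken by index", {
  D <- pairwise_euclidean(matrix(c(0, 1, 3)))
  W <- knn_adjacency(D, 1)
  expect_true(is.finite(W[1, 2]) && is.finite(W[2, 1]))  # 0-1
  expect_true(is.finite(W[2, 3]) && is.finite(W[3, 2]))  # 1-3 via OR
  expect_false(is.finite(W[1, 3]))
  expect_equal(is.finite(W), t(is.finite(W)))
  # complete graph at k = n-1
  set.seed(1)
  D2 <- pairwise_euclidean(matrix(rnorm(20), 10, 2))
  W2 <- knn_adjacency(D2, 9)
  expect_true(all(is.finite(W2[upper.tri(W2)])))
  expect_error(knn_adjacency(D2, 10), "k")
})

test_that("select_k starts at ceil(sqrt(n)) and returns the minimal
           connecting k", {
  set.seed(42)
  D <- pairwise_euclidean(matrix(rnorm(180), 90, 2))
  k <- select_k(D)
  expect_identical(k, 10L)  # dense cloud already connected at k0 = 10

  # 4 mutually close points: k0 = 2 connects
  D4 <- pairwise_euclidean(matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2,
                                  byrow = TRUE))
  expect_identical(select_k(D4), 2L)

  # two tight, well-separated clusters: need k above k0, and k-1 must not
  # connect (brute-force scan over k confirms minimality)
  set.seed(7)
  n_half <- 18
  X <- rbind(matrix(rnorm(2 * n_half, sd = 0.05), ncol = 2),
             matrix(rnorm(2 * n_half, sd = 0.05) + 50, ncol = 2))
  Dc <- pairwise_euclidean(X)
  ks <- select_k(Dc)
  k0 <- ceiling(sqrt(nrow(X)))
  expect_gt(ks, k0)
  connected <- function(k)
    igraph::is_connected(igraph::graph_from_adjacency_matrix(
      ifelse(is.finite(unclass(knn_adjacency(Dc, k))), 1, 0),
      mode = "undirected"))
  expect_true(connected(ks))
  expect_false(connected(ks - 1))
})

test_that("geodesic distances equal brute-force shortest paths and dominate
           Euclidean distances", {
  # path graph a-b-c with unit weights
  Dp <- pairwise_euclidean(matrix(c(0, 1, 2)))
  G <- geodesic_distances(knn_adjacency(Dp, 1))
  expect_equal(G[1, 3], 2)

  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  D <- pairwise_euclidean(X)
  W <- knn_adjacency(D, 4)
  G2 <- geodesic_distances(W)
  expect_equal(G2, naive_shortest_paths(W), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(G2 - D >= -1e-12))
  # complete graph: geodesics are the direct edges
  expect_equal(geodesic_distances(knn_adjacency(D, 19)), D,
               tolerance = 1e-12, ignore_attr = TRUE)
  # disconnected graph errors with advice
  W2 <- knn_adjacency(D, 2)
  W2[1:10, 11:20] <- Inf; W2[11:20, 1:10] <- Inf
  expect_error(geodesic_distances(W2), "raise k")
})

test_that("classical MDS reproduces Euclidean configurations exactly", {
  # collinear points, d = 1
  G <- pairwise_euclidean(matrix(c(0, 1, 3, 7)))
  emb <- classical_mds(G, 1)
  expect_equal(pairwise_euclidean(emb$coords), G, tolerance = 1e-8)

  # full-rank configuration, d = rank
  set.seed(9)
  X <- matrix(rnorm(80), 20, 4)
  G2 <- pairwise_euclidean(X)
  emb2 <- classical_mds(G2, 4)
  expect_equal(pairwise_euclidean(emb2$coords), G2, tolerance = 1e-6)

  # agreement with the established reference implementation
  ref <- stats::cmdscale(G2, k = 4)
  for (j in 1:4)
    expect_lt(min(max(abs(emb2$coords[, j] - ref[, j])),
                  max(abs(emb2$coords[, j] + ref[, j]))), 1e-6)

  # coordinate column norms match the eigenvalues (Y = V Lambda^(1/2))
  expect_equal(colSums(emb2$coords^2), emb2$eigenvalues[1:4],
               tolerance = 1e-8)
  expect_error(classical_mds(G2, 25), "maximum usable")
})

test_that("isomap coordinates agree with vegan's reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(5)
  X <- matrix(rnorm(120), 40, 3)
  k <- 6
  emb <- isomap_embed(X, d = 3, k = k)
  ref <- vegan::isomap(stats::dist(X), ndim = 3, k = k)$points
  for (j in 1:3)
    expect_lt(min(max(abs(emb$coords[, j] - ref[, j])),
                  max(abs(emb$coords[, j] + ref[, j]))), 1e-6)
})

test_that("PCA embedding centres scores, reports the spectrum, and is
           rotation-invariant", {
  set.seed(2)
  # data on a 2-D plane inside 10-D
  B <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:2]
  X <- matrix(rnorm(120), 60, 2) %*% t(B)
  emb <- pca_embed(X, d = 2)
  expect_equal(explained_variance(emb$eigenvalues, 2), 100, tolerance = 1e-8)
  expect_lt(max(abs(colMeans(emb$coords))), 1e-10)
  # spectrum invariant under orthonormal rotation of input columns
  R <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
  emb_rot <- pca_embed(X %*% B %*% R, d = 2)  # rotate in the 2-D plane
  expect_equal(emb$eigenvalues[1:2], emb_rot$eigenvalues[1:2],
               tolerance = 1e-8)
  expect_error(pca_embed(X, d = 11), "channels")
})

test_that("elbow selection matches hand-computed curvature and flags
           geometric decay", {
  expect_identical(elbow_dimension(c(10, 5, 2, 0.50, 0.45, 0.40)), 3L)
  expect_identical(elbow_dimension(c(10, 0.1, 0.09, 0.08)), 1L)
  geom <- 10 * 0.5^(0:9)
  res <- elbow_dimension(geom, default_d = 4L)
  expect_identical(as.integer(res), 4L)
  expect_true(isTRUE(attr(res, "no_clear_elbow")))
  expect_error(elbow_dimension(c(2, 1)), "at least 3")
})

test_that("trustworthiness is 1 for the identity embedding, below it for a
           row permutation, and always in [0, 1]", {
  set.seed(4)
  X <- matrix(rnorm(40 * 5), 40, 5)
  expect_equal(trustworthiness(X, X, 5), 1)
  worse <- 0
  for (s in 1:20) {
    set.seed(s)
    tp <- trustworthiness(X, X[sample(40), ], 5)
    expect_gte(tp, 0); expect_lte(tp, 1)
    worse <- worse + tp
  }
  expect_lt(worse / 20, 1)
  expect_error(trustworthiness(X, X, 20), "k_t")
})

test_that("explained variance handles negative eigenvalues by exclusion", {
  expect_equal(explained_variance(c(3, 1), 1), 75)
  expect_equal(explained_variance(c(3, 1), 2), 100)
  expect_equal(explained_variance(c(3, 1, -0.5), 1),
               explained_variance(c(3, 1, -50), 1))
  expect_error(explained_variance(c(-1, -2), 1), "positive")
})

test_that("isomap preserves a curved manifold better than PCA at equal d", {
  sr <- swiss_roll(300, seed = 8)
  D_true <- pairwise_euclidean(sr$intrinsic)
  # small fixed k: neighbourhoods must stay on the sheet, not jump layers
  emb_i <- isomap_embed(sr$X, d = 2, k = 7)
  emb_p <- pca_embed(sr$X, d = 2)
  distortion <- function(Y)
    1 - stats::cor(as.vector(pairwise_euclidean(Y)), as.vector(D_true))^2
  expect_lt(distortion(emb_i$coords), distortion(emb_p$coords))
})
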