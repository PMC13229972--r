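# Independent brute-force oracles used to validate the implementation.
# These are deliberately naive (explicit loops, lm() per segment,
# Floyd-Warshall) and share no code with the package internals.

# naive DFA: explicit segment loop, lm() polynomial fit per segment
naive_dfa <- function(y, order = 1) {
  n <- length(y)
  Z <- cumsum(y - mean(y))
  ps <- 4:(n %/% 4)
  Fp <- sapply(ps, function(p) {
    nseg <- n %/% p
    res2 <- 0
    for (s in seq_len(nseg)) {
      idx <- ((s - 1) * p + 1):(s * p)
      fit <- stats::lm(Z[idx] ~ stats::poly(seq_len(p), order, raw = TRUE))
      res2 <- res2 + sum(stats::resid(fit)^2)
    }
    sqrt(res2 / (nseg * p))
  })
  co <- stats::coef(stats::lm(log10(Fp) ~ log10(ps)))
  list(alpha = unname(co[2]), scales = ps, fluctuations = Fp)
}

# all-pairs shortest paths by Floyd-Warshall on a finite/Inf weight matrix
naive_shortest_paths <- function(W) {
  G <- matrix(as.numeric(W), nrow(W))
  diag(G) <- 0
  n <- nrow(G)
  for (k in seq_len(n))
    for (i in seq_len(n))
      G[i, ] <- pmin(G[i, ], G[i, k] + G[k, ])
  G
}

# white-noise embedding with iid standard normal coordinates
white_embedding <- function(n, d) {
  structure(list(coords = matrix(stats::rnorm(n * d), n, d),
                 eigenvalues = rep(1, d), method = "pca",
                 k_used = NA_integer_, d = as.integer(d)),
            class = "embedding")
}

# swiss-roll-style curved 2-manifold in 3-D with its intrinsic coordinates
swiss_roll <- function(n, seed) {
  set.seed(seed)
  t <- sort(stats::runif(n, 1.5 * pi, 4.5 * pi))
  h <- stats::runif(n, 0, 10)
  # arc length of the spiral r = t: integral of sqrt(1 + t^2)
  arc <- sapply(t, function(u)
    stats::integrate(function(s) sqrt(1 + s^2), 1.5 * pi, u)$value)
  list(X = cbind(t * cos(t), h, t * sin(t)), intrinsic = cbind(arc, h))
}
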