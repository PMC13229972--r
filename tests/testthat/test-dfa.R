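test_that("norm collapse and profile follow their definitions", {
  expect_equal(norm_collapse(rbind(c(3, 4), c(0, 0))), c(5, 0))
  expect_equal(norm_collapse(matrix(c(-2, 1))), c(2, 1))  # d = 1: |y|
  expect_equal(dfa_profile(c(1, 2, 3)), c(-1, -1, 0))
  expect_true(all(dfa_profile(rep(4, 10)) == 0))
  set.seed(1)
  y <- rnorm(100)
  expect_lt(abs(dfa_profile(y)[100]), 1e-10)
  expect_error(dfa_profile(1), "2 samples")
})

test_that("fluctuation at a scale matches a brute-force per-segment fit", {
  set.seed(6)
  Z <- cumsum(rnorm(16))
  # independent oracle: explicit lm per segment
  naive <- sqrt(mean(unlist(lapply(split(Z, rep(1:4, each = 4)), function(z)
    stats::resid(stats::lm(z ~ seq_along(z)))^2))))
  expect_equal(fluctuation_at_scale(Z, 4), naive, tolerance = 1e-10)

  # linear profile: order-1 detrending removes it entirely
  expect_lt(fluctuation_at_scale(3 + 2 * (1:64), 8), 1e-10)
  # constant offsets are absorbed by the fit
  set.seed(2)
  Z2 <- cumsum(rnorm(64))
  expect_equal(fluctuation_at_scale(Z2, 8),
               fluctuation_at_scale(Z2 + 100, 8), tolerance = 1e-10)
  expect_error(fluctuation_at_scale(Z2, 3), "p")
  expect_error(fluctuation_at_scale(Z2, 17), "p")
})

test_that("dfa equals the naive reference implementation on small series", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(64:256, 1)
    y <- rnorm(n)
    fit <- dfa(y)
    ref <- naive_dfa(y)
    expect_equal(fit$scales, ref$scales)
    expect_equal(fit$fluctuations, ref$fluctuations, tolerance = 1e-10)
    expect_equal(fit$alpha, ref$alpha, tolerance = 1e-10)
  }
})

test_that("an exact power law in the fitting step returns its exponent", {
  ps <- 4:40
  fit <- isodfa:::fit_scaling(ps, 2 * ps^0.7)
  expect_equal(fit$alpha, 0.7, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("alpha is invariant to positive rescaling of the series", {
  set.seed(10)
  y <- rnorm(300)
  expect_equal(dfa(y)$alpha, dfa(7.3 * y)$alpha, tolerance = 1e-10)
})

test_that("dfa rejects degenerate inputs", {
  expect_error(dfa(rnorm(10)), "n >= 16")
  expect_error(dfa(rep(1, 100)), "zero fluctuation at scale")
})

test_that("white noise scales at ~0.5 and persistent fgn at ~H", {
  a_white <- mean(sapply(1:20, function(s) { set.seed(s)
    dfa(rnorm(1e4))$alpha }))
  expect_gt(a_white, 0.47); expect_lt(a_white, 0.53)
  a_pers <- mean(sapply(1:20, function(s)
    dfa(as.numeric(fgn(0.8, 2^14, s)))$alpha))
  expect_gt(a_pers, 0.75); expect_lt(a_pers, 0.85)
})

test_that("F(p) is nondecreasing in p for persistent fgn in >= 95% of seeds", {
  # dyadic scales: every F(p) then averages >= 4 segments, so the growth of
  # the fluctuation function is not masked by single-segment noise
  ok <- sapply(1:40, function(s) {
    f <- dfa(as.numeric(fgn(0.8, 512, s)), scales = c(4, 8, 16, 32, 64, 128))
    all(diff(f$fluctuations) >= 0)
  })
  expect_gte(mean(ok), 0.95)
})

test_that("mean-based DFA averages per-dimension exponents", {
  set.seed(20)
  y <- rnorm(200)
  same <- white_embedding(200, 3)
  same$coords <- cbind(y, y, y)
  fit <- dfa(same, approach = "mean")
  expect_equal(fit$alpha, dfa(y)$alpha, tolerance = 1e-12)
  expect_equal(fit$per_dimension_alphas, rep(dfa(y)$alpha, 3),
               tolerance = 1e-12)

  set.seed(21)
  emb <- white_embedding(200, 2)
  fit2 <- dfa(emb, approach = "mean")
  expect_equal(fit2$alpha,
               mean(c(dfa(emb$coords[, 1])$alpha,
                      dfa(emb$coords[, 2])$alpha)), tolerance = 1e-12)
  expect_equal(fit2$r_squared,
               mean(fit2$per_dimension_r_squared), tolerance = 1e-12)
})

test_that("mean-based alpha is at least as stable as norm-based alpha on
           white-noise embeddings", {
  res <- sapply(1:100, function(s) {
    set.seed(s)
    emb <- white_embedding(90, 3)
    c(mean = dfa(emb, approach = "mean")$alpha,
      norm = dfa(emb, approach = "norm")$alpha)
  })
  expect_lte(stats::sd(res["mean", ]), stats::sd(res["norm", ]))
  # centred near the white-noise value (small-n DFA has a mild upward bias)
  expect_lt(abs(mean(res["mean", ]) - 0.5), 0.1)
})

test_that("dfa methods expose coefficients, fitted line and surrogates", {
  set.seed(30)
  fit <- dfa(rnorm(500))
  expect_named(coef(fit), "alpha")
  expect_equal(predict(fit)[1], 10^(fit$intercept +
                                    fit$alpha * log10(fit$scales[1])))
  expect_equal(length(residuals(fit)), length(fit$scales))
  surr <- simulate(fit, nsim = 2, seed = 1)
  expect_length(surr, 2)
  expect_length(surr[[1]], fit$n)
  expect_output(print(fit), "alpha")
  expect_output(summary(fit), "Interpretation")
})
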