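make_rec <- function(nch = 3, n = 4000, fs = 500, seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(nch * n), nch, n), fs = fs)
}

test_that("count_windows floors and rejects bad window lengths", {
  expect_identical(count_windows(90000, 1000), 90L)  # 180 s at 500 Hz, 2 s
  expect_identical(count_windows(999, 1000), 0L)
  expect_identical(count_windows(2500, 1000), 2L)
  expect_error(count_windows(100, 0))
})

test_that("z-scoring gives zero mean, unit SD, is idempotent, and rejects
           constant channels", {
  rec <- make_rec()
  z <- zscore_channels(rec)
  expect_lt(max(abs(rowMeans(z$data))), 1e-10)
  expect_lt(max(abs(apply(z$data, 1, sd) - 1)), 1e-10)
  z2 <- zscore_channels(z)
  expect_lt(max(abs(z2$data - z$data)), 1e-10)
  bad <- recording(rbind(rnorm(100), rep(2, 100)), 100,
                   channel_labels = c("good", "flat"))
  expect_error(zscore_channels(bad), "flat")
})

test_that("alpha band-pass keeps a 10 Hz tone and rejects a 2 Hz tone", {
  fs <- 500
  t <- seq(1 / fs, 8, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))
  in_band <- recording(matrix(sin(2 * pi * 10 * t), 1), fs)
  out_band <- recording(matrix(sin(2 * pi * 2 * t), 1), fs)
  expect_gt(rms(bandpass_alpha(in_band)$data), 0.9 / sqrt(2))
  expect_lt(rms(bandpass_alpha(out_band)$data), 0.1 / sqrt(2))
  # linearity: all-zero input stays zero, doubling input doubles output
  zf <- bandpass_alpha(recording(matrix(0, 2, 1000), fs))
  expect_true(all(zf$data == 0))
  x <- matrix(rnorm(2000), 2)
  f1 <- bandpass_alpha(recording(x, fs))$data
  f2 <- bandpass_alpha(recording(2 * x, fs))$data
  expect_equal(f2, 2 * f1, tolerance = 1e-10)
  expect_error(bandpass_alpha(recording(x, 20)), "too low")
  expect_error(bandpass_alpha(recording(x, fs), low = 13, high = 8))
})

test_that("band power integrates a sinusoid to A^2/2 and is band-selective", {
  fs <- 500
  t <- seq(1 / fs, 2, by = 1 / fs)
  expect_equal(band_power(sin(2 * pi * 10 * t), fs), 0.5, tolerance = 0.1)
  expect_lt(band_power(sin(2 * pi * 20 * t), fs), 0.01)
  expect_equal(band_power(numeric(1000), fs), 0)
  expect_error(band_power(numeric(0), fs), "empty")
  expect_error(band_power(t, fs, band = c(8, 400)), "band")
})

test_that("feature matrix has the contracted shape and nonnegative entries", {
  rec <- make_rec(nch = 4, n = 180 * 500, fs = 500)
  X <- build_feature_matrix(rec, 2)
  expect_equal(dim(X), c(90L, 4L))
  expect_true(all(X >= 0))
  expect_error(build_feature_matrix(make_rec(n = 500), 2), "shorter")
})

test_that("trailing samples short of a full window do not change features", {
  rec <- make_rec(nch = 2, n = 5000, fs = 500)
  X1 <- build_feature_matrix(rec, 2)
  padded <- recording(cbind(rec$data, matrix(rnorm(2 * 999), 2)), 500)
  X2 <- build_feature_matrix(padded, 2)
  expect_equal(unclass(X1), unclass(X2), ignore_attr = TRUE)
})

test_that("pipeline order matters: z-score then band-pass differs from the
           reverse (golden check, fixed seed)", {
  rec <- make_rec(nch = 2, n = 4000, fs = 500, seed = 11)
  a <- build_feature_matrix(bandpass_alpha(zscore_channels(rec)), 2)
  b <- build_feature_matrix(zscore_channels(bandpass_alpha(rec)), 2)
  expect_gt(max(abs(a - b)), 1e-8)
})

test_that("a 2-s window yields 0.5 Hz frequency resolution", {
  fs <- 500
  n <- 2 * fs
  expect_equal(fs / n, 0.5)
})
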