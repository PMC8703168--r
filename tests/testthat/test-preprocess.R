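test_that("denoising preserves length and passes smooth signals through", {
  x <- rep(5, 128)
  for (ord in c(3L, 6L, 10L)) {
    for (lev in c(3L, 5L)) {
      out <- wavelet_denoise(x, wavelet_params(ord, lev))
      expect_length(out, 128L)
      expect_equal(out, x, tolerance = 1e-8)
    }
  }
  # odd lengths reconstruct at the right length too
  expect_length(wavelet_denoise(rnorm(101), wavelet_params(4, 3)), 101L)
  expect_error(wavelet_denoise(rnorm(7), wavelet_params(4, 3)), "too short")
  expect_error(wavelet_params(2, 3), "\\[3, 10\\]")
  expect_error(wavelet_params(4, 11), "\\[3, 10\\]")
})

test_that("denoising a noisy peak removes most of the injected noise", {
  lambda <- seq_len(512)
  clean <- 100 * exp(-(lambda - 256)^2 / (2 * 15^2))
  set.seed(42)
  noise <- rnorm(512, 0, 4)
  den <- wavelet_denoise(clean + noise, wavelet_params(4, 3))
  expect_lt(sd(den - clean), sd(noise))
  # most of the noise energy should be gone, not just a sliver
  expect_lt(sd(den - clean), 0.5 * sd(noise))
})

test_that("snr follows its peak-over-residual definition", {
  den <- c(rep(0, 9), 10)           # peak height 10
  res <- rep(c(-1, 1), 5)           # residual sd known
  expect_equal(snr(den + res, den), 10 / sd(res))
  # halving the residual doubles the ratio at fixed peak height
  expect_equal(snr(den + res / 2, den), 2 * snr(den + res, den))
  expect_error(snr(den, den), "residual is zero")
  expect_error(snr(1:3, 1:4), "equal length")
})

test_that("wavelet search is an exhaustive argmax with lexicographic ties", {
  set.seed(7)
  clean <- 50 * exp(-(seq_len(256) - 128)^2 / (2 * 10^2))
  mat <- t(replicate(4, clean + rnorm(256, 0, 3)))
  ds <- spectrum_set(mat, data.frame(origin = 1L, plant_id = "p",
                                     tablet_id = "t", part = "underground",
                                     position = 1:4),
                     seq(229, 878, length.out = 256))
  orders <- 3:5; levels <- 3:4
  got <- optimize_wavelet(ds, orders, levels)

  # independent oracle: evaluate the full grid directly
  best <- NULL; best_val <- -Inf
  for (o in orders) for (l in levels) {
    val <- mean(apply(mat, 1, function(x) {
      d <- wavelet_denoise(x, wavelet_params(o, l))
      tryCatch(snr(x, d), error = function(e) Inf)
    }))
    if (val > best_val + 1e-12) { best_val <- val; best <- c(o, l) }
  }
  expect_equal(c(got$family_order, got$level), best)

  # single-candidate grid returns that candidate
  one <- optimize_wavelet(ds, 5L, 4L)
  expect_equal(c(one$family_order, one$level), c(5L, 4L))

  # constant spectra: every candidate is degenerate (treated as +Inf),
  # so the lexicographically smallest pair wins
  const <- spectrum_set(matrix(3, 2, 64),
                        data.frame(origin = 1L, plant_id = "p",
                                   tablet_id = "t", part = "underground",
                                   position = 1:2),
                        seq(300, 500, length.out = 64))
  tie <- optimize_wavelet(const, 3:4, 3:4)
  expect_equal(c(tie$family_order, tie$level), c(3L, 3L))
})

test_that("area normalization implements the sum-to-one contract", {
  expect_equal(area_normalize(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  set.seed(1)
  for (i in 1:5) {
    x <- runif(50, 0, 10)
    nx <- area_normalize(x)
    expect_lt(abs(sum(nx) - 1), 1e-12)
    # idempotence and scale invariance
    expect_equal(area_normalize(nx), nx)
    expect_equal(area_normalize(3.7 * x), nx)
  }
  expect_equal(area_normalize(rep(2, 8)), rep(1 / 8, 8))
  expect_error(area_normalize(c(-1, 1)), "not positive")
})

test_that("preprocessing a set normalizes every spectrum and logs steps", {
  ds <- tiny_dataset(V = 64L)
  out <- preprocess_set(ds, wavelet_params(4, 3))
  expect_equal(rowSums(out$intensities), rep(1, n_spectra(ds)),
               tolerance = 1e-12)
  expect_true(any(grepl("wavelet", out$provenance)))
  expect_true(any(grepl("area normalization", out$provenance)))
  # denoising then normalizing keeps well-separated peak ordering on
  # noise-free input
  cfg <- tiny_config(V = 64L, noise_sd = 0, jitter_sd = 0)
  clean <- generate_dataset(cfg)
  pk <- function(m) apply(m, 1, which.max)
  expect_equal(pk(preprocess_set(clean, wavelet_params(4, 3))$intensities),
               pk(clean$intensities))
})
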