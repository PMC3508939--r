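# Synthetic validation data: waveforms, blob images, mixing, noise,
# surrogates.

test_that("temporal waveforms are standardized, 256 samples, weakly overlapping", {
  S <- make_blobs_temporal()
  expect_equal(dim(S), c(5L, 256L))
  expect_true(all(abs(rowMeans(S)) < 1e-10))
  expect_true(all(abs(apply(S, 1, var) - 1) < 1e-10))
  cm <- abs(cor(t(S)))
  expect_true(all(cm[upper.tri(cm)] < 0.5))
})

test_that("blob images have the requested geometry and standardization", {
  sp <- make_blobs_spatial(seed = 3)
  expect_equal(dim(sp$sources), c(5L, 256L))
  expect_equal(sp$image_shape, c(16L, 16L))
  expect_true(all(abs(rowMeans(sp$sources)) < 1e-10))
  expect_true(all(abs(apply(sp$sources, 1, var) - 1) < 1e-10))
  # naturalistic-scale configuration
  sp2 <- make_blobs_spatial(seed = 3, n_sources = 2, image_size = 128L,
                            n_blobs_range = c(4L, 15L))
  expect_equal(dim(sp2$sources), c(2L, 128L^2))
  expect_identical(make_blobs_spatial(seed = 3)$sources, sp$sources)
})

test_that("an isotropic centered blob is symmetric under x-y reflection", {
  img <- bicar:::gaussian_blob(
    x = rep((seq_len(16) - 0.5) / 16, times = 16),
    y = rep((seq_len(16) - 0.5) / 16, each = 16),
    center = c(0.5, 0.5), h = c(50, 50), theta = 0)
  M <- matrix(img, 16, 16, byrow = TRUE)
  expect_equal(M, t(M), tolerance = 1e-12)
})

test_that("mixing produces the documented shapes and exact block means", {
  sim <- blobs_fixture(seed = 23)
  expect_equal(dim(sim$X_T$values), c(16L, 256L))  # 16 block sensors
  expect_equal(dim(sim$X_S$values), c(16L, 256L))  # 256/q frames, 256 px
  expect_equal(dim(sim$truth$temporal_mixing), c(16L, 5L))
  expect_equal(dim(sim$truth$spatial_mixing), c(16L, 5L))
  # block means against a scalar per-pixel loop
  flat <- sim$truth$spatial_sources[2, ]
  img <- matrix(flat, 16, 16, byrow = TRUE)
  want <- numeric(16); i <- 0
  for (br in 0:3) for (bc in 0:3) {
    i <- i + 1
    acc <- 0
    for (r in 1:4) for (c in 1:4) acc <- acc + img[br * 4 + r, bc * 4 + c]
    want[i] <- acc / 16
  }
  expect_equal(bicar:::block_means(flat, c(16L, 16L)), want,
               tolerance = 1e-12)
  # constant image: all block means equal
  expect_equal(bicar:::block_means(rep(2.5, 256), c(16L, 16L)), rep(2.5, 16))
  expect_error(bicar:::block_means(rep(1, 15 * 15), c(15L, 15L)),
               "does not tile")
})

test_that("spatial mixing columns are the transferred temporal sources", {
  sim <- blobs_fixture(seed = 24)
  for (j in 1:5) {
    expect_equal(sim$truth$spatial_mixing[, j],
                 as.numeric(apply_transfer(sim$truth$temporal_sources[j, ],
                                           sim$truth$transfer)),
                 tolerance = 1e-12)
  }
})

test_that("matching the ground truth against itself recovers the pairing", {
  sim <- blobs_fixture(seed = 25)
  tr <- sim$truth
  tdec <- toy_decomposition(tr$temporal_sources, tr$temporal_mixing)
  sdec <- toy_decomposition(tr$spatial_sources, tr$spatial_mixing,
                            modality = "spatial")
  m <- match_realization(tdec, sdec, tr$transfer)
  expect_equal(m$permutation, tr$pairing)
  expect_equal(m$match_correlations, rep(1, 5), tolerance = 1e-10)
})

test_that("noise injection is symmetric, scaled, and honors the SNR definition", {
  sim <- blobs_fixture(seed = 26)
  # sigma2 = 0: unit-variance scaling only
  clean <- add_noise(sim$X_T, sim$X_S, 0)
  expect_null(clean$snr)
  expect_equal(sd(as.numeric(clean$X_T$values)), 1, tolerance = 1e-12)
  expect_equal(cor(as.numeric(clean$X_T$values),
                   as.numeric(sim$X_T$values)), 1, tolerance = 1e-12)
  # sigma2 = 1: SNR 1; empirical noise variance within 5%
  noisy <- add_noise(sim$X_T, sim$X_S, 1, seed = 9)
  expect_equal(noisy$snr, 1)
  eps_t <- noisy$X_T$values - clean$X_T$values
  eps_s <- noisy$X_S$values - clean$X_S$values
  expect_equal(var(as.numeric(eps_t)), 1, tolerance = 0.05)
  expect_equal(var(as.numeric(eps_s)), 1, tolerance = 0.05)
  expect_equal(add_noise(sim$X_T, sim$X_S, 4, seed = 1)$snr, 0.25)
  expect_error(add_noise(sim$X_T, sim$X_S, -1), "nonnegative")
})

test_that("surrogate signals are standardized, reproducible, and pink", {
  S <- make_surrogate_naturalistic(seed = 7, n_samples = 4096)
  expect_equal(dim(S), c(5L, 4096L))
  expect_true(all(abs(rowMeans(S)) < 1e-10))
  expect_identical(make_surrogate_naturalistic(seed = 7, n_samples = 4096),
                   S)
  # periodogram log-log slope ~ -1
  slopes <- apply(S, 1, function(x) {
    p <- abs(fft(x))[2:1024]^2
    f <- seq_along(p)
    coef(lm(log(p) ~ log(f)))[[2]]
  })
  expect_true(all(abs(slopes + 1) < 0.2))
  # window cutting from a supplied signal
  sig <- sin(seq_len(5000) / 3)
  W <- make_surrogate_naturalistic(seed = 1, n_samples = 512,
                                   kind = "signal", signal = sig)
  expect_equal(dim(W), c(5L, 512L))
  expect_error(
    make_surrogate_naturalistic(seed = 1, n_samples = 9000,
                                kind = "signal", signal = sig),
    "at least")
})

test_that("default-length surrogates match the naturalistic window size", {
  S <- make_surrogate_naturalistic(seed = 2, n_sources = 1L)
  expect_equal(ncol(S), 128L^2)
})
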