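# Synthetic validation data: windowed temporal waveforms, Gaussian-blob
# images, the convolve/decimate + block-average mixing construction, and
# symmetric Gaussian noise injection.

blackman_window <- function(n) {
  k <- seq_len(n) - 1L
  0.42 - 0.5 * cos(2 * pi * k / (n - 1)) + 0.08 * cos(4 * pi * k / (n - 1))
}

#' Five windowed temporal source waveforms
#'
#' Deterministic fixture of five simple signals with limited temporal
#' support and limited mutual overlap, emulating a 1-second recording at
#' 256 Hz: a windowed sinusoid burst, two Blackman windows at distinct
#' offsets, a Gaussian pulse and a double Gaussian pulse. Each row is
#' standardized to zero mean and unit variance.
#'
#' @param seed accepted for interface symmetry with the other generators;
#'   the waveforms are a fixed fixture and do not depend on it.
#' @param n_samples samples per signal (default 256).
#' @return 5 x n_samples matrix of standardized signals.
#' @export
make_blobs_temporal <- function(seed = NULL, n_samples = 256L) {
  n <- as.integer(n_samples)
  t <- seq_len(n)
  place <- function(sig, at) {
    out <- numeric(n)
    idx <- at + seq_along(sig) - 1L
    keep <- idx >= 1L & idx <= n
    out[idx[keep]] <- sig[keep]
    out
  }
  w <- round(n / 5)  # support of each event: ~20% of the record
  sources <- rbind(
    place(sin(2 * pi * 4 * seq_len(w) / w) * blackman_window(w),
          round(0.05 * n)),
    place(blackman_window(w), round(0.28 * n)),
    place(blackman_window(round(0.7 * w)), round(0.62 * n)),
    place(exp(-((seq_len(w) - w / 2)^2) / (2 * (w / 8)^2)),
          round(0.45 * n)),
    place(exp(-((seq_len(w) - w / 4)^2) / (2 * (w / 10)^2)) +
            exp(-((seq_len(w) - 3 * w / 4)^2) / (2 * (w / 10)^2)),
          round(0.80 * n)))
  standardize_rows(sources)
}

#' Random Gaussian-blob spatial sources
#'
#' Each source is an `image_size` x `image_size` pixelisation of the unit
#' square containing a uniform-random number of non-normalized anisotropic
#' Gaussians \eqn{\exp(-(r-r_0)^T R(\theta)^T H R(\theta) (r-r_0))} with a
#' random center in the unit square, a diagonal Hessian with entries drawn
#' from `hessian_range`, and a random rotation angle. Images are
#' standardized and flattened row-major.
#'
#' Defaults follow the small benchmark configuration (16 x 16 pixels, two
#' to four blobs); a larger naturalistic configuration uses 128 x 128
#' pixels and 4-15 blobs.
#'
#' @param seed integer RNG seed.
#' @param n_sources number of images (default 5).
#' @param image_size pixels per side, >= 4 (default 16).
#' @param n_blobs_range integer range for the blob count per image
#'   (default c(2, 4)).
#' @param hessian_range range for the diagonal Hessian entries; the default
#'   c(10, 300) gives blob full widths spanning roughly 10-50% of the unit
#'   square.
#' @return list with `sources` (n_sources x image_size^2, standardized
#'   rows) and `image_shape` c(H, W).
#' @export
make_blobs_spatial <- function(seed = NULL, n_sources = 5L,
                               image_size = 16L,
                               n_blobs_range = c(2L, 4L),
                               hessian_range = c(10, 300)) {
  image_size <- as.integer(image_size)
  if (image_size < 4L) stop("image_size must be >= 4")
  with_seed(seed, {
    gx <- (seq_len(image_size) - 0.5) / image_size
    grid <- expand.grid(x = gx, y = gx)  # row-major flatten: x varies fastest
    sources <- t(vapply(seq_len(n_sources), function(s) {
      k <- sample(seq.int(n_blobs_range[1], n_blobs_range[2]), 1L)
      img <- numeric(image_size^2)
      for (bl in seq_len(k)) {
        img <- img + gaussian_blob(grid$x, grid$y,
                                   center = runif(2),
                                   h = runif(2, hessian_range[1],
                                             hessian_range[2]),
                                   theta = runif(1, 0, pi))
      }
      standardize(img)
    }, numeric(image_size^2)))
    list(sources = sources, image_shape = c(image_size, image_size))
  })
}

# One non-normalized rotated anisotropic Gaussian evaluated at (x, y).
gaussian_blob <- function(x, y, center, h, theta) {
  ct <- cos(theta); st <- sin(theta)
  dx <- x - center[1]; dy <- y - center[2]
  u <- ct * dx + st * dy
  v <- -st * dx + ct * dy
  exp(-(h[1] * u^2 + h[2] * v^2))
}

#' Mix paired temporal and spatial sources into two data matrices
#'
#' Builds the two observed matrices from ground-truth sources. The spatial
#' mixing column for source j is the transfer-transformed temporal source
#' (convolved with the filter and decimated to the frame grid), so
#' X_S = A_S S_S has one frame per decimated time point. The temporal
#' mixing column for source j holds the mean intensities of spatial source
#' j over a `block_grid` tiling of the image (sixteen blocks by default),
#' so X_T = A_T S_T has one sensor per block.
#'
#' @param temporal_sources n x N_TT matrix of standardized signals.
#' @param spatial_sources n x N_SS matrix of standardized flattened images.
#' @param image_shape c(H, W) of the images.
#' @param transfer a [transfer_config()]; `q` must divide N_TT.
#' @param block_grid c(rows, cols) tiling of the image (default c(4, 4));
#'   must divide the image dimensions exactly.
#' @return list with `X_T` (blocks x N_TT [data_matrix]), `X_S` (frames x
#'   N_SS [data_matrix]) and `truth`, a `ground_truth` holding the sources,
#'   both true mixing matrices, the (identity) temporal-spatial pairing,
#'   the transfer config and the image shape.
#' @export
mix_sources <- function(temporal_sources, spatial_sources, image_shape,
                        transfer = transfer_config(),
                        block_grid = c(4L, 4L)) {
  n <- nrow(temporal_sources)
  if (nrow(spatial_sources) != n) {
    stop("temporal and spatial source counts differ")
  }
  A_S <- vapply(seq_len(n), function(j) {
    as.numeric(apply_transfer(temporal_sources[j, ], transfer))
  }, numeric(ncol(temporal_sources) / transfer$q))
  A_T <- vapply(seq_len(n), function(j) {
    block_means(spatial_sources[j, ], image_shape, block_grid)
  }, numeric(prod(block_grid)))
  X_S <- A_S %*% spatial_sources
  X_T <- A_T %*% temporal_sources
  truth <- structure(
    list(temporal_sources = temporal_sources,
         spatial_sources = spatial_sources,
         temporal_mixing = A_T, spatial_mixing = A_S,
         pairing = seq_len(n), transfer = transfer,
         image_shape = image_shape, block_grid = block_grid),
    class = "ground_truth")
  list(X_T = data_matrix(X_T, "temporal",
                         sampling_interval = transfer$dt),
       X_S = data_matrix(X_S, "spatial",
                         sampling_interval = transfer$dt * transfer$q),
       truth = truth)
}

# Mean intensity of a flattened row-major image over a block tiling.
block_means <- function(flat_image, image_shape, block_grid = c(4L, 4L)) {
  H <- image_shape[1]; W <- image_shape[2]
  if (H %% block_grid[1] != 0L || W %% block_grid[2] != 0L) {
    stop(sprintf("block grid %dx%d does not tile a %dx%d image",
                 block_grid[1], block_grid[2], H, W))
  }
  img <- matrix(flat_image, nrow = H, ncol = W, byrow = TRUE)
  bh <- H / block_grid[1]; bw <- W / block_grid[2]
  out <- numeric(prod(block_grid))
  i <- 1L
  for (br in seq_len(block_grid[1])) {
    for (bc in seq_len(block_grid[2])) {
      rows <- ((br - 1L) * bh + 1L):(br * bh)
      cols <- ((bc - 1L) * bw + 1L):(bc * bw)
      out[i] <- mean(img[rows, cols])
      i <- i + 1L
    }
  }
  out
}

#' Add symmetric Gaussian noise to both data matrices
#'
#' Each matrix is first rescaled so the variance of its pooled entries is
#' one, then i.i.d. Gaussian noise of variance `sigma2` is added to both.
#' With unit signal variance by construction, SNR = 1 / sigma2.
#'
#' @param X_T,X_S the two data matrices ([data_matrix()] or plain).
#' @param sigma2 noise variance, >= 0 (the benchmark noise sweep spans
#'   1e-2 to 1e2).
#' @param seed integer RNG seed.
#' @return list `X_T`, `X_S` (noisy, unit signal variance), `snr`
#'   (1/sigma2; NULL when sigma2 = 0).
#' @export
add_noise <- function(X_T, X_S, sigma2, seed = NULL) {
  if (sigma2 < 0) stop("sigma2 must be nonnegative")
  X_T <- as_data_matrix(X_T, "temporal")
  X_S <- as_data_matrix(X_S, "spatial")
  unitize <- function(M) M / sd(as.numeric(M))
  vt <- unitize(X_T$values)
  vs <- unitize(X_S$values)
  if (sigma2 > 0) {
    noise <- with_seed(seed, {
      list(t = matrix(rnorm(length(vt), sd = sqrt(sigma2)), nrow(vt)),
           s = matrix(rnorm(length(vs), sd = sqrt(sigma2)), nrow(vs)))
    })
    vt <- vt + noise$t
    vs <- vs + noise$s
  }
  list(X_T = data_matrix(vt, "temporal", X_T$sampling_interval),
       X_S = data_matrix(vs, "spatial", X_S$sampling_interval),
       snr = if (sigma2 > 0) 1 / sigma2 else NULL)
}

#' Naturalistic 1-D surrogate signals
#'
#' Emulates speech/music-style temporal sources without external media:
#' either random contiguous windows cut from a user-supplied signal, or
#' 1/f-spectrum ("pink") Gaussian noise synthesized in the frequency
#' domain. Rows are standardized.
#'
#' @param seed integer RNG seed.
#' @param n_samples window length (default 128^2 = 16384, roughly six
#'   seconds at 2.75 kHz).
#' @param kind `"colored-noise"` (default) or `"signal"` (cut windows from
#'   `signal`).
#' @param n_sources number of rows (default 5).
#' @param signal numeric vector to cut windows from when
#'   `kind = "signal"`; must be at least `n_samples` long.
#' @return n_sources x n_samples matrix of standardized signals.
#' @export
make_surrogate_naturalistic <- function(seed = NULL, n_samples = 128L^2,
                                        kind = c("colored-noise", "signal"),
                                        n_sources = 5L, signal = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n_samples)
  with_seed(seed, {
    rows <- lapply(seq_len(n_sources), function(s) {
      if (kind == "signal") {
        if (is.null(signal)) stop("kind = 'signal' requires `signal`")
        if (length(signal) < n) {
          stop(sprintf("signal has %d samples, need at least %d",
                       length(signal), n))
        }
        start <- sample.int(length(signal) - n + 1L, 1L)
        signal[start:(start + n - 1L)]
      } else {
        # 1/f amplitude spectrum with random phases, real signal via
        # Hermitian symmetry
        half <- n %/% 2L
        freq <- seq_len(half)
        amp <- 1 / sqrt(freq)  # power ~ 1/f
        phase <- runif(half, 0, 2 * pi)
        spec <- complex(modulus = amp, argument = phase)
        full <- complex(real = numeric(n))
        full[2L:(half + 1L)] <- spec
        if (n %% 2L == 0L) {
          full[half + 1L] <- complex(real = amp[half])  # Nyquist bin real
          full[n:(n - half + 2L)] <- Conj(spec[1:(half - 1L)])
        } else {
          full[n:(n - half + 1L)] <- Conj(spec)
        }
        Re(fft(full, inverse = TRUE))
      }
    })
    standardize_rows(do.call(rbind, rows))
  })
}

#' Generate a complete small benchmark dataset
#'
#' Convenience wrapper: fixed windowed temporal waveforms, seeded random
#' blob images, mixing through the transfer function and block averaging,
#' and optional symmetric noise.
#'
#' @param seed integer RNG seed (drives blob images and noise).
#' @param sigma2 noise variance (default 0 = noiseless).
#' @param transfer a [transfer_config()] (default: a=6, b=1, delta=2,
#'   dt=0.05, q=16).
#' @param image_size,n_blobs_range,hessian_range forwarded to
#'   [make_blobs_spatial()].
#' @param n_samples temporal length (default 256).
#' @return list `X_T`, `X_S`, `truth`, `snr`.
#' @export
simulate_blobs <- function(seed = 1L, sigma2 = 0,
                           transfer = transfer_config(),
                           image_size = 16L, n_blobs_range = c(2L, 4L),
                           hessian_range = c(10, 300),
                           n_samples = 256L) {
  seeds <- spawn_seeds(seed, 2L)
  st <- make_blobs_temporal(n_samples = n_samples)
  sp <- make_blobs_spatial(seed = seeds[1], image_size = image_size,
                           n_blobs_range = n_blobs_range,
                           hessian_range = hessian_range)
  mixed <- mix_sources(st, sp$sources, sp$image_shape, transfer = transfer)
  noisy <- add_noise(mixed$X_T, mixed$X_S, sigma2, seed = seeds[2])
  list(X_T = noisy$X_T, X_S = noisy$X_S, truth = mixed$truth,
       snr = noisy$snr)
}
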