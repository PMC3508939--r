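# Transfer: the physical linkage between temporal sources and spatial
# mixing time courses -- a delayed gamma-variate low-pass filter applied by
# (circulant) convolution, followed by integer decimation.

#' Transfer function configuration
#'
#' Parameters of the delayed low-pass filter
#' \deqn{h(t) = (t-\Delta)^a \, e^{-(t-\Delta)/b}\, \Theta(t-\Delta)}
#' (\eqn{\Theta} the Heaviside step), the form commonly used for
#' hemodynamic-style impulse responses. It has a single peak at
#' \eqn{t = \Delta + ab}. A temporal source is circularly convolved with h
#' sampled on the source's grid, then decimated by the integer factor `q`
#' to land on the spatial frame grid.
#'
#' Defaults a = 6, b = 1, delta = 2 put the peak at t = 8 s. The grid
#' spacing `dt` must be chosen so the filter has support on the sampled
#' window (with 256-sample sources, dt = 0.05 puts the peak at sample 160).
#' Pearson-based matching is scale- and unit-invariant, so only dt relative
#' to (a, b, delta) matters.
#'
#' @param a shape exponent, > 0 (dimensionless).
#' @param b decay scale, > 0 (seconds).
#' @param delta onset delay, >= 0 (seconds); h is identically zero before it.
#' @param dt sample spacing of the temporal grid (seconds).
#' @param q integer decimation factor >= 1; must divide the source length
#'   when applied.
#' @param conv_mode `"circulant"` (circular convolution, the matrix form of
#'   the linkage) or `"linear-zeropad"` (causal linear convolution, no
#'   wraparound -- wraparound is unphysical for real recordings).
#' @param normalize filter normalization: `"peak-one"`, `"unit-sum"`, or
#'   `"none"`. Inert under correlation-based matching.
#' @param phase decimation phase in `[0, q)`: index of the sample kept in
#'   each block (default 0, i.e. samples 1, 1+q, 1+2q, ... in R indexing).
#' @param identity if TRUE the filter is replaced by a unit impulse
#'   (identity linkage; replaces the singular a -> 0 limit).
#' @return an object of class `transfer_config`.
#' @export
transfer_config <- function(a = 6, b = 1, delta = 2, dt = 0.05, q = 16L,
                            conv_mode = c("circulant", "linear-zeropad"),
                            normalize = c("peak-one", "unit-sum", "none"),
                            phase = 0L, identity = FALSE) {
  conv_mode <- match.arg(conv_mode)
  normalize <- match.arg(normalize)
  if (!identity && (a <= 0 || b <= 0)) stop("a and b must be positive")
  if (delta < 0) stop("delta must be nonnegative")
  if (dt <= 0) stop("dt must be positive")
  q <- as.integer(q)
  if (q < 1L) stop("q must be a positive integer")
  phase <- as.integer(phase)
  if (phase < 0L || phase >= q) stop("phase must be in [0, q)")
  structure(
    list(a = a, b = b, delta = delta, dt = dt, q = q,
         conv_mode = conv_mode, normalize = normalize, phase = phase,
         identity = identity),
    class = "transfer_config")
}

#' @export
print.transfer_config <- function(x, ...) {
  if (x$identity) {
    cat(sprintf("<transfer_config: identity filter, q = %d>\n", x$q))
  } else {
    cat(sprintf(
      "<transfer_config: a=%g b=%g delta=%g (peak %g s), dt=%g, q=%d, %s>\n",
      x$a, x$b, x$delta, x$delta + x$a * x$b, x$dt, x$q, x$conv_mode))
  }
  invisible(x)
}

#' Sample the transfer function on a regular grid
#'
#' Evaluates h on t = 0, dt, ..., (n-1) dt and applies the configured
#' normalization. Strictly zero for t < delta.
#'
#' @param cfg a [transfer_config()].
#' @param n_samples grid length, >= 2.
#' @return numeric vector of length `n_samples`.
#' @export
sample_transfer_function <- function(cfg, n_samples) {
  n <- as.integer(n_samples)
  if (n < 2L) stop("n_samples must be >= 2")
  if (cfg$identity) return(c(1, rep(0, n - 1L)))
  t <- (seq_len(n) - 1L) * cfg$dt
  u <- t - cfg$delta
  h <- ifelse(u > 0, u^cfg$a * exp(-u / cfg$b), 0)
  if (all(h == 0)) {
    stop(sprintf(
      "sampled filter is identically zero: grid ends at t = %g < delta = %g",
      t[n], cfg$delta))
  }
  switch(cfg$normalize,
         "peak-one" = h / max(h),
         "unit-sum" = h / sum(h),
         "none" = h)
}

#' Apply the transfer function to a temporal source
#'
#' Convolves `source` with the sampled filter (circularly by default --
#' the circulant-matrix form of the linkage -- or by causal linear
#' convolution with zero padding) and decimates by keeping one sample in
#' every block of `q`. The result is standardized to zero mean and unit
#' variance; a constant result is returned unstandardized with attribute
#' `constant = TRUE` and a warning.
#'
#' @param source numeric vector of length N; `cfg$q` must divide N.
#' @param cfg a [transfer_config()].
#' @return numeric vector of length N / q.
#' @export
apply_transfer <- function(source, cfg) {
  n <- length(source)
  if (n %% cfg$q != 0L) {
    stop(sprintf("decimation factor q = %d does not divide source length %d",
                 cfg$q, n))
  }
  h <- sample_transfer_function(cfg, n)
  y <- switch(cfg$conv_mode,
    "circulant" = {
      # y_t = sum_k h_k s_{(t - k) mod N}: circular convolution via FFT.
      Re(fft(fft(source) * fft(h), inverse = TRUE)) / n
    },
    "linear-zeropad" = {
      # causal linear convolution truncated to the first N samples
      full <- convolve(source, rev(h), type = "open")
      full[seq_len(n)]
    })
  dec <- y[seq(1L + cfg$phase, n, by = cfg$q)]
  if (sd(dec) == 0) {
    warning("transfer output is constant; returned unstandardized")
    attr(dec, "constant") <- TRUE
    return(dec)
  }
  standardize(dec)
}

#' Perturb a transfer function configuration
#'
#' Controlled misspecifications used to probe robustness when the recovery
#' filter differs from the generating one:
#' \describe{
#'   \item{shape-fixed-peak}{a' = a f, b' = b / f: rise time and decay
#'     change, peak location delta + a b is preserved.}
#'   \item{peak-shift-fixed-decay}{a' = a f, b unchanged: the peak moves to
#'     delta + a f b while the asymptotic decay rate 1/b stays fixed.}
#'   \item{delay-shift}{delta' = delta f, shape untouched.}
#' }
#'
#' @param cfg a [transfer_config()].
#' @param mode one of `"shape-fixed-peak"`, `"peak-shift-fixed-decay"`,
#'   `"delay-shift"`.
#' @param factor positive multiplier; 1 returns `cfg` unchanged.
#' @return a new [transfer_config()].
#' @export
perturb_transfer <- function(cfg,
                             mode = c("shape-fixed-peak",
                                      "peak-shift-fixed-decay",
                                      "delay-shift"),
                             factor) {
  mode <- match.arg(mode)
  if (factor <= 0) stop("factor must be positive")
  out <- cfg
  switch(mode,
         "shape-fixed-peak" = {
           out$a <- cfg$a * factor
           out$b <- cfg$b / factor
         },
         "peak-shift-fixed-decay" = {
           out$a <- cfg$a * factor
         },
         "delay-shift" = {
           out$delta <- cfg$delta * factor
         })
  if (!out$identity && (out$a <= 0 || out$b <= 0 || out$delta < 0)) {
    stop("perturbation produced invalid transfer parameters")
  }
  out
}

# Explicit circulant-matrix construction of the linkage; O(N^2), used as an
# independent oracle for apply_transfer at small N.
transfer_operator_matrices <- function(cfg, n) {
  h <- sample_transfer_function(cfg, n)
  F <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      F[i, j] <- h[((i - j) %% n) + 1L]
    }
  }
  keep <- seq(1L + cfg$phase, n, by = cfg$q)
  D <- matrix(0, length(keep), n)
  D[cbind(seq_along(keep), keep)] <- 1
  list(F = F, D = D)
}
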