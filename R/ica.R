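# Unmixing: repeated stochastic ICA decompositions of one data matrix.

#' Symmetric fixed-point ICA of one matrix
#'
#' One stochastic ICA realization under the linear source separation model
#' X = A S + N. Rows of `x` are mixtures, columns are observations. The
#' data are row-centered, whitened to `n_components` principal directions,
#' and unmixed by symmetric (parallel) fixed-point iteration with the
#' log-cosh contrast and a random orthogonal initialization drawn from
#' `seed`. All scale is carried by the mixing columns: source rows are
#' standardized to zero mean and unit sample variance so that downstream
#' Pearson correlations are meaningful.
#'
#' This is the default, pluggable ICA backend: any function with the same
#' signature returning `list(mixing, sources)` can replace it in
#' [run_realizations()].
#'
#' @param x numeric matrix (mixtures x observations).
#' @param n_components number of sources to extract; at most the rank of x.
#' @param seed integer seed for the random initialization.
#' @param tol convergence tolerance on the unmixing matrix (default 1e-6).
#' @param max_iter maximum fixed-point iterations per attempt (default 500).
#' @param max_retries fresh-seed restarts allowed on non-convergence
#'   (default 3).
#' @param on_nonconvergence what to do when every attempt hits `max_iter`:
#'   `"error"` (default, the strict contract) or `"use-last"` -- keep the
#'   final iterate with a warning and `converged = FALSE`. On
#'   near-Gaussian data (e.g. noise variance far above signal variance)
#'   the contrast surface is flat and no orthogonal rotation is preferred,
#'   so a tight tolerance is unattainable; the last iterate is still a
#'   valid whitened rotation and lets extreme-noise sweeps run.
#' @return list with `mixing` (mixtures x n_components), `sources`
#'   (n_components x observations, standardized rows), `center` (row
#'   means), `converged`, `iterations`, `seed_used`.
#' @export
fastica_decompose <- function(x, n_components, seed, tol = 1e-6,
                              max_iter = 500L, max_retries = 3L,
                              on_nonconvergence = c("error", "use-last")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  nc <- as.integer(n_components)
  if (nc < 1L || nc > min(n, p)) {
    stop(sprintf("n_components must be in [1, %d]", min(n, p)))
  }
  center <- rowMeans(x)
  xc <- x - center

  # Whiten to nc principal directions; sample covariance with n-1 divisor so
  # whitened rows have unit sample variance exactly.
  cv <- tcrossprod(xc) / (p - 1)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values[1], 0) * 1e-10
  achievable <- sum(pos)
  if (achievable < nc) {
    stop(sprintf(
      "data is rank-deficient: achievable rank %d < n_components %d",
      achievable, nc))
  }
  d <- eg$values[seq_len(nc)]
  E <- eg$vectors[, seq_len(nc), drop = FALSE]
  wh <- diag(1 / sqrt(d), nc) %*% t(E)      # whitening: nc x n
  dewh <- E %*% diag(sqrt(d), nc)           # de-whitening: n x nc
  z <- wh %*% xc                            # nc x p, identity sample cov

  seeds <- c(seed, spawn_seeds(seed + 1L, max_retries))
  converged <- FALSE
  iter_used <- NA_integer_
  seed_used <- NA_integer_
  W <- NULL
  for (attempt in seq_along(seeds)) {
    W0 <- with_seed(seeds[attempt],
                    qr.Q(qr(matrix(rnorm(nc * nc), nc, nc))))
    res <- fixed_point_iterate(W0, z, tol, max_iter)
    if (res$converged) {
      W <- res$W
      converged <- TRUE
      iter_used <- res$iterations
      seed_used <- seeds[attempt]
      break
    }
    W <- res$W  # keep last in case all attempts fail
    iter_used <- res$iterations
    seed_used <- seeds[attempt]
  }
  if (!converged) {
    if (on_nonconvergence == "error") {
      stop(sprintf(
        "ICA failed to converge after %d attempts (tol %g, %d iterations)",
        length(seeds), tol, max_iter))
    }
    warning(sprintf(
      "ICA did not converge in %d attempts; keeping the final iterate",
      length(seeds)))
  }

  s <- W %*% z
  # Rows already have mean 0 and unit sample variance up to numerical error;
  # enforce exactly.
  s <- standardize_rows(s)
  # Least-squares mixing on the centered data: all scale in the columns.
  A <- xc %*% t(s) %*% solve(tcrossprod(s))
  list(mixing = A, sources = s, center = center, converged = converged,
       iterations = iter_used, seed_used = seed_used)
}

# Symmetric fixed-point iteration with the log-cosh contrast
# (g = tanh, g' = 1 - tanh^2) and symmetric decorrelation.
fixed_point_iterate <- function(W, z, tol, max_iter) {
  p <- ncol(z)
  sym_decorrelate <- function(M) {
    e <- eigen(tcrossprod(M), symmetric = TRUE)
    # clamp tiny eigenvalues: a (numerically) rank-deficient update makes
    # the decorrelation blow up; the attempt is then abandoned as
    # non-converged rather than propagating NaN
    ev <- pmax(e$values, .Machine$double.eps)
    e$vectors %*% diag(1 / sqrt(ev), nrow(M)) %*% t(e$vectors) %*% M
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- rowMeans(1 - g^2)
    W1 <- g %*% t(z) / p - diag(gp, nrow(W)) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    if (!is.finite(delta)) {
      return(list(W = W, converged = FALSE, iterations = it))
    }
    W <- W1
    if (delta < tol) {
      return(list(W = W, converged = TRUE, iterations = it))
    }
  }
  list(W = W, converged = FALSE, iterations = max_iter)
}

#' Run K independently seeded ICA realizations
#'
#' Performs `n_realizations` stochastic ICA decompositions of the same data
#' matrix, each with a fresh random initialization drawn from a child seed
#' of `master_seed`. Repeated estimation is the backbone of
#' reproducibility ranking: sources recurring across realizations are the
#' trustworthy ones.
#'
#' @param data a [data_matrix()] (or plain matrix, assumed temporal).
#' @param n_components number of sources per realization.
#' @param n_realizations K >= 2 (pairwise cross-realization correlations
#'   require at least two).
#' @param master_seed integer; deterministically spawns the K per-run seeds,
#'   so the full list is reproducible end-to-end.
#' @param backend decomposition function with the signature of
#'   [fastica_decompose()].
#' @param ... passed to the backend (e.g. `tol`, `max_iter`).
#' @return list of K `decomposition` objects, each with fields `mixing`,
#'   `sources`, `center`, `realization_index`, `seed`, `modality`,
#'   `converged`, `iterations`, `recon_error`.
#' @export
run_realizations <- function(data, n_components, n_realizations,
                             master_seed, backend = fastica_decompose, ...) {
  data <- as_data_matrix(data, "temporal")
  K <- as.integer(n_realizations)
  if (K < 2L) stop("n_realizations must be >= 2")
  if (n_components > min(dim(data$values))) {
    stop(sprintf("n_components (%d) exceeds min matrix dimension (%d)",
                 n_components, min(dim(data$values))))
  }
  seeds <- spawn_seeds(master_seed, K)
  lapply(seq_len(K), function(k) {
    fit <- backend(data$values, n_components, seed = seeds[k], ...)
    dec <- structure(
      list(mixing = fit$mixing, sources = fit$sources, center = fit$center,
           realization_index = k, seed = seeds[k], modality = data$modality,
           converged = fit$converged, iterations = fit$iterations),
      class = "decomposition")
    dec$recon_error <- reconstruction_error(dec, data)
    dec
  })
}

#' Relative reconstruction error of one decomposition
#'
#' Frobenius norm of the residual between the row-centered data and the
#' model reconstruction `mixing %*% sources`, divided by the Frobenius norm
#' of the row-centered data. Sources are zero-mean by construction, so the
#' model cannot represent per-sensor means; they are held in the
#' decomposition's `center` field and removed before comparison.
#'
#' @param dec a `decomposition`.
#' @param data the [data_matrix()] (or matrix) it was fitted to.
#' @return nonnegative scalar; 0 for an exact factorization, 1 when the
#'   reconstruction is identically zero.
#' @export
reconstruction_error <- function(dec, data) {
  data <- as_data_matrix(data, dec$modality %||% "temporal")
  x <- data$values
  if (!identical(dim(x), c(nrow(dec$mixing), ncol(dec$sources)))) {
    stop(sprintf("shape mismatch: data is %dx%d, model reconstructs %dx%d",
                 nrow(x), ncol(x), nrow(dec$mixing), ncol(dec$sources)))
  }
  xc <- x - rowMeans(x)
  resid <- xc - dec$mixing %*% dec$sources
  sqrt(sum(resid^2)) / sqrt(sum(xc^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf(
    "<decomposition: %s, %d sources x %d samples, realization %d, seed %d>\n",
    x$modality, nrow(x$sources), ncol(x$sources),
    x$realization_index, x$seed))
  invisible(x)
}
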