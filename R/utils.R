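# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. With seed = NULL the global stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministically spawn n child seeds (< 2^31) from a master seed.
spawn_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  with_seed(as.integer(master_seed), sample.int(.Machine$integer.max, n))
}

# Pearson correlation that maps zero-variance vectors to 0 (with a warning)
# instead of NA: constant ICA outputs occur at extreme noise levels.
safe_cor <- function(x, y, warn = TRUE) {
  if (anyNA(x) || anyNA(y)) stop("NaN/NA values in correlation input")
  if (sd(x) == 0 || sd(y) == 0) {
    if (warn) warning("zero-variance vector in correlation; returning 0")
    return(0)
  }
  cor(x, y)
}

# |Pearson| between all row pairs of two matrices (rows are observations of
# equal length); zero-variance rows give 0.
abs_cor_rows <- function(A, B) {
  sa <- apply(A, 1L, sd)
  sb <- apply(B, 1L, sd)
  out <- matrix(0, nrow(A), nrow(B))
  ok_a <- sa > 0
  ok_b <- sb > 0
  if (any(ok_a) && any(ok_b)) {
    out[ok_a, ok_b] <- abs(cor(t(A[ok_a, , drop = FALSE]),
                               t(B[ok_b, , drop = FALSE])))
  }
  if (!all(ok_a) || !all(ok_b)) {
    warning("zero-variance rows in correlation; entries set to 0")
  }
  out
}

# Standardize a vector to zero mean, unit (sample) variance.
standardize <- function(x) {
  s <- sd(x)
  if (s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

# Standardize each row of a matrix.
standardize_rows <- function(M) {
  t(apply(M, 1L, standardize))
}

# FNV-1a hash of a character scalar, hex string; dependency-free provenance
# fingerprint for configurations.
fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
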