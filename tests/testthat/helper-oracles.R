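# Independent oracles and fixture builders. The oracles are deliberately
# naive (scalar loops, explicit matrices, exhaustive scans) and share no
# code with the implementation paths they check.

# Scalar-loop Pearson correlation.
pearson_scalar <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Greedy nondegenerate assignment by exhaustive full-matrix rescan at every
# round (oracle for greedy_match / the quality search).
greedy_oracle <- function(cm) {
  n <- nrow(cm)
  perm <- integer(n); cors <- numeric(n); order_t <- integer(n)
  used_r <- used_c <- logical(n)
  for (round in seq_len(n)) {
    best <- -Inf; bi <- bj <- NA
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (!used_r[i] && !used_c[j] && cm[i, j] > best) {
        best <- cm[i, j]; bi <- i; bj <- j
      }
    }
    perm[bi] <- bj; cors[round] <- best; order_t[round] <- bi
    used_r[bi] <- TRUE; used_c[bj] <- TRUE
  }
  list(permutation = perm, match_correlations = cors, pick_order = order_t)
}

# Scalar-loop CRCM oracle: w_T |rho| between temporal rows plus w_S |rho|
# between matched-order spatial rows, entry by entry.
crcm_oracle <- function(temporal_decs, spatial_decs, matches, w_T, w_S) {
  K <- length(temporal_decs)
  n_c <- nrow(temporal_decs[[1]]$sources)
  out <- list()
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    m <- matrix(0, n_c, n_c)
    for (r in seq_len(n_c)) for (c in seq_len(n_c)) {
      rt <- pearson_scalar(temporal_decs[[i]]$sources[r, ],
                           temporal_decs[[j]]$sources[c, ])
      pi_ <- matches[[i]]$permutation[r]
      pj <- matches[[j]]$permutation[c]
      rs <- pearson_scalar(spatial_decs[[i]]$sources[pi_, ],
                           spatial_decs[[j]]$sources[pj, ])
      m[r, c] <- w_T * abs(rt) + w_S * abs(rs)
    }
    out[[paste(i, j, sep = "_")]] <- m
  }
  out
}

# Naive seed-then-extend alignment oracle: full rescan of every matrix at
# each step, explicit bookkeeping of used (realization, source) pairs.
# Returns the member source index per realization for each group.
align_oracle <- function(mats, K, n_c) {
  used <- matrix(FALSE, K, n_c)
  entry <- function(a, r, k, s) {
    if (a < k) mats[[paste(a, k, sep = "_")]][r, s]
    else mats[[paste(k, a, sep = "_")]][s, r]
  }
  groups <- list()
  for (g in seq_len(n_c)) {
    best <- -Inf; sa <- sr <- sb <- sc <- NA
    for (a in seq_len(K - 1)) for (b in (a + 1):K) {
      for (r in seq_len(n_c)) for (c in seq_len(n_c)) {
        if (!used[a, r] && !used[b, c] &&
            mats[[paste(a, b, sep = "_")]][r, c] > best) {
          best <- mats[[paste(a, b, sep = "_")]][r, c]
          sa <- a; sr <- r; sb <- b; sc <- c
        }
      }
    }
    member <- integer(K); member[sa] <- sr; member[sb] <- sc
    for (k in setdiff(seq_len(K), c(sa, sb))) {
      v1best <- v2best <- -Inf; s1 <- s2 <- NA
      for (s in seq_len(n_c)) {
        if (used[k, s]) next
        if (entry(sa, sr, k, s) > v1best) { v1best <- entry(sa, sr, k, s); s1 <- s }
        if (entry(sb, sc, k, s) > v2best) { v2best <- entry(sb, sc, k, s); s2 <- s }
      }
      member[k] <- if (s1 == s2) s1 else if (v1best >= v2best) s1 else s2
    }
    for (k in seq_len(K)) used[k, member[k]] <- TRUE
    groups[[g]] <- member
  }
  groups
}

# Seeded evaluation that restores the caller's RNG state.
with_seed_local <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Minimal decomposition-like object for matching/fusion tests.
toy_decomposition <- function(sources, mixing, realization_index = 1L,
                              modality = "temporal") {
  structure(list(sources = sources, mixing = mixing,
                 center = rep(0, nrow(mixing)),
                 realization_index = realization_index,
                 seed = 0L, modality = modality, converged = TRUE,
                 iterations = 0L),
            class = "decomposition")
}

# Two standardized, weakly overlapping 256-sample test signals.
toy_sources <- function() {
  n <- 256
  s1 <- sin(2 * pi * 5 * seq_len(n) / n)
  s2 <- exp(-((seq_len(n) - 80)^2) / (2 * 15^2))
  rbind((s1 - mean(s1)) / sd(s1), (s2 - mean(s2)) / sd(s2))
}

# Small noiseless mixed dataset shared by several test files.
blobs_fixture <- function(seed = 42, sigma2 = 0) {
  simulate_blobs(seed = seed, sigma2 = sigma2)
}
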