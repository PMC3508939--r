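# CRCMs, cross-realization alignment, sign canonicalization, aggregation.

# K toy realizations with known sources; matching permutations identity.
make_realizations <- function(K, n_c, n_samples = 120, seed = 1,
                              jitter = 0.05) {
  base_t <- with_seed_local(seed,
                            matrix(rnorm(n_c * n_samples), n_c))
  base_s <- with_seed_local(seed + 1,
                            matrix(rnorm(n_c * n_samples), n_c))
  std <- function(M) t(apply(M, 1, function(r) (r - mean(r)) / sd(r)))
  temporal <- spatial <- matches <- list()
  for (k in seq_len(K)) {
    nt <- with_seed_local(seed + 10 * k,
                          matrix(rnorm(n_c * n_samples, sd = jitter), n_c))
    ns <- with_seed_local(seed + 10 * k + 1,
                          matrix(rnorm(n_c * n_samples, sd = jitter), n_c))
    temporal[[k]] <- toy_decomposition(std(base_t + nt),
                                       matrix(rnorm(8 * n_c), 8),
                                       realization_index = k)
    spatial[[k]] <- toy_decomposition(std(base_s + ns),
                                      matrix(rnorm(8 * n_c), 8),
                                      realization_index = k,
                                      modality = "spatial")
    matches[[k]] <- structure(list(permutation = seq_len(n_c),
                                   match_correlations = rep(1, n_c),
                                   pick_order = seq_len(n_c),
                                   realization_index = k),
                              class = "match_result")
  }
  list(temporal = temporal, spatial = spatial, matches = matches)
}

test_that("CRCM entries match a scalar brute-force Pearson loop", {
  rl <- make_realizations(K = 3, n_c = 2, seed = 4)
  crcms <- compute_crcms(rl$temporal, rl$spatial, rl$matches,
                         w_T = 0.3, w_S = 0.7)
  want <- crcm_oracle(rl$temporal, rl$spatial, rl$matches, 0.3, 0.7)
  expect_length(crcms$matrices, 3)  # K(K-1)/2
  for (nm in names(want)) {
    expect_equal(crcms$matrices[[nm]], want[[nm]], tolerance = 1e-12)
  }
  expect_true(all(unlist(crcms$matrices) >= 0 &
                    unlist(crcms$matrices) <= 1 + 1e-12))
})

test_that("two identical realizations give a unit CRCM diagonal; w_T = 1 reduces to the temporal CRCM", {
  rl <- make_realizations(K = 2, n_c = 3, seed = 9, jitter = 0)
  crcms <- compute_crcms(rl$temporal, rl$spatial, rl$matches)
  expect_equal(diag(crcms$matrices[["1_2"]]), rep(1, 3), tolerance = 1e-12)
  ct <- compute_crcms(rl$temporal, rl$spatial, rl$matches,
                      w_T = 1, w_S = 0)
  direct <- abs(cor(t(rl$temporal[[1]]$sources),
                    t(rl$temporal[[2]]$sources)))
  expect_equal(ct$matrices[["1_2"]], direct, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(compute_crcms(rl$temporal, rl$spatial, rl$matches,
                             w_T = 0, w_S = 0), "weights")
})

test_that("CRCM of swapped realizations is the transpose", {
  rl <- make_realizations(K = 2, n_c = 3, seed = 2)
  ab <- compute_crcms(rl$temporal, rl$spatial, rl$matches)$matrices[["1_2"]]
  rev_rl <- list(temporal = rl$temporal[2:1], spatial = rl$spatial[2:1],
                 matches = rl$matches[2:1])
  ba <- compute_crcms(rev_rl$temporal, rev_rl$spatial,
                      rev_rl$matches)$matrices[["1_2"]]
  expect_equal(ab, t(ba), tolerance = 1e-12)
})

test_that("alignment groups identical realizations by source index and partitions all pairs", {
  rl <- make_realizations(K = 4, n_c = 3, seed = 6, jitter = 0.02)
  crcms <- compute_crcms(rl$temporal, rl$spatial, rl$matches)
  groups <- align_sources(crcms, rl$temporal, rl$spatial, rl$matches)
  expect_length(groups, 3)
  # low jitter: every group should hold one source index across realizations
  for (g in groups) {
    idx <- vapply(g$members, `[[`, integer(1), "source_index")
    expect_length(unique(idx), 1)
  }
  # partition property: all (realization, source) pairs appear exactly once
  pairs <- do.call(rbind, lapply(groups, function(g) {
    t(vapply(g$members, function(m) c(m$realization_index, m$source_index),
             integer(2)))
  }))
  expect_equal(nrow(unique(pairs)), 4 * 3)
})

test_that("alignment equals the naive seed-then-extend oracle on random CRCMs", {
  for (seed in 1:10) {
    K <- 3; n_c <- 3
    rl <- make_realizations(K, n_c, seed = 100 + seed, jitter = 2)
    crcms <- compute_crcms(rl$temporal, rl$spatial, rl$matches)
    got <- align_sources(crcms, rl$temporal, rl$spatial, rl$matches)
    want <- align_oracle(crcms$matrices, K, n_c)
    for (g in seq_len(n_c)) {
      expect_equal(
        vapply(got[[g]]$members, `[[`, integer(1), "source_index"),
        want[[g]])
    }
  }
})

test_that("sign canonicalization aligns orientations and preserves reconstruction", {
  rl <- make_realizations(K = 5, n_c = 2, seed = 12, jitter = 0.01)
  # corrupt signs randomly: flip source rows and mixing columns together
  flips <- with_seed_local(3, matrix(sample(c(-1, 1), 5 * 2, TRUE), 5))
  for (k in 1:5) {
    for (r in 1:2) {
      rl$temporal[[k]]$sources[r, ] <- flips[k, r] * rl$temporal[[k]]$sources[r, ]
      rl$temporal[[k]]$mixing[, r] <- flips[k, r] * rl$temporal[[k]]$mixing[, r]
    }
  }
  crcms <- compute_crcms(rl$temporal, rl$spatial, rl$matches)
  groups <- align_sources(crcms, rl$temporal, rl$spatial, rl$matches)
  canon <- lapply(groups, canonicalize_signs)
  for (g in canon) {
    ref <- g$members[[min(g$seed_pair$a, g$seed_pair$b)]]
    for (m in g$members) {
      expect_gt(cor(m$temporal_source, ref$temporal_source), 0)
      expect_gt(cor(m$spatial_source, ref$spatial_source), 0)
      # flipping source and mixing column together cancels in A.S
      k <- m$realization_index; r <- m$source_index
      expect_equal(m$temporal_mixing %o% m$temporal_source,
                   rl$temporal[[k]]$mixing[, r] %o%
                     rl$temporal[[k]]$sources[r, ],
                   tolerance = 1e-12)
    }
  }
})

test_that("group statistics follow the stated arithmetic", {
  sim <- matrix(1, 3, 3)
  sim[1, 2] <- sim[2, 1] <- 0.9
  sim[1, 3] <- sim[3, 1] <- 0.8
  sim[2, 3] <- sim[3, 2] <- 0.7
  st <- bicar:::group_statistics(sim)
  expect_equal(st$reproducibility, 0.8)
  expect_equal(st$weights, c(0.85, 0.80, 0.75) / sum(c(0.85, 0.80, 0.75)))
})

test_that("aggregation of identical members gives R = 1 and returns the member", {
  rl <- make_realizations(K = 3, n_c = 2, seed = 21, jitter = 0)
  crcms <- compute_crcms(rl$temporal, rl$spatial, rl$matches)
  groups <- lapply(align_sources(crcms, rl$temporal, rl$spatial,
                                 rl$matches), canonicalize_signs)
  res <- aggregate_groups(groups)
  expect_equal(res$reproducibility, c(1, 1), tolerance = 1e-12)
  # averaged source equals the (identical) member up to sign
  m1 <- groups[[1]]$members[[1]]$temporal_source
  expect_equal(abs(cor(res$temporal_sources[1, ], m1)), 1,
               tolerance = 1e-12)
  expect_true(all(diff(res$reproducibility) <= 0))
})

test_that("mutually uncorrelated members give near-zero reproducibility", {
  rl <- make_realizations(K = 4, n_c = 2, seed = 31, jitter = 1e6)
  crcms <- compute_crcms(rl$temporal, rl$spatial, rl$matches)
  groups <- lapply(align_sources(crcms, rl$temporal, rl$spatial,
                                 rl$matches), canonicalize_signs)
  res <- aggregate_groups(groups)
  # |Pearson| of independent 120-sample vectors ~ 0.07; alignment picks
  # maxima so allow generous sampling slack
  expect_true(all(res$reproducibility < 0.35))
  expect_true(all(res$reproducibility >= 0))
})
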