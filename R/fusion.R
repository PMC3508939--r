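# Fusion: cross-realization correlation matrices, alignment of matched
# source pairs across realizations, sign canonicalization, and aggregation
# into reproducibility-ranked components.

#' Cross-realization correlation matrices (CRCMs)
#'
#' For every realization pair i < j, entry (r, c) of R^(ij) combines the
#' temporal and spatial similarity of matched super-sources:
#' w_T |cor(S_T^(i) row r, S_T^(j) row c)| +
#' w_S |cor((P^(i) S_S^(i)) row r, (P^(j) S_S^(j)) row c)|,
#' where P^(i) reorders the spatial sources into matched (temporal) order.
#' With w_T = 1, w_S = 0 this reduces to the single-modality
#' (RAICAR-style) CRCM. `method = "concatenated"` instead correlates the
#' concatenation of each temporal source with its matched spatial source
#' ("super-source" view).
#'
#' @param temporal_decs,spatial_decs lists of K `decomposition`s.
#' @param matches list of K `match_result`s (realization i of temporal
#'   matched against realization i of spatial).
#' @param w_T,w_S nonnegative modality weights, sum > 0 (defaults 1/2, 1/2).
#' @param method `"weighted"` (default) or `"concatenated"`.
#' @return a `crcm_set`: named list `matrices` (key `"i_j"`), weights, K,
#'   n_components.
#' @export
compute_crcms <- function(temporal_decs, spatial_decs, matches,
                          w_T = 0.5, w_S = 0.5,
                          method = c("weighted", "concatenated")) {
  method <- match.arg(method)
  K <- length(temporal_decs)
  if (K < 2L) stop("need at least 2 realizations")
  if (length(spatial_decs) != K || length(matches) != K) {
    stop("temporal_decs, spatial_decs and matches must have equal length")
  }
  if (w_T < 0 || w_S < 0 || w_T + w_S <= 0) {
    stop("weights must be nonnegative with positive sum")
  }
  n_c <- nrow(temporal_decs[[1]]$sources)
  # spatial sources permuted into matched order: row r pairs temporal row r
  perm_spatial <- lapply(seq_len(K), function(i) {
    spatial_decs[[i]]$sources[matches[[i]]$permutation, , drop = FALSE]
  })
  mats <- list()
  for (i in seq_len(K - 1L)) {
    for (j in seq.int(i + 1L, K)) {
      if (method == "weighted") {
        rt <- abs_cor_rows(temporal_decs[[i]]$sources,
                           temporal_decs[[j]]$sources)
        rs <- abs_cor_rows(perm_spatial[[i]], perm_spatial[[j]])
        mats[[paste(i, j, sep = "_")]] <- w_T * rt + w_S * rs
      } else {
        ci <- cbind(temporal_decs[[i]]$sources, perm_spatial[[i]])
        cj <- cbind(temporal_decs[[j]]$sources, perm_spatial[[j]])
        mats[[paste(i, j, sep = "_")]] <- abs_cor_rows(ci, cj)
      }
    }
  }
  structure(list(matrices = mats, w_T = w_T, w_S = w_S, K = K,
                 n_components = n_c, method = method),
            class = "crcm_set")
}

# Fetch the block linking realization a (rows) to realization k (columns)
# from an i<j keyed list of CRCMs.
crcm_entry_block <- function(mats, a, k) {
  if (a < k) mats[[paste(a, k, sep = "_")]]
  else t(mats[[paste(k, a, sep = "_")]])
}

#' Align matched source pairs across realizations
#'
#' RAICAR-style search over the CRCMs. Each of the N_C groups is seeded by
#' the largest remaining element over all matrices, at (r, c) in the matrix
#' linking realizations (a, b): the two most similar super-sources overall.
#' For every other realization k, two candidates are found -- the best
#' partner of (a, r) in k and the best partner of (b, c) in k; if they
#' coincide that source joins the group, otherwise the one with the larger
#' correlation does. Rows and columns of extracted sources are then masked
#' (nondestructive equivalent of deletion) and the search repeats N_C - 1
#' more times, so every (realization, source) pair lands in exactly one
#' group.
#'
#' @param crcms a `crcm_set` from [compute_crcms()].
#' @param temporal_decs,spatial_decs,matches as in [compute_crcms()].
#' @return list of N_C `super_source_group` objects, each with `members`
#'   (per realization: source index, temporal/spatial source vectors and
#'   mixing columns, per-modality signs) and `seed_pair`.
#' @export
align_sources <- function(crcms, temporal_decs, spatial_decs, matches) {
  K <- crcms$K
  n_c <- crcms$n_components
  # masked working copies
  work <- lapply(crcms$matrices, identity)
  mask_source <- function(k, s) {
    for (nm in names(work)) {
      ij <- as.integer(strsplit(nm, "_", fixed = TRUE)[[1]])
      if (ij[1] == k) work[[nm]][s, ] <<- -Inf
      if (ij[2] == k) work[[nm]][, s] <<- -Inf
    }
  }
  groups <- vector("list", n_c)
  for (g in seq_len(n_c)) {
    # global maximum over all matrices; scan order fixed for determinism
    best <- -Inf; seed <- NULL
    for (nm in names(work)) {
      m <- work[[nm]]
      if (all(!is.finite(m))) next
      idx <- which(m == max(m[is.finite(m)]), arr.ind = TRUE)[1, ]
      if (m[idx[1], idx[2]] > best) {
        best <- m[idx[1], idx[2]]
        ij <- as.integer(strsplit(nm, "_", fixed = TRUE)[[1]])
        seed <- list(a = ij[1], r = idx[[1]], b = ij[2], c = idx[[2]])
      }
    }
    if (is.null(seed)) {
      stop("alignment exhausted the CRCMs before forming all groups")
    }
    member_source <- integer(K)
    member_source[seed$a] <- seed$r
    member_source[seed$b] <- seed$c
    for (k in setdiff(seq_len(K), c(seed$a, seed$b))) {
      row_block <- crcm_entry_block(work, seed$a, k)  # (source in a) x (in k)
      col_block <- crcm_entry_block(work, seed$b, k)
      v1 <- row_block[seed$r, ]
      v2 <- col_block[seed$c, ]
      s1 <- which.max(v1); s2 <- which.max(v2)
      if (!is.finite(v1[s1]) || !is.finite(v2[s2])) {
        stop("alignment found no unmasked candidate; masking is inconsistent")
      }
      member_source[k] <- if (s1 == s2) s1
                          else if (v1[s1] >= v2[s2]) s1 else s2
    }
    for (k in seq_len(K)) mask_source(k, member_source[k])
    members <- lapply(seq_len(K), function(k) {
      td <- temporal_decs[[k]]; sd_ <- spatial_decs[[k]]
      r <- member_source[k]
      sp <- matches[[k]]$permutation[r]
      list(realization_index = k, source_index = r,
           spatial_source_index = sp,
           sign_t = 1L, sign_s = 1L,
           temporal_source = td$sources[r, ],
           spatial_source = sd_$sources[sp, ],
           temporal_mixing = td$mixing[, r],
           spatial_mixing = sd_$mixing[, sp])
    })
    groups[[g]] <- structure(
      list(members = members, seed_pair = seed, seed_value = best),
      class = "super_source_group")
  }
  groups
}

#' Canonicalize signs within an aligned group
#'
#' ICA fixes sources only up to a sign: flipping a source and its mixing
#' column leaves A S unchanged, and alignment by absolute correlation mixes
#' orientations freely. The member of the seed pair from the lower-indexed
#' realization supplies the canonical orientation; every other member whose
#' signed correlation with it is negative has its source and corresponding
#' mixing column flipped. Temporal and spatial parts are canonicalized
#' independently, because the two ICA runs can flip independently.
#'
#' @param group a `super_source_group`.
#' @return the group with `sign_t`/`sign_s` set and flips applied.
#' @export
canonicalize_signs <- function(group) {
  ref_k <- min(group$seed_pair$a, group$seed_pair$b)
  ref <- group$members[[ref_k]]
  group$members <- lapply(group$members, function(m) {
    if (m$realization_index == ref_k) return(m)
    if (safe_cor(m$temporal_source, ref$temporal_source, warn = FALSE) < 0) {
      m$temporal_source <- -m$temporal_source
      m$temporal_mixing <- -m$temporal_mixing
      m$sign_t <- -m$sign_t
    }
    if (safe_cor(m$spatial_source, ref$spatial_source, warn = FALSE) < 0) {
      m$spatial_source <- -m$spatial_source
      m$spatial_mixing <- -m$spatial_mixing
      m$sign_s <- -m$sign_s
    }
    m
  })
  group
}

# Reproducibility and member weights from a K x K pairwise-similarity
# matrix: R is the mean of the K(K-1)/2 unique off-diagonal similarities
# (placing R in [0,1]); a member's weight is its mean similarity to the
# other K-1 members, normalized to sum 1.
group_statistics <- function(simmat) {
  K <- nrow(simmat)
  if (K < 2L) stop("a group needs at least 2 members")
  ut <- simmat[upper.tri(simmat)]
  R <- sum(ut) / (K * (K - 1) / 2)
  w <- (rowSums(simmat) - diag(simmat)) / (K - 1)
  if (sum(w) == 0) w <- rep(1, K)  # all-zero similarity: fall back to uniform
  list(reproducibility = R, weights = w / sum(w))
}

# Pairwise weighted similarity matrix of a group's members
# (w_T |rho_T| + w_S |rho_S|, absolute so orientation-independent).
group_similarity_matrix <- function(group, w_T, w_S) {
  Tm <- do.call(rbind, lapply(group$members, `[[`, "temporal_source"))
  Sm <- do.call(rbind, lapply(group$members, `[[`, "spatial_source"))
  w_T * abs_cor_rows(Tm, Tm) + w_S * abs_cor_rows(Sm, Sm)
}

#' Aggregate canonicalized groups into ranked components
#'
#' Each group of K aligned super-sources collapses to one component by
#' weighted averaging: a member's weight is its average absolute
#' similarity to the other K - 1 members (normalized to sum 1), so every
#' realization contributes, but unreliable members contribute less. The
#' group's reproducibility R is the mean of its unique pairwise
#' similarities, in [0, 1]. Components are returned sorted by descending
#' R.
#'
#' @param groups list of canonicalized `super_source_group`s.
#' @param w_T,w_S modality weights for the similarity (defaults 1/2, 1/2).
#' @param provenance optional list stored on the result.
#' @return a `bicar_result` with `temporal_sources` (N_C x N_TT),
#'   `spatial_sources` (N_C x N_SS), `temporal_mixing` (N_TS x N_C),
#'   `spatial_mixing` (N_ST x N_C), `reproducibility` (descending),
#'   `ranking` (order of the input groups), `weights`, `provenance`.
#' @export
aggregate_groups <- function(groups, w_T = 0.5, w_S = 0.5,
                             provenance = list()) {
  K <- length(groups[[1]]$members)
  if (K < 2L) stop("aggregation requires K >= 2 members per group")
  stats <- lapply(groups, function(g) {
    sim <- group_similarity_matrix(g, w_T, w_S)
    group_statistics(sim)
  })
  R <- vapply(stats, `[[`, numeric(1), "reproducibility")
  ord <- order(R, decreasing = TRUE)
  wavg <- function(g, st, field, byrow = TRUE) {
    M <- do.call(rbind, lapply(g$members, `[[`, field))
    as.numeric(st$weights %*% M)
  }
  temporal_sources <- do.call(rbind, lapply(ord, function(i) {
    wavg(groups[[i]], stats[[i]], "temporal_source")
  }))
  spatial_sources <- do.call(rbind, lapply(ord, function(i) {
    wavg(groups[[i]], stats[[i]], "spatial_source")
  }))
  temporal_mixing <- do.call(cbind, lapply(ord, function(i) {
    wavg(groups[[i]], stats[[i]], "temporal_mixing")
  }))
  spatial_mixing <- do.call(cbind, lapply(ord, function(i) {
    wavg(groups[[i]], stats[[i]], "spatial_mixing")
  }))
  structure(
    list(temporal_sources = temporal_sources,
         spatial_sources = spatial_sources,
         temporal_mixing = temporal_mixing,
         spatial_mixing = spatial_mixing,
         reproducibility = R[ord],
         ranking = ord,
         weights = lapply(stats[ord], `[[`, "weights"),
         provenance = provenance),
    class = "bicar_result")
}

#' @export
print.bicar_result <- function(x, ...) {
  cat(sprintf("<bicar_result: %d components>\n", length(x$reproducibility)))
  cat("reproducibility:",
      paste(sprintf("%.3f", x$reproducibility), collapse = " "), "\n")
  invisible(x)
}

#' Run the full BICAR pipeline
#'
#' Unmix both matrices K times, match temporal to spatial sources within
#' each realization through the transfer function, compute CRCMs, align
#' across realizations, canonicalize signs, and aggregate into
#' reproducibility-ranked paired components.
#'
#' @param X_T temporal data: sensors x time samples ([data_matrix()] or
#'   plain matrix).
#' @param X_S spatial data: frames x pixels.
#' @param n_components number of sources to extract from each matrix;
#'   defaults to min(sensors, frames).
#' @param n_realizations number of ICA realizations K (default 30).
#' @param master_seed integer governing all randomness.
#' @param transfer the [transfer_config()] linking the modalities; its `q`
#'   and `dt` must map the temporal grid onto the spatial frame grid
#'   (time samples = q x frames).
#' @param w_T,w_S modality weights used in CRCMs, alignment and
#'   reproducibility.
#' @param crcm_method `"weighted"` or `"concatenated"`, see
#'   [compute_crcms()].
#' @param on_nonconvergence per-realization non-convergence policy
#'   (default `"use-last"` so extreme-noise data still run end to end;
#'   see [fastica_decompose()]).
#' @param ... passed to [run_realizations()] (e.g. `backend`, `tol`).
#' @return a `bicar_result`; see [aggregate_groups()].
#' @export
bicar <- function(X_T, X_S, n_components = NULL, n_realizations = 30L,
                  master_seed = 1L, transfer = transfer_config(),
                  w_T = 0.5, w_S = 0.5, crcm_method = "weighted",
                  on_nonconvergence = "use-last", ...) {
  X_T <- as_data_matrix(X_T, "temporal")
  X_S <- as_data_matrix(X_S, "spatial")
  check_resolution_regime(X_T, X_S)
  if (is.null(n_components)) {
    n_components <- min(nrow(X_T$values), nrow(X_S$values))
  }
  seeds <- spawn_seeds(master_seed, 2L)
  temporal_decs <- run_realizations(X_T, n_components, n_realizations,
                                    master_seed = seeds[1],
                                    on_nonconvergence = on_nonconvergence,
                                    ...)
  spatial_decs <- run_realizations(X_S, n_components, n_realizations,
                                   master_seed = seeds[2],
                                   on_nonconvergence = on_nonconvergence,
                                   ...)
  matches <- lapply(seq_len(n_realizations), function(i) {
    match_realization(temporal_decs[[i]], spatial_decs[[i]], transfer)
  })
  crcms <- compute_crcms(temporal_decs, spatial_decs, matches,
                         w_T = w_T, w_S = w_S, method = crcm_method)
  groups <- align_sources(crcms, temporal_decs, spatial_decs, matches)
  groups <- lapply(groups, canonicalize_signs)
  prov <- list(
    master_seed = master_seed,
    n_realizations = n_realizations,
    n_components = n_components,
    w_T = w_T, w_S = w_S,
    transfer = unclass(transfer),
    mean_match_correlation =
      mean(vapply(matches, function(m) mean(m$match_correlations),
                  numeric(1))),
    mean_recon_error_temporal =
      mean(vapply(temporal_decs, `[[`, numeric(1), "recon_error")),
    mean_recon_error_spatial =
      mean(vapply(spatial_decs, `[[`, numeric(1), "recon_error")),
    n_converged_temporal =
      sum(vapply(temporal_decs, `[[`, logical(1), "converged")),
    n_converged_spatial =
      sum(vapply(spatial_decs, `[[`, logical(1), "converged")))
  prov$config_hash <- fnv1a(jsonlite::toJSON(
    prov[c("master_seed", "n_realizations", "n_components",
           "w_T", "w_S", "transfer")], auto_unbox = TRUE, digits = NA))
  aggregate_groups(groups, w_T = w_T, w_S = w_S, provenance = prov)
}
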