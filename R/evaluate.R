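# Evaluation: reconstruction-quality metrics against known sources, and
# the robustness experiments (noise sweep, over-extraction /
# reproducibility-truth correlation, transfer-function misspecification).

# Combined similarity matrix between recovered (temporal, spatial) pairs
# and true pairs: w_T |rho_T| + w_S |rho_S| with weights 1/2, 1/2.
pair_similarity_matrix <- function(result, truth) {
  if (ncol(result$temporal_sources) != ncol(truth$temporal_sources) ||
      ncol(result$spatial_sources) != ncol(truth$spatial_sources)) {
    stop("result and truth source lengths differ")
  }
  true_spatial_paired <- truth$spatial_sources[truth$pairing, , drop = FALSE]
  rho_t <- abs_cor_rows(result$temporal_sources, truth$temporal_sources)
  rho_s <- abs_cor_rows(result$spatial_sources, true_spatial_paired)
  list(combined = 0.5 * rho_t + 0.5 * rho_s,
       temporal = 0.5 * rho_t, spatial = 0.5 * rho_s)
}

#' Score a recovered decomposition against ground truth
#'
#' Every recovered component (a paired temporal and spatial source) is
#' absolute-correlated with every true pair; the per-pair similarity is
#' half the temporal plus half the spatial absolute correlation. The
#' similarity matrix is searched for successive maxima, removing the
#' matched row and column at each step, so each recovered component gets a
#' unique best true match. Q is the mean matched similarity; Q_T and Q_S
#' are its temporal and spatial halves, each bounded above by 0.5, with
#' Q = Q_T + Q_S bounded by 1.
#'
#' When more components were extracted than true sources exist, only the
#' greedily matched pairs (one per true source) enter the averages; the
#' surplus components are reported with `true_index = NA`.
#'
#' @param result a `bicar_result` (or any list with `temporal_sources`,
#'   `spatial_sources` matrices).
#' @param truth a `ground_truth` from [mix_sources()].
#' @return a `quality_report`: `Q`, `Q_T`, `Q_S`, `per_source_matches`
#'   data.frame (component, true_index, q_c, q_t, q_s), `n_components`,
#'   `n_true`.
#' @export
quality <- function(result, truth) {
  sims <- pair_similarity_matrix(result, truth)
  nc <- nrow(sims$combined)
  n_true <- ncol(sims$combined)
  n_match <- min(nc, n_true)
  work <- sims$combined
  comp <- integer(n_match); true_i <- integer(n_match)
  q_c <- q_t <- q_s <- numeric(n_match)
  for (step in seq_len(n_match)) {
    idx <- which(work == max(work), arr.ind = TRUE)[1, ]
    comp[step] <- idx[[1]]; true_i[step] <- idx[[2]]
    q_c[step] <- sims$combined[idx[1], idx[2]]
    q_t[step] <- sims$temporal[idx[1], idx[2]]
    q_s[step] <- sims$spatial[idx[1], idx[2]]
    work[idx[1], ] <- -Inf
    work[, idx[2]] <- -Inf
  }
  matches <- data.frame(component = comp, true_index = true_i,
                        q_c = q_c, q_t = q_t, q_s = q_s)
  unmatched <- setdiff(seq_len(nc), comp)
  if (length(unmatched)) {
    matches <- rbind(matches,
                     data.frame(component = unmatched, true_index = NA,
                                q_c = NA, q_t = NA, q_s = NA))
  }
  structure(
    list(Q = mean(q_c), Q_T = mean(q_t), Q_S = mean(q_s),
         per_source_matches = matches[order(matches$component), ],
         n_components = nc, n_true = n_true),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report: Q = %.4f (Q_T = %.4f, Q_S = %.4f), %d/%d matched>\n",
              x$Q, x$Q_T, x$Q_S, min(x$n_components, x$n_true), x$n_true))
  invisible(x)
}

# Per-component similarity to the best-matching true source: row maxima of
# the combined absolute-correlation matrix (no uniqueness constraint).
component_truth_similarity <- function(result, truth) {
  apply(pair_similarity_matrix(result, truth)$combined, 1L, max)
}

#' Noise sweep experiment
#'
#' For each inverse-SNR level and each run: regenerate the blob images
#' (fresh seed), mix, add symmetric noise, run the full pipeline, and
#' score against the run's own ground truth. Returns a tidy per-component
#' table.
#'
#' @param inv_snr_grid noise variances sigma^2 = 1/SNR (default the
#'   seven-level grid 0.01 ... 100).
#' @param n_runs independent repetitions per level (default 10).
#' @param n_components components to extract (default 5, the true count).
#' @param n_realizations ICA realizations K per run (default 30).
#' @param seed master seed; every run derives its own child seed.
#' @param transfer the generating and recovering [transfer_config()].
#' @param ... forwarded to [simulate_blobs()] (image size, blob counts...).
#' @return data.frame with one row per (inv_snr, run, rank): columns
#'   `inv_snr`, `run`, `rank`, `reproducibility`, `similarity`, `Q`,
#'   `Q_T`, `Q_S`.
#' @export
noise_sweep <- function(inv_snr_grid = c(0.01, 0.1, 0.5, 1, 2, 10, 100),
                        n_runs = 10L, n_components = 5L,
                        n_realizations = 30L, seed = 1L,
                        transfer = transfer_config(), ...) {
  if (!length(inv_snr_grid) || n_runs < 1L) {
    stop("inv_snr_grid and n_runs must be nonempty/positive")
  }
  seeds <- matrix(spawn_seeds(seed, 2L * length(inv_snr_grid) * n_runs),
                  ncol = 2L)
  rows <- list(); i <- 0L
  for (run in seq_len(n_runs)) {
    for (lev in seq_along(inv_snr_grid)) {
      i <- i + 1L
      sim <- simulate_blobs(seed = seeds[i, 1],
                            sigma2 = inv_snr_grid[lev],
                            transfer = transfer, ...)
      res <- bicar(sim$X_T, sim$X_S, n_components = n_components,
                   n_realizations = n_realizations,
                   master_seed = seeds[i, 2], transfer = transfer)
      qr_ <- quality(res, sim$truth)
      simv <- component_truth_similarity(res, sim$truth)
      rows[[i]] <- data.frame(
        inv_snr = inv_snr_grid[lev], run = run,
        rank = seq_along(res$reproducibility),
        reproducibility = res$reproducibility,
        similarity = simv,
        Q = qr_$Q, Q_T = qr_$Q_T, Q_S = qr_$Q_S)
    }
  }
  do.call(rbind, rows)
}

#' Correlation between reproducibility and similarity to true sources
#'
#' For each run and each component rank, the reproducibility values across
#' the noise levels are Pearson-correlated with the corresponding
#' best-true-match similarities (row maxima of the combined absolute
#' correlation matrix). One correlation per (run, rank); constant vectors
#' give NA.
#'
#' @param sweep a data.frame from [noise_sweep()].
#' @return list with `per_run` (data.frame run, rank, correlation) and
#'   `mean_by_rank` (data.frame rank, mean_correlation over runs).
#' @export
reproducibility_truth_correlation <- function(sweep) {
  runs <- sort(unique(sweep$run))
  ranks <- sort(unique(sweep$rank))
  per <- do.call(rbind, lapply(runs, function(r) {
    do.call(rbind, lapply(ranks, function(k) {
      sub <- sweep[sweep$run == r & sweep$rank == k, ]
      if (nrow(sub) < 2L) stop("need >= 2 noise levels per (run, rank)")
      rho <- if (sd(sub$reproducibility) == 0 || sd(sub$similarity) == 0) {
        NA_real_
      } else {
        cor(sub$reproducibility, sub$similarity)
      }
      data.frame(run = r, rank = k, correlation = rho)
    }))
  }))
  means <- vapply(ranks, function(k) {
    mean(per$correlation[per$rank == k], na.rm = TRUE)
  }, numeric(1))
  list(per_run = per,
       mean_by_rank = data.frame(rank = ranks, mean_correlation = means))
}

#' Transfer function misspecification experiment
#'
#' Data are generated with the reference transfer function; recovery runs
#' with a perturbed one ([perturb_transfer()]) and is scored against the
#' generating truth.
#'
#' @param mode perturbation mode, see [perturb_transfer()].
#' @param factor_grid positive perturbation factors (1 = perfect match).
#' @param n_runs repetitions per factor (default 10).
#' @param sigma2 noise variance (default 1, SNR of unity).
#' @param n_components,n_realizations,seed,transfer as in [noise_sweep()].
#' @param ... forwarded to [simulate_blobs()].
#' @return data.frame (mode, factor, run, Q, Q_T, Q_S).
#' @export
tf_mismatch_experiment <- function(mode, factor_grid, n_runs = 10L,
                                   sigma2 = 1, n_components = 5L,
                                   n_realizations = 30L, seed = 1L,
                                   transfer = transfer_config(), ...) {
  for (f in factor_grid) perturb_transfer(transfer, mode, f)  # validate
  seeds <- matrix(spawn_seeds(seed, 2L * length(factor_grid) * n_runs),
                  ncol = 2L)
  rows <- list(); i <- 0L
  for (run in seq_len(n_runs)) {
    for (f in factor_grid) {
      i <- i + 1L
      sim <- simulate_blobs(seed = seeds[i, 1], sigma2 = sigma2,
                            transfer = transfer, ...)
      recov <- perturb_transfer(transfer, mode, f)
      res <- bicar(sim$X_T, sim$X_S, n_components = n_components,
                   n_realizations = n_realizations,
                   master_seed = seeds[i, 2], transfer = recov)
      qr_ <- quality(res, sim$truth)
      rows[[i]] <- data.frame(mode = mode, factor = f, run = run,
                              Q = qr_$Q, Q_T = qr_$Q_T, Q_S = qr_$Q_S)
    }
  }
  do.call(rbind, rows)
}
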