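# Matching: pair temporal sources with spatial sources within one
# realization by greedy maximal absolute correlation between transformed
# temporal sources and spatial mixing columns.

#' Absolute correlation matrix between transformed sources and mixing columns
#'
#' Entry (r, c) is the absolute Pearson correlation between row r of
#' `transformed_sources` and column c of `mixing`. Zero-variance vectors
#' yield 0 with a warning (constant ICA outputs occur at extreme noise);
#' non-finite inputs are an error.
#'
#' @param transformed_sources matrix (sources x frames), e.g. rows already
#'   passed through [apply_transfer()].
#' @param mixing matrix (frames x sources).
#' @return matrix of absolute correlations in \[0, 1\].
#' @export
correlation_matrix <- function(transformed_sources, mixing) {
  if (!all(is.finite(transformed_sources)) || !all(is.finite(mixing))) {
    stop("non-finite values in correlation inputs")
  }
  if (ncol(transformed_sources) != nrow(mixing)) {
    stop(sprintf("sample count mismatch: %d vs %d",
                 ncol(transformed_sources), nrow(mixing)))
  }
  abs_cor_rows(transformed_sources, t(mixing))
}

#' Match temporal to spatial sources within one realization
#'
#' Each temporal source row is pushed through the transfer function
#' (convolve + decimate) and absolute-correlated with every column of the
#' spatial mixing matrix. Pairs are then assigned greedily and without
#' degeneracy: the largest remaining absolute correlation fixes a pair,
#' whose row and column leave the pool; repeat until every temporal source
#' has a unique spatial partner. Pairing a mixing column j also pairs
#' spatial source (row) j. Ties break to the lexicographically lowest
#' (temporal index, spatial index).
#'
#' @param temporal,spatial `decomposition` objects with equal numbers of
#'   sources.
#' @param cfg the [transfer_config()] describing the linkage.
#' @return a `match_result`: `permutation[r]` is the spatial source index
#'   paired with temporal source r; `match_correlations` are the absolute
#'   correlations in greedy pick order (non-increasing); `pick_order` the
#'   temporal indices in that order; `realization_index` copied from input.
#' @export
match_realization <- function(temporal, spatial, cfg) {
  n_c <- nrow(temporal$sources)
  if (nrow(spatial$sources) != n_c) {
    stop("temporal and spatial decompositions must have equal source counts")
  }
  n_frames <- nrow(spatial$mixing)
  transformed <- t(apply(temporal$sources, 1L,
                         function(s) as.numeric(apply_transfer(s, cfg))))
  if (ncol(transformed) != n_frames) {
    stop(sprintf(
      paste0("transformed temporal sources have length %d but spatial ",
             "mixing columns have length %d (q = %d); adjust q/dt"),
      ncol(transformed), n_frames, cfg$q))
  }
  cm <- correlation_matrix(transformed, spatial$mixing)
  greedy_match(cm, realization_index = temporal$realization_index %||% NA)
}

# Greedy nondegenerate assignment on an absolute-correlation matrix.
greedy_match <- function(cm, realization_index = NA) {
  n_c <- nrow(cm)
  perm <- integer(n_c)
  cors <- numeric(n_c)
  order_t <- integer(n_c)
  work <- cm
  for (round in seq_len(n_c)) {
    # row-major scan => ties break to lowest (temporal, spatial) index
    best <- -Inf; bi <- bj <- NA_integer_
    for (i in seq_len(n_c)) {
      if (!is.finite(work[i, 1]) && all(!is.finite(work[i, ]))) next
      for (j in seq_len(n_c)) {
        v <- work[i, j]
        if (is.finite(v) && v > best) {
          best <- v; bi <- i; bj <- j
        }
      }
    }
    perm[bi] <- bj
    cors[round] <- best
    order_t[round] <- bi
    work[bi, ] <- -Inf
    work[, bj] <- -Inf
  }
  structure(
    list(permutation = perm, match_correlations = cors,
         pick_order = order_t, realization_index = realization_index),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: %d pairs, correlations %s>\n",
              length(x$permutation),
              paste(sprintf("%.3f", x$match_correlations), collapse = " ")))
  invisible(x)
}
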