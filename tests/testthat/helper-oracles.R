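# Independent oracles used by the clustering and matching tests. These are
# deliberately brute-force and share no code with the implementation.

# Global explained variance of the best partition of the rows of `maps` into
# exactly K clusters, by exhaustive enumeration of set partitions. For each
# block the optimal sign-invariant prototype contributes the top eigenvalue
# of the block's scatter matrix.
oracle_partition_gev <- function(maps, K) {
  X <- maps - rowMeans(maps)
  M <- nrow(X)
  denom <- sum(X^2)
  best <- -Inf
  recurse <- function(i, lab, nblocks) {
    if (i > M) {
      if (nblocks == K) {
        g <- 0
        for (k in seq_len(K)) {
          Xk <- X[lab == k, , drop = FALSE]
          g <- g + max(eigen(crossprod(Xk), symmetric = TRUE,
                             only.values = TRUE)$values)
        }
        if (g / denom > best) best <<- g / denom
      }
      return(invisible(NULL))
    }
    for (k in seq_len(min(nblocks + 1L, K))) {
      lab[i] <- k
      recurse(i + 1L, lab, max(nblocks, k))
    }
  }
  recurse(1L, integer(M), 0L)
  best
}

# All permutations of 1..n, written independently of the package's version.
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Best one-to-one matching of fitted rows to reference rows by total absolute
# correlation, solved by scanning every permutation.
oracle_best_matching <- function(fitted, reference) {
  fn <- fitted / sqrt(rowSums(fitted^2))
  rn <- reference / sqrt(rowSums(reference^2))
  C <- abs(fn %*% t(rn))
  best <- NULL; best_score <- -Inf
  for (p in oracle_perms(nrow(C))) {
    s <- sum(C[cbind(p, seq_along(p))])
    if (s > best_score) { best_score <- s; best <- p }
  }
  best
}

# Mann-Whitney U for x by direct enumeration of all pairwise comparisons.
oracle_u_statistic <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# Zero-mean and unit-normalize the rows of a topography matrix.
normalize_rows <- function(m) {
  if (!is.matrix(m)) m <- t(m)
  m <- m - rowMeans(m)
  m / sqrt(rowSums(m^2))
}

# A segmentation built directly from a label vector (fit = 1 everywhere).
toy_seg <- function(labels, fs = 200, epoch_starts = 1L, K = max(labels)) {
  ms_segmentation(labels, rep(1, length(labels)), fs = fs,
                  epoch_starts = epoch_starts, K = K)
}

# A small synthetic average-referenced recording with known ground truth.
toy_synth <- function(K = 4, duration_s = 20, snr = 5, seed = 7,
                      templates_seed = 42, fs = 200) {
  tm <- make_templates(K = K, seed = templates_seed)
  tr <- ground_truth(tm, snr = snr)
  sim <- synthesize_eeg(tr, duration_s = duration_s, fs = fs, seed = seed)
  list(rec = average_reference(sim$rec), truth = sim$truth, templates = tm)
}
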