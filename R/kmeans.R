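#' Microstate model container
#'
#' @param maps K x n_channels matrix of prototype topographies; rows are
#'   zero-meaned and unit-normalized on construction.
#' @param labels class names, default `A, B, C, ...`.
#' @return object of class `microstate_model` with fields `maps`, `labels`,
#'   `K`, `polarity_invariant` (always TRUE: spontaneous-EEG microstate
#'   similarity ignores map sign).
#' @export
microstate_model <- function(maps, labels = LETTERS[seq_len(nrow(maps))]) {
  maps <- normalize_maps(as.matrix(maps))
  if (anyDuplicated(labels)) stop("class labels must be distinct")
  if (length(labels) != nrow(maps)) stop("one label per map required")
  rownames(maps) <- labels
  structure(list(maps = maps, labels = labels, K = nrow(maps),
                 polarity_invariant = TRUE),
            class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> K = %d (%s), %d channels\n",
              x$K, paste(x$labels, collapse = ""), ncol(x$maps)))
  invisible(x)
}

# Zero-mean the rows of a topography matrix (average reference per map).
center_rows <- function(x) x - rowMeans(x)

#' Modified K-means clustering of topographies
#'
#' K-means variant for EEG topographies: similarity between a map and a
#' prototype is the squared spatial correlation (so polarity is ignored), and
#' the prototype update is the first principal direction of the maps assigned
#' to the cluster (the sign-invariant analogue of the mean), re-normalized to
#' zero mean and unit norm. The objective is the global explained variance
#' (GEV) of the input maps; the best of `n_restarts` random initializations
#' is returned.
#'
#' @param maps M x n_channels matrix of (typically GFP-peak) topographies.
#' @param K number of clusters, `2 <= K <= M` (K = 1 is allowed and fits a
#'   single principal direction).
#' @param n_restarts random restarts (default 20).
#' @param max_iter iteration cap per restart (default 100).
#' @param tol stop when the relative GEV improvement falls below this
#'   (default 1e-6).
#' @param seed integer seed; the fit is deterministic given `seed`.
#' @return list with `model` (`microstate_model`), `gev` (fraction in
#'   \[0, 1\]), and `assignments` (per-input-map cluster index).
#' @export
modified_kmeans <- function(maps, K, n_restarts = 20, max_iter = 100,
                            tol = 1e-6, seed = 1) {
  X <- center_rows(as.matrix(maps))
  M <- nrow(X)
  if (K > M) stop("K = ", K, " exceeds the number of maps (", M, ")")
  if (K < 1) stop("K must be positive")
  denom <- sum(X^2)
  if (denom == 0) stop("all input maps are zero")
  set.seed(as.integer(seed))

  best <- list(gev = -Inf)
  for (r in seq_len(n_restarts)) {
    # alternate between seeding from K observed maps and from the principal
    # directions of a random partition; the two reach different basins
    P <- if (r %% 2 == 1) {
      normalize_maps(X[sample.int(M, K), , drop = FALSE])
    } else {
      lab0 <- c(sample.int(K), sample.int(K, M - K, replace = TRUE))[sample.int(M)]
      prototype_update(X, lab0, K)
    }
    gev_old <- -Inf
    lab <- rep(1L, M)
    for (it in seq_len(max_iter)) {
      S2 <- (X %*% t(P))^2                     # M x K squared projections
      lab <- max.col(S2, ties.method = "first")
      fit_num <- S2[cbind(seq_len(M), lab)]
      # re-seed each empty cluster from the worst-fitted map, stealing only
      # from clusters that keep at least one member
      for (k in which(tabulate(lab, K) == 0)) {
        eligible <- which(tabulate(lab, K)[lab] > 1)
        if (length(eligible) == 0) break
        rel <- fit_num[eligible] / pmax(rowSums(X[eligible, , drop = FALSE]^2),
                                        .Machine$double.eps)
        worst <- eligible[which.min(rel)]
        lab[worst] <- k
        fit_num[worst] <- sum(X[worst, ]^2)    # provisional: own direction
      }
      P <- prototype_update(X, lab, K, previous = P)
      S2 <- (X %*% t(P))^2
      lab <- max.col(S2, ties.method = "first")
      gev <- sum(S2[cbind(seq_len(M), lab)]) / denom
      if (is.finite(gev_old) && (gev - gev_old) < tol * max(gev_old, .Machine$double.eps)) break
      gev_old <- gev
    }
    if (gev > best$gev) best <- list(gev = gev, P = P, lab = lab)
  }
  list(model = microstate_model(best$P), gev = best$gev, assignments = best$lab)
}

# First principal direction of each cluster's maps, unit-norm zero-mean. A
# cluster that is still empty (more clusters than assignable maps) keeps its
# previous prototype.
prototype_update <- function(X, lab, K, previous = NULL) {
  P <- matrix(0, K, ncol(X))
  for (k in seq_len(K)) {
    Xk <- X[lab == k, , drop = FALSE]
    if (nrow(Xk) == 0) {
      if (is.null(previous)) stop("cannot seed ", K, " clusters from these maps")
      P[k, ] <- previous[k, ]
    } else if (nrow(Xk) == 1) {
      P[k, ] <- Xk
    } else {
      P[k, ] <- eigen(crossprod(Xk), symmetric = TRUE)$vectors[, 1]
    }
  }
  normalize_maps(P)
}

#' Fit group-level prototypes from a set of recordings
#'
#' Pools the highest-GFP peak topographies from every recording (up to
#' `peaks_per_subject` per recording), clusters the pooled set with
#' [modified_kmeans()], and orders/labels the result against reference
#' templates. This mirrors the two-step group analysis in which all subjects'
#' data are aggregated into a single dataset to derive shared prototypes.
#'
#' @param recordings list of `eeg_recording`s on one common montage.
#' @param K number of classes (default 4).
#' @param peaks_per_subject cap on peak maps taken per recording
#'   (default 1000; the highest-GFP peaks are kept).
#' @param seed integer seed for the clustering restarts.
#' @param reference_maps templates used by [order_classes()] for labeling;
#'   default the canonical A-D(-E, -F) maps when the montage has known 10-20
#'   positions, otherwise no reordering.
#' @param ... passed to [modified_kmeans()].
#' @return list with `model`, `gev` (GEV on the pooled peak maps), and
#'   `n_peaks` (pooled peak count).
#' @export
aggregate_group_prototypes <- function(recordings, K = 4, peaks_per_subject = 1000,
                                       seed = 1, reference_maps = NULL, ...) {
  if (length(recordings) < 1) stop("need at least one recording")
  mont <- recordings[[1]]$montage
  same <- vapply(recordings, function(r) identical(r$montage$channel_names,
                                                  mont$channel_names), logical(1))
  if (!all(same)) stop("all recordings must share one montage")
  peak_maps <- lapply(recordings, function(rec) {
    g <- global_field_power(rec)
    pk <- detect_gfp_peaks(g)
    if (length(pk) == 0) return(NULL)
    if (length(pk) > peaks_per_subject) {
      pk <- pk[order(g$values[pk], decreasing = TRUE)[seq_len(peaks_per_subject)]]
    }
    center_rows(rec$data[pk, , drop = FALSE])
  })
  pooled <- do.call(rbind, peak_maps)
  if (is.null(pooled) || nrow(pooled) < K) stop("too few GFP peaks pooled to fit K = ", K)
  fit <- modified_kmeans(pooled, K = K, seed = seed, ...)
  if (is.null(reference_maps) && K <= 6 &&
      all(mont$channel_names %in% rownames(positions_1020()))) {
    reference_maps <- canonical_templates(mont, K)
  }
  if (!is.null(reference_maps)) fit$model <- order_classes(fit$model, reference_maps)
  list(model = fit$model, gev = fit$gev, n_peaks = nrow(pooled))
}

#' Order and label fitted classes against reference templates
#'
#' Finds the one-to-one assignment of fitted maps to reference maps that
#' maximizes the total absolute spatial correlation, by exhaustive search over
#' all K! permutations (K <= 8), and reorders/renames the model accordingly.
#'
#' @param model `microstate_model`.
#' @param reference_maps K x n_channels matrix of reference templates; its
#'   rownames (or `A, B, ...`) become the class labels.
#' @return re-ordered `microstate_model`.
#' @export
order_classes <- function(model, reference_maps) {
  R <- normalize_maps(as.matrix(reference_maps))
  K <- model$K
  if (nrow(R) != K) stop("reference has ", nrow(R), " maps but model has K = ", K)
  if (K > 8) stop("exhaustive ordering supported for K <= 8")
  C <- abs(model$maps %*% t(R))        # |spatial correlation|, unit-norm rows
  perms <- permutations(K)
  scores <- apply(perms, 1, function(p) sum(C[cbind(p, seq_len(K))]))
  p <- perms[which.max(scores), ]      # p[j] = model row assigned to reference j
  labels <- rownames(R)
  if (is.null(labels)) labels <- LETTERS[seq_len(K)]
  microstate_model(model$maps[p, , drop = FALSE], labels = labels)
}

# All permutations of 1..n as rows (n! x n); n is small (<= 8).
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    out[rows, -1] <- ifelse(sub >= i, sub + 1L, sub)
  }
  out
}
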