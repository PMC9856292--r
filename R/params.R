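#' Maximal constant-label segments of a segmentation
#'
#' Runs of constant class label, computed within each epoch (a run never
#' spans an epoch boundary).
#'
#' @param seg `ms_segmentation`.
#' @return data.frame with columns `class` (index), `start` (1-based sample),
#'   `length` (samples), `at_boundary` (touches an epoch edge).
#' @export
segments_of <- function(seg) {
  segments_of_labels(seg$labels, seg$epoch_starts, length(seg$labels))
}

#' Temporal microstate parameters
#'
#' Per class: mean duration (ms) of its segments, occurrence (segments per
#' second of labeled time), and coverage (fraction of samples). Segments
#' touching epoch boundaries are included, which preserves the exact identity
#' `coverage = occurrence * duration` (in consistent units). Classes absent
#' from the segmentation get zeros.
#'
#' @param seg `ms_segmentation`.
#' @return data.frame with one row per class: `class`, `duration_ms`,
#'   `occurrence_per_s`, `coverage`.
#' @export
temporal_parameters <- function(seg) {
  n <- length(seg$labels)
  if (n == 0) stop("empty segmentation")
  runs <- segments_of(seg)
  total_s <- n / seg$fs
  out <- data.frame(class = seg$class_labels,
                    duration_ms = 0, occurrence_per_s = 0, coverage = 0)
  for (k in seq_len(seg$K)) {
    rk <- runs$length[runs$class == k]
    if (length(rk) > 0) {
      out$duration_ms[k] <- mean(rk) * 1000 / seg$fs
      out$occurrence_per_s[k] <- length(rk) / total_s
    }
    out$coverage[k] <- sum(seg$labels == k) / n
  }
  out
}

#' Between-class transition syntax
#'
#' Counts every within-epoch consecutive pair of samples with differing
#' labels as one directed transition, and normalizes the counts by the grand
#' total of between-class transitions (a single normalization over the whole
#' off-diagonal, not per row).
#'
#' @param seg `ms_segmentation`.
#' @return object of class `ms_transitions`: `counts` (K x K integer,
#'   diagonal 0), `probs` (K x K, off-diagonal sums to 1; all-`NA` when there
#'   are no transitions), `n_transitions`.
#' @export
transition_syntax <- function(seg) {
  K <- seg$K
  counts <- matrix(0L, K, K, dimnames = list(seg$class_labels, seg$class_labels))
  n <- length(seg$labels)
  ep_end <- c(seg$epoch_starts[-1] - 1L, n)
  for (e in seq_along(seg$epoch_starts)) {
    idx <- seg$epoch_starts[e]:ep_end[e]
    if (length(idx) < 2) next
    from <- seg$labels[idx[-length(idx)]]
    to <- seg$labels[idx[-1]]
    keep <- from != to
    if (any(keep)) {
      tab <- table(factor(from[keep], levels = seq_len(K)),
                   factor(to[keep], levels = seq_len(K)))
      counts <- counts + array(as.integer(tab), dim = c(K, K))
    }
  }
  total <- sum(counts)
  probs <- if (total > 0) counts / total else matrix(NA_real_, K, K)
  dimnames(probs) <- dimnames(counts)
  structure(list(counts = counts, probs = probs, n_transitions = total),
            class = "ms_transitions")
}

#' @export
print.ms_transitions <- function(x, ...) {
  cat("<ms_transitions> ", x$n_transitions, " between-class transitions\n", sep = "")
  print(round(x$probs, 4))
  invisible(x)
}

#' Directed rates for each unordered class pair
#'
#' Extracts, for every unordered pair \{X, Y\}, the normalized forward
#' (X to Y) and backward (Y to X) transition probabilities — the quantities
#' compared when asking whether traffic between two classes changed.
#'
#' @param tm `ms_transitions`.
#' @return data.frame with columns `from`, `to`, `prob`, one row per ordered
#'   off-diagonal pair (K(K-1) rows).
#' @export
symmetric_pair_rates <- function(tm) {
  K <- nrow(tm$probs)
  labels <- rownames(tm$probs)
  out <- expand.grid(from = seq_len(K), to = seq_len(K))
  out <- out[out$from != out$to, ]
  data.frame(from = labels[out$from], to = labels[out$to],
             prob = tm$probs[cbind(out$from, out$to)])
}
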