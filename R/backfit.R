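#' Segmentation container
#'
#' @param labels integer vector of per-sample class indices (1..K).
#' @param fit per-sample squared spatial correlation to the assigned map,
#'   in \[0, 1\].
#' @param fs sampling rate in Hz.
#' @param epoch_starts 1-based start indices of the epochs making up the
#'   label sequence; transitions are never counted across these boundaries.
#' @param K number of classes.
#' @param class_labels class names (default `A, B, ...`).
#' @return object of class `ms_segmentation`.
#' @export
ms_segmentation <- function(labels, fit, fs, epoch_starts = 1L, K = max(labels),
                            class_labels = LETTERS[seq_len(K)]) {
  labels <- as.integer(labels)
  if (length(fit) != length(labels)) stop("labels and fit lengths differ")
  if (any(fit < -1e-12 | fit > 1 + 1e-12)) stop("fit values must lie in [0, 1]")
  if (any(labels < 1 | labels > K)) stop("labels out of range 1..K")
  structure(list(labels = labels, fit = pmin(pmax(fit, 0), 1), fs = fs,
                 epoch_starts = sort(unique(as.integer(epoch_starts))),
                 K = as.integer(K), class_labels = class_labels),
            class = "ms_segmentation")
}

#' @export
print.ms_segmentation <- function(x, ...) {
  cat(sprintf("<ms_segmentation> %d samples @ %g Hz, K = %d, %d epoch(s)\n",
              length(x$labels), x$fs, x$K, length(x$epoch_starts)))
  invisible(x)
}

#' Back-fit prototype maps to a recording
#'
#' Labels every sample with the class whose prototype has the largest squared
#' spatial correlation with the sample's topography (polarity ignored). Ties
#' are broken toward the previous sample's label, else the lowest class
#' index. A zero-GFP sample carries the previous label (class 1 at the start)
#' with fit 0.
#'
#' @param model `microstate_model`.
#' @param rec `eeg_recording` on the model's montage width; average
#'   referencing is applied internally if needed.
#' @param epoch_starts epoch boundary bookkeeping passed through to the
#'   segmentation (default: one epoch).
#' @return `ms_segmentation`.
#' @export
backfit <- function(model, rec, epoch_starts = 1L) {
  if (ncol(rec$data) != ncol(model$maps)) {
    stop("recording has ", ncol(rec$data), " channels; model expects ", ncol(model$maps))
  }
  X <- center_rows(rec$data)
  n <- nrow(X)
  norm2 <- rowSums(X^2)
  S2 <- (X %*% t(model$maps))^2
  lab <- max.col(S2, ties.method = "first")
  # tie-break toward the previous label; zero-GFP samples inherit it
  rowmax <- S2[cbind(seq_len(n), lab)]
  tied <- which(rowSums(S2 == rowmax) > 1L | norm2 == 0)
  for (t in tied) {                 # ascending, so lab[t - 1] is already final
    prev <- if (t == 1L) 1L else lab[t - 1L]
    if (norm2[t] == 0 || S2[t, prev] == rowmax[t]) {
      lab[t] <- prev
    } else {
      lab[t] <- which(S2[t, ] == rowmax[t])[1]
    }
  }
  fit <- unname(ifelse(norm2 > 0,
                       S2[cbind(seq_len(n), lab)] / pmax(norm2, .Machine$double.eps), 0))
  ms_segmentation(lab, fit, fs = rec$fs, epoch_starts = epoch_starts,
                  K = model$K, class_labels = model$labels)
}

#' Temporally smooth a segmentation
#'
#' Absorbs segments shorter than `min_duration_ms` into a temporally adjacent
#' segment: the offending segment is relabeled to whichever neighbour has the
#' higher stored fit at the shared boundary, iterating until no short
#' internal segment remains. Segments touching an epoch boundary are left
#' untouched (their true extent is unknown). `min_duration_ms = 0` is the
#' identity.
#'
#' @param seg `ms_segmentation`.
#' @param min_duration_ms minimum segment duration in milliseconds
#'   (default 30).
#' @return smoothed `ms_segmentation`.
#' @export
smooth_segmentation <- function(seg, min_duration_ms = 30) {
  if (min_duration_ms < 0) stop("min_duration_ms must be >= 0")
  if (min_duration_ms == 0) return(seg)
  lab <- seg$labels
  n <- length(lab)
  ep_id <- rep(seq_along(seg$epoch_starts),
               diff(c(seg$epoch_starts, n + 1L)))
  max_pass <- length(rle(lab)$lengths) + 1L   # every pass removes >= 1 run
  for (pass in seq_len(max_pass)) {
    new_run <- c(TRUE, lab[-1] != lab[-n] | ep_id[-1] != ep_id[-n])
    starts <- which(new_run)
    lens <- diff(c(starts, n + 1L))
    R <- length(starts)
    ep_run <- ep_id[starts]
    internal <- logical(R)   # run has both neighbours within its own epoch
    if (R >= 3) {
      mid <- 2:(R - 1)
      internal[mid] <- ep_run[mid - 1] == ep_run[mid] & ep_run[mid + 1] == ep_run[mid]
    }
    short <- which(internal & lens * 1000 / seg$fs < min_duration_ms)
    if (length(short) == 0) break
    # absorb shortest first; skip runs whose neighbours were touched this pass
    touched <- logical(length(starts))
    for (s in short[order(lens[short])]) {
      if (touched[s] || touched[s - 1L] || touched[s + 1L]) next
      left <- starts[s] - 1L                 # last sample of left neighbour
      right <- starts[s] + lens[s]           # first sample of right neighbour
      target <- if (seg$fit[left] >= seg$fit[right]) lab[left] else lab[right]
      lab[starts[s]:(right - 1L)] <- target
      touched[(s - 1L):(s + 1L)] <- TRUE
    }
  }
  ms_segmentation(lab, seg$fit, fs = seg$fs, epoch_starts = seg$epoch_starts,
                  K = seg$K, class_labels = seg$class_labels)
}

# Run-length segments of a label vector, split at epoch boundaries.
# Returns data.frame(class, start, length, at_boundary) where at_boundary
# flags runs touching an epoch start or end.
segments_of_labels <- function(lab, epoch_starts, n) {
  ep_end <- c(epoch_starts[-1] - 1L, n)
  out <- vector("list", length(epoch_starts))
  for (e in seq_along(epoch_starts)) {
    idx <- epoch_starts[e]:ep_end[e]
    r <- rle(lab[idx])
    start <- epoch_starts[e] + c(0L, cumsum(r$lengths[-length(r$lengths)]))
    out[[e]] <- data.frame(
      class = r$values, start = start, length = r$lengths,
      at_boundary = seq_along(r$values) == 1L | seq_along(r$values) == length(r$values)
    )
  }
  do.call(rbind, out)
}

#' Global explained variance of a segmentation
#'
#' GEV is the GFP-squared-weighted mean squared spatial correlation between
#' each sample and its assigned prototype:
#' `GEV = sum_t (GFP_t * r_t)^2 / sum_t GFP_t^2`. Per-class values restrict
#' the numerator to that class's samples, so they sum to the total.
#'
#' @param model `microstate_model`.
#' @param rec the segmented `eeg_recording`.
#' @param seg its `ms_segmentation` (labels are used; fit is recomputed from
#'   the recording so that smoothing does not stale the result).
#' @return list with `total` and named `per_class` fractions.
#' @export
global_explained_variance <- function(model, rec, seg) {
  X <- center_rows(rec$data)
  if (nrow(X) != length(seg$labels)) stop("recording and segmentation lengths differ")
  norm2 <- rowSums(X^2)
  if (all(norm2 == 0)) stop("GEV undefined for an all-zero recording")
  # (GFP_t r_t)^2 = <x_t, p_label>^2 / N and GFP_t^2 = |x_t|^2 / N
  proj2 <- (X %*% t(model$maps))^2
  num_t <- proj2[cbind(seq_along(seg$labels), seg$labels)]
  denom <- sum(norm2)
  per_class <- vapply(seq_len(model$K), function(k) {
    sum(num_t[seg$labels == k]) / denom
  }, numeric(1))
  names(per_class) <- model$labels
  list(total = sum(per_class), per_class = per_class)
}
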