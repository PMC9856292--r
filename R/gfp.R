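#' Global field power
#'
#' GFP at each sample is the spatial standard deviation of the instantaneous
#' voltage across channels (population SD, i.e. divisor N). Peaks of GFP mark
#' moments of maximal topographic signal-to-noise and are the standard input
#' to microstate clustering.
#'
#' @param rec `eeg_recording`. If not average-referenced the channel mean is
#'   removed internally (GFP is reference-invariant by definition).
#' @return object of class `ms_gfp`: `values` (non-negative, uV) and `fs`.
#' @export
global_field_power <- function(rec) {
  x <- rec$data - rowMeans(rec$data)
  structure(list(values = sqrt(rowSums(x^2) / ncol(x)), fs = rec$fs),
            class = "ms_gfp")
}

#' Detect GFP peaks
#'
#' Local maxima `gfp[t-1] < gfp[t] >= gfp[t+1]`, thinned so that any two
#' retained peaks are at least `min_separation_ms` apart; when two candidate
#' peaks are closer, the larger is kept.
#'
#' @param gfp `ms_gfp` (or numeric vector with attribute-free use via `fs`).
#' @param min_separation_ms minimum peak separation in milliseconds
#'   (default 10).
#' @param fs sampling rate, taken from `gfp` when it is an `ms_gfp`.
#' @return integer vector of peak sample indices (possibly empty), ascending.
#' @export
detect_gfp_peaks <- function(gfp, min_separation_ms = 10, fs = NULL) {
  if (inherits(gfp, "ms_gfp")) {
    v <- gfp$values
    fs <- gfp$fs
  } else {
    v <- as.numeric(gfp)
    if (is.null(fs)) stop("fs required when gfp is a bare vector")
  }
  n <- length(v)
  if (n < 3) stop("need at least 3 samples to define a peak")
  i <- 2:(n - 1)
  cand <- i[v[i - 1] < v[i] & v[i] >= v[i + 1]]
  if (length(cand) == 0) return(integer(0))
  min_gap <- min_separation_ms / 1000 * fs
  if (min_gap <= 0 || length(cand) == 1) return(cand)
  # greedy by amplitude: keep the larger of any pair closer than min_gap
  ord <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
  }
  sort(kept)
}
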