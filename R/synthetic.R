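#' Ground truth for a synthetic microstate EEG
#'
#' Bundles everything the generator plants into a recording: the template
#' topographies, the semi-Markov dynamics (embedded transition matrix and
#' per-class mean dwell times), and the signal-to-noise ratio, defined as the
#' ratio of mean signal GFP to mean noise GFP.
#'
#' @param templates K x n_channels matrix; rows are zero-meaned and
#'   unit-normalized.
#' @param transition_probs K x K row-stochastic matrix with zero diagonal
#'   (default: uniform over the other classes).
#' @param mean_dwell_ms per-class expected dwell time in ms (recycled to K).
#'   Default 85, 85, 75, 95 ms for K = 4 — dwell times in the range observed
#'   in clinical resting EEG; otherwise 80 ms.
#' @param snr signal-GFP / noise-GFP ratio, > 0 (may be `Inf`); default 5.
#' @param dwell_law `"geometric"` (truncated geometric, minimum 2 samples) or
#'   `"fixed"` (deterministic dwell).
#' @return object of class `ms_ground_truth`.
#' @export
ground_truth <- function(templates,
                         transition_probs = NULL,
                         mean_dwell_ms = NULL,
                         snr = 5,
                         dwell_law = c("geometric", "fixed")) {
  dwell_law <- match.arg(dwell_law)
  templates <- normalize_maps(as.matrix(templates))
  K <- nrow(templates)
  if (is.null(transition_probs)) {
    transition_probs <- matrix(1 / (K - 1), K, K)
    diag(transition_probs) <- 0
  }
  transition_probs <- as.matrix(transition_probs)
  if (any(diag(transition_probs) != 0)) stop("transition matrix diagonal must be 0")
  if (any(transition_probs < 0) || max(abs(rowSums(transition_probs) - 1)) > 1e-9) {
    stop("transition matrix rows must be non-negative and sum to 1")
  }
  if (is.null(mean_dwell_ms)) {
    mean_dwell_ms <- if (K == 4) c(85, 85, 75, 95) else rep(80, K)
  }
  mean_dwell_ms <- rep_len(mean_dwell_ms, K)
  if (any(mean_dwell_ms <= 0)) stop("mean_dwell_ms must be positive")
  if (!(snr > 0)) stop("snr must be positive (use Inf for noise-free)")
  structure(list(templates = templates, transition_probs = transition_probs,
                 mean_dwell_ms = mean_dwell_ms, snr = snr,
                 dwell_law = dwell_law, label_sequence = NULL),
            class = "ms_ground_truth")
}

#' Random average-referenced template maps
#'
#' Draws K mutually distinct zero-mean unit-norm topographies with pairwise
#' absolute spatial correlation at most 0.7, regenerating until the
#' constraint holds.
#'
#' @param mont montage.
#' @param K number of maps, `2 <= K < n_channels` (K = 1 allowed for toys).
#' @param seed integer seed.
#' @param max_abs_cor pairwise correlation ceiling (default 0.7).
#' @return K x n_channels matrix with class-letter rownames.
#' @export
make_templates <- function(mont = montage(), K = 4, seed = 1, max_abs_cor = 0.7) {
  if (K >= mont$n_channels) {
    stop("K must be smaller than the channel count (", mont$n_channels, ")")
  }
  if (K < 1) stop("K must be positive")
  set.seed(as.integer(seed))
  for (try in seq_len(1000)) {
    maps <- normalize_maps(matrix(stats::rnorm(K * mont$n_channels), K))
    cc <- abs(maps %*% t(maps))
    if (K == 1 || max(cc[upper.tri(cc)]) <= max_abs_cor) {
      dimnames(maps) <- list(LETTERS[seq_len(K)], mont$channel_names)
      return(maps)
    }
  }
  stop("could not satisfy the pairwise correlation constraint")
}

#' Simulate a semi-Markov class-label sequence
#'
#' Dwell lengths are drawn per class (truncated geometric with minimum
#' 2 samples, or deterministic) with the requested mean; the successor class
#' is drawn from the embedded transition matrix.
#'
#' @param truth `ms_ground_truth`.
#' @param duration_s sequence length in seconds.
#' @param fs sampling rate in Hz (default 200).
#' @param seed integer seed.
#' @return integer vector of length `round(duration_s * fs)` with values in
#'   1..K.
#' @export
simulate_label_sequence <- function(truth, duration_s, fs = 200, seed = 1) {
  n <- round(duration_s * fs)
  if (n < 1) stop("duration_s * fs must be at least 1 sample")
  K <- nrow(truth$templates)
  mean_samples <- truth$mean_dwell_ms / 1000 * fs
  if (truth$dwell_law == "geometric" && any(mean_samples <= 2)) {
    stop("geometric dwell needs mean dwell > 2 samples at this fs")
  }
  set.seed(as.integer(seed))
  lab <- integer(n)
  state <- sample.int(K, 1, prob = stationary_distribution(truth))
  pos <- 1L
  while (pos <= n) {
    d <- if (truth$dwell_law == "fixed") {
      round(mean_samples[state])
    } else {
      2L + stats::rgeom(1, prob = 1 / (mean_samples[state] - 1))
    }
    end <- min(pos + d - 1L, n)
    lab[pos:end] <- state
    pos <- end + 1L
    state <- sample.int(K, 1, prob = truth$transition_probs[state, ])
  }
  lab
}

#' Stationary class distribution of the planted dynamics
#'
#' For a semi-Markov chain the long-run fraction of time in class k is
#' proportional to `nu_k * m_k`, where `nu` is the stationary distribution of
#' the embedded jump chain and `m_k` the mean dwell.
#'
#' @param truth `ms_ground_truth`.
#' @return probability vector of length K.
#' @export
stationary_distribution <- function(truth) {
  P <- truth$transition_probs
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  nu <- abs(Re(e$vectors[, i]))
  nu <- nu / sum(nu)
  pi_k <- nu * truth$mean_dwell_ms
  pi_k / sum(pi_k)
}

#' Synthesize a multichannel EEG with planted microstates
#'
#' Each sample is `a_t * s_t * template[L_t] + noise_t`: `L_t` the simulated
#' label sequence, `a_t` a strictly positive alpha-like amplitude envelope
#' (rectified 10 Hz sinusoid riding on a small floor, so GFP peaks about
#' every 50 ms and no sample is exactly zero), `s_t` a polarity sign that
#' flips on a slow random schedule (mean interval ~1 s; spontaneous-EEG
#' microstate analysis must be invariant to it), and spatially uncorrelated
#' Gaussian noise scaled so that mean signal GFP over mean noise GFP equals
#' `truth$snr`.
#'
#' @param truth `ms_ground_truth`.
#' @param duration_s recording length in seconds (default 360, i.e. the
#'   6-minute clinical minimum).
#' @param fs sampling rate in Hz (default 200).
#' @param seed integer seed.
#' @param mont montage for the recording (default 19-channel 10-20; must
#'   match the template width).
#' @param amplitude_uv peak envelope amplitude in microvolts (default 30).
#' @return list with `rec` (`eeg_recording`) and `truth` (input truth with
#'   `label_sequence` filled in).
#' @export
synthesize_eeg <- function(truth, duration_s = 360, fs = 200, seed = 1,
                           mont = montage(), amplitude_uv = 30) {
  if (ncol(truth$templates) != mont$n_channels) {
    stop("templates have ", ncol(truth$templates), " channels; montage has ",
         mont$n_channels)
  }
  lab <- simulate_label_sequence(truth, duration_s, fs, seed = seed)
  n <- length(lab)
  # RNG state continues past the label simulation; same seed => same recording
  tt <- (seq_len(n) - 1) / fs
  a <- amplitude_uv * (0.1 + abs(sin(2 * pi * 10 * tt)))
  flips <- stats::rbinom(n, 1, min(1, 1 / fs))           # mean interval ~1 s
  s <- ifelse(cumsum(flips) %% 2 == 0, 1, -1)
  signal <- (a * s) * truth$templates[lab, , drop = FALSE]
  if (is.finite(truth$snr)) {
    noise <- matrix(stats::rnorm(n * mont$n_channels), n)
    sig_gfp <- mean(sqrt(rowSums(center_rows(signal)^2) / ncol(signal)))
    noise_gfp <- mean(sqrt(rowSums(center_rows(noise)^2) / ncol(noise)))
    noise <- noise * sig_gfp / (noise_gfp * truth$snr)
    signal <- signal + noise
  }
  truth$label_sequence <- lab
  list(rec = eeg_recording(signal, fs = fs, mont = mont, reference = "raw"),
       truth = truth)
}
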