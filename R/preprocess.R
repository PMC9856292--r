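#' Power-line notch filter
#'
#' Zero-phase (forward-backward) second-order IIR notch. The default 50 Hz
#' removes mains interference from recordings made on a 50 Hz grid.
#'
#' @param rec `eeg_recording`.
#' @param freq notch centre frequency in Hz (default 50).
#' @param Q quality factor; bandwidth is `freq / Q` (default 30).
#' @return filtered `eeg_recording` (same reference state).
#' @export
notch_filter <- function(rec, freq = 50, Q = 30) {
  if (freq >= rec$fs / 2) stop("notch frequency must be below Nyquist (", rec$fs / 2, " Hz)")
  w0 <- 2 * pi * freq / rec$fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  apply_filter(rec, b, a)
}

#' Band-pass filter
#'
#' Zero-phase 4th-order Butterworth band-pass (order 2 applied forward and
#' backward). Defaults follow common clinical resting-EEG practice:
#' 0.1-40 Hz.
#'
#' @param rec `eeg_recording`.
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @return filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, lo = 0.1, hi = 40) {
  nyq <- rec$fs / 2
  if (!(lo > 0 && lo < hi && hi < nyq)) {
    stop("band edges must satisfy 0 < lo < hi < fs/2 = ", nyq)
  }
  bf <- signal::butter(2, c(lo, hi) / nyq, type = "pass")
  apply_filter(rec, bf$b, bf$a)
}

apply_filter <- function(rec, b, a) {
  out <- apply(rec$data, 2, function(ch) signal::filtfilt(signal::Arma(b = b, a = a), ch))
  eeg_recording(out, fs = rec$fs, mont = rec$montage, reference = "raw")
}

#' Average reference
#'
#' Subtracts each sample's mean over channels, so every topography becomes
#' zero-mean. Idempotent.
#'
#' @param rec `eeg_recording`.
#' @return `eeg_recording` with `reference = "average"`.
#' @export
average_reference <- function(rec) {
  eeg_recording(rec$data - rowMeans(rec$data), fs = rec$fs,
                mont = rec$montage, reference = "average")
}

#' Split a recording into epochs and reject by amplitude
#'
#' The recording is cut into consecutive non-overlapping epochs of
#' `epoch_s` seconds (a trailing remainder shorter than one epoch is
#' dropped). An epoch is kept iff no sample on any channel exceeds
#' `threshold_uv` in absolute value (+-150 uV by default).
#'
#' @param rec `eeg_recording`.
#' @param epoch_s epoch length in seconds (default 2).
#' @param threshold_uv rejection threshold in microvolts (default 150).
#' @return object of class `eeg_epochs`: list of equal-length epoch matrices,
#'   `kept_mask`, `fs`, `montage`, `reference`. Zero kept epochs is allowed;
#'   downstream concatenation signals it.
#' @export
reject_epochs <- function(rec, epoch_s = 2, threshold_uv = 150) {
  len <- round(epoch_s * rec$fs)
  if (len < 1) stop("epoch_s * fs must be at least 1 sample")
  n_ep <- nrow(rec$data) %/% len
  if (n_ep < 1) stop("recording shorter than one epoch")
  epochs <- lapply(seq_len(n_ep), function(i) {
    rec$data[((i - 1) * len + 1):(i * len), , drop = FALSE]
  })
  kept <- vapply(epochs, function(e) max(abs(e)) <= threshold_uv, logical(1))
  structure(list(epochs = epochs, kept_mask = kept, fs = rec$fs,
                 montage = rec$montage, reference = rec$reference),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs of %d samples @ %g Hz, %d kept\n",
              length(x$epochs), nrow(x$epochs[[1]]), x$fs, sum(x$kept_mask)))
  invisible(x)
}

#' Concatenate kept epochs back into one recording
#'
#' @param eps `eeg_epochs`.
#' @param kept_only drop rejected epochs (default TRUE).
#' @return list with `rec` (`eeg_recording`) and `epoch_starts` (1-based
#'   start index of each retained epoch in the concatenated recording), for
#'   transition counting that must not cross epoch boundaries.
#' @export
concatenate_epochs <- function(eps, kept_only = TRUE) {
  use <- if (kept_only) which(eps$kept_mask) else seq_along(eps$epochs)
  if (length(use) == 0) stop("no epochs kept: all rejected by amplitude threshold")
  len <- nrow(eps$epochs[[1]])
  mat <- do.call(rbind, eps$epochs[use])
  list(
    rec = eeg_recording(mat, fs = eps$fs, mont = eps$montage, reference = eps$reference),
    epoch_starts = (seq_along(use) - 1) * len + 1
  )
}

#' Standard preprocessing chain
#'
#' Notch, band-pass, epoch rejection, then average referencing of the kept
#' epochs, in that order.
#'
#' @param rec raw `eeg_recording`.
#' @param notch notch frequency in Hz, or `NULL` to skip.
#' @param bandpass length-2 numeric band edges in Hz, or `NULL` to skip.
#' @param epoch_s epoch length in seconds.
#' @param reject_uv amplitude rejection threshold in microvolts.
#' @return list with `rec` (average-referenced concatenated kept epochs),
#'   `epoch_starts`, and `kept_mask`.
#' @export
preprocess <- function(rec, notch = 50, bandpass = c(0.1, 40),
                       epoch_s = 2, reject_uv = 150) {
  if (!is.null(notch)) rec <- notch_filter(rec, notch)
  if (!is.null(bandpass)) rec <- bandpass_filter(rec, bandpass[1], bandpass[2])
  eps <- reject_epochs(rec, epoch_s = epoch_s, threshold_uv = reject_uv)
  cc <- concatenate_epochs(eps)
  list(rec = average_reference(cc$rec), epoch_starts = cc$epoch_starts,
       kept_mask = eps$kept_mask)
}
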