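#' EEG recording container
#'
#' @param data numeric matrix, samples x channels, in microvolts.
#' @param fs sampling rate in Hz.
#' @param mont montage whose channel count matches `ncol(data)`.
#' @param reference `"raw"` or `"average"`. When `"average"`, every sample's
#'   channel mean must be zero (within 1e-9 uV).
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, mont = montage(colnames(data)),
                          reference = c("raw", "average")) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  if (ncol(data) != mont$n_channels) {
    stop("data has ", ncol(data), " columns but montage has ", mont$n_channels, " channels")
  }
  colnames(data) <- mont$channel_names
  if (reference == "average" && nrow(data) > 0 &&
      max(abs(rowMeans(data))) > 1e-9) {
    stop("reference = 'average' but channel means are not zero")
  }
  structure(list(data = data, fs = fs, montage = mont, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels @ %g Hz (%.1f s), %s reference\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs, x$reference))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Read an EEG recording from disk
#'
#' CSV files must have a header row of channel labels and one row per sample;
#' values are taken as microvolts as-is. EDF files are read with the built-in
#' minimal EDF reader and physical units converted to microvolts. Channels are
#' reordered to match `mont`; a file missing a montage channel is an error.
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"`; default guessed from the file extension.
#' @param mont target montage; default the 19-channel 10-20 set for EDF-less
#'   CSV files is taken from the CSV header itself when `mont` is `NULL`.
#' @param fs sampling rate in Hz, required for CSV (EDF carries its own).
#' @return `eeg_recording` with `reference = "raw"`.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           mont = NULL, fs = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    if (is.null(fs)) stop("fs is required to read a CSV recording")
    df <- utils::read.csv(path, check.names = FALSE)
    mat <- as.matrix(df)
    labels <- colnames(mat)
  } else {
    edf <- read_edf(path)
    mat <- edf$data
    labels <- edf$labels
    fs <- edf$fs
  }
  if (is.null(mont)) mont <- montage(labels)
  missing <- setdiff(mont$channel_names, labels)
  if (length(missing) > 0) {
    stop("recording is missing montage channel(s): ", paste(missing, collapse = ", "))
  }
  mat <- mat[, mont$channel_names, drop = FALSE]
  eeg_recording(mat, fs = fs, mont = mont, reference = "raw")
}

#' Write an EEG recording to disk
#'
#' CSV output is samples x channels with a channel-label header. EDF output
#' quantizes each channel to 16 bits over its physical range.
#'
#' @param rec `eeg_recording`.
#' @param path destination path.
#' @param format `"csv"` or `"edf"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "csv") {
    utils::write.csv(as.data.frame(rec$data), path, row.names = FALSE)
  } else {
    write_edf(rec$data, fs = rec$fs, labels = rec$montage$channel_names, path = path)
  }
  invisible(path)
}
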