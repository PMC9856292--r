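#' Electrode montage
#'
#' A montage is an ordered set of unique channel labels. The default is the
#' 19-channel international 10-20 clinical set used by bedside EEG systems.
#'
#' @param channel_names character vector of unique channel labels.
#' @return An object of class `eeg_montage` with fields `channel_names` and
#'   `n_channels`.
#' @export
#' @examples
#' montage()            # default 19-channel 10-20 set
#' montage(c("C3", "C4"))
montage <- function(channel_names = channels_1020()) {
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names)) {
    stop("montage channel labels must be unique")
  }
  if (length(channel_names) < 1) stop("montage needs at least one channel")
  structure(
    list(channel_names = channel_names, n_channels = length(channel_names)),
    class = "eeg_montage"
  )
}

#' The 19-channel 10-20 label set
#'
#' Standard clinical montage ordering, occipital to frontopolar.
#' @return character vector of 19 labels.
#' @export
channels_1020 <- function() {
  c("O1", "O2", "P3", "P4", "Pz", "T5", "T6", "C3", "C4", "Cz",
    "T3", "T4", "F3", "F4", "Fz", "F7", "F8", "Fp1", "Fp2")
}

# Schematic 2D head coordinates (x: left -1 .. right +1, y: back -1 .. front +1)
# for the 10-20 labels; used only to synthesize canonical class topographies.
positions_1020 <- function() {
  pos <- rbind(
    O1  = c(-0.31, -0.95), O2  = c(0.31, -0.95),
    P3  = c(-0.41, -0.52), P4  = c(0.41, -0.52), Pz = c(0, -0.50),
    T5  = c(-0.81, -0.59), T6  = c(0.81, -0.59),
    C3  = c(-0.50,  0.00), C4  = c(0.50,  0.00), Cz = c(0,  0.00),
    T3  = c(-1.00,  0.00), T4  = c(1.00,  0.00),
    F3  = c(-0.41,  0.52), F4  = c(0.41,  0.52), Fz = c(0,  0.50),
    F7  = c(-0.81,  0.59), F8  = c(0.81,  0.59),
    Fp1 = c(-0.31,  0.95), Fp2 = c(0.31,  0.95)
  )
  colnames(pos) <- c("x", "y")
  pos
}

#' Canonical microstate class templates
#'
#' Idealized average-referenced topographies for the four classical resting
#' microstate classes on a 10-20 montage: class A has a left-right diagonal
#' orientation, class B the mirrored right-left diagonal, class C a
#' rostral-caudal (front-back) axis, and class D a fronto-central maximum.
#' For K = 5 or 6 two further synthetic orthogonalized maps are appended
#' (an occipital focus and a left-right lateral gradient). Rows are zero-mean
#' and unit-norm; polarity is arbitrary.
#'
#' @param mont montage; must contain only 10-20 labels with known positions.
#' @param K number of classes, 2..6 (default 4).
#' @return K x n_channels numeric matrix with class-letter rownames.
#' @export
canonical_templates <- function(mont = montage(), K = 4) {
  if (K < 2 || K > 6) stop("canonical templates defined for K in 2..6")
  pos <- positions_1020()
  missing <- setdiff(mont$channel_names, rownames(pos))
  if (length(missing) > 0) {
    stop("no canonical position for channel(s): ", paste(missing, collapse = ", "))
  }
  p <- pos[mont$channel_names, , drop = FALSE]
  x <- p[, "x"]; y <- p[, "y"]
  maps <- rbind(
    A = x + y,
    B = -x + y,
    C = y,
    D = exp(-((x^2 + (y - 0.3)^2) / 0.4)),
    E = exp(-((x^2 + (y + 0.8)^2) / 0.4)),
    F = x
  )[seq_len(K), , drop = FALSE]
  colnames(maps) <- mont$channel_names
  normalize_maps(maps)
}

# Zero-mean each row across channels and scale to unit Euclidean norm.
normalize_maps <- function(maps) {
  maps <- maps - rowMeans(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm == 0)) stop("degenerate (constant) map cannot be normalized")
  maps / nrm
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", x$n_channels, " channels: ",
      paste(x$channel_names, collapse = " "), "\n", sep = "")
  invisible(x)
}
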