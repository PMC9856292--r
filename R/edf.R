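# Minimal EDF (European Data Format) support: fixed-width ASCII header,
# 16-bit little-endian samples, one signal block per channel. Covers what a
# single continuous multichannel EEG needs: uniform sampling, physical units
# in uV, a single data record holding the whole recording on write, arbitrary
# equal-length records on read.

edf_field <- function(raw, from, n) {
  trimws(rawToChar(raw[from:(from + n - 1)]))
}

pad_field <- function(x, n) {
  s <- formatC(as.character(x), width = -n)
  if (nchar(s) > n) s <- substr(s, 1, n)
  s
}

# Read an EDF file. Returns list(data = samples x channels matrix in the
# file's physical units, fs, labels). Requires all signals to share one
# sampling rate (non-uniform multirate files are not supported).
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256)
  n_records <- as.integer(edf_field(hdr, 237, 8))
  record_dur <- as.numeric(edf_field(hdr, 245, 8))
  ns <- as.integer(edf_field(hdr, 253, 4))
  sig <- readBin(con, "raw", 256 * ns)
  fld <- function(off, w) {
    vapply(seq_len(ns), function(i) {
      edf_field(sig, off * ns + (i - 1) * w + 1, w)
    }, character(1))
  }
  labels <- fld(0, 16)
  pmin <- as.numeric(fld(104, 8))
  pmax <- as.numeric(fld(112, 8))
  dmin <- as.numeric(fld(120, 8))
  dmax <- as.numeric(fld(128, 8))
  spr  <- as.integer(fld(216, 8))
  if (length(unique(spr / record_dur)) != 1) {
    stop("unsupported EDF: signals have non-uniform sampling rates")
  }
  fs <- spr[1] / record_dur
  data <- matrix(0, nrow = n_records * spr[1], ncol = ns)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      phys <- (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
      data[(r - 1) * spr[1] + seq_len(spr[i]), i] <- phys
    }
  }
  colnames(data) <- labels
  list(data = data, fs = fs, labels = labels)
}

# Write a samples x channels matrix (uV) as a single-record EDF file.
write_edf <- function(data, fs, labels, path) {
  data <- as.matrix(data)
  ns <- ncol(data)
  n <- nrow(data)
  pmin <- apply(data, 2, min)
  pmax <- apply(data, 2, max)
  flat <- pmax - pmin < 1e-12   # widen degenerate ranges so scaling is defined
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32767; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8),
    pad_field("", 44),
    pad_field(1, 8),
    pad_field(format(n / fs, digits = 7), 8),
    pad_field(ns, 4)
  )
  sig <- paste0(
    paste(vapply(labels, pad_field, "", n = 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, function(v) pad_field(format(v, digits = 7), 8), ""), collapse = ""),
    paste(vapply(pmax, function(v) pad_field(format(v, digits = 7), 8), ""), collapse = ""),
    paste(rep(pad_field(dmin, 8), ns), collapse = ""),
    paste(rep(pad_field(dmax, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(n, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig), con, eos = NULL)
  for (i in seq_len(ns)) {
    dig <- round((data[, i] - pmin[i]) / (pmax[i] - pmin[i]) * (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}
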