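# Minimal 16-bit European Data Format (EDF) reader/writer.  Covers plain
# EDF with identical sampling rate across signals, which is all the
# pipeline needs; EDF+ annotations are not supported.

#' Read / write EDF recordings
#'
#' `read_edf()` parses a plain EDF file into an [eeg_recording()];
#' `write_edf()` writes one, using 1-second data records and a symmetric
#' per-channel physical range.  EDF stores samples as 16-bit integers, so a
#' write/read round trip is exact only to the per-channel quantization step
#' `(2 * max|x|) / 65534`.
#'
#' @param path file path.
#' @return `read_edf()` returns an `eeg_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rchar <- function(n) rawToChar(readBin(con, "raw", n))
  trim <- function(s) sub("\\s+$", "", s)
  rchar(8)                                   # version
  patient <- trim(rchar(80))
  rchar(80); rchar(8); rchar(8); rchar(8); rchar(44)
  n_rec <- as.integer(rchar(8))
  rec_dur <- as.numeric(rchar(8))
  ns <- as.integer(rchar(4))
  if (!is.finite(ns) || ns < 1) stop("EDF header: bad signal count")
  fld <- function(w) vapply(seq_len(ns), function(i) trim(rchar(w)), "")
  labels <- fld(16)
  fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr)) != 1L)
    stop("EDF: signals with differing sampling rates are not supported")
  spr1 <- spr[1L]
  data <- matrix(0, nrow = ns, ncol = n_rec * spr1)
  for (r in seq_len(n_rec)) {
    blk <- readBin(con, integer(), n = ns * spr1, size = 2L,
                   endian = "little", signed = TRUE)
    cols <- ((r - 1L) * spr1 + 1L):(r * spr1)
    data[, cols] <- t(matrix(blk, nrow = spr1, ncol = ns))
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  data <- (data - dmin) * scale + pmin
  eeg_recording(subject_id = if (nzchar(patient)) patient else "unknown",
                fs = spr1 / rec_dur, data = data, lead_names = labels)
}

#' @rdname read_edf
#' @param rec an `eeg_recording`; its sampling rate must be a whole number
#'   of samples per second.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate; use the delimited dialect")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_samp <- ncol(rec$data)
  n_rec <- n_samp %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF data record (1 s)")
  if (n_samp %% fs != 0L)
    warning("dropping ", n_samp %% fs, " trailing samples (partial EDF record)")
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmax <- apply(abs(x), 1L, max)
  pmax[pmax == 0] <- 1
  dig <- round(sweep(x, 1L, pmax, "/") * 32767)
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, w) {
    s <- substr(paste0(s, strrep(" ", w)), 1L, w)
    writeBin(charToRaw(s), con)
  }
  put("0", 8); put(rec$subject_id, 80); put("strokecoh", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(as.character(256L + ns * 256L), 8); put("", 44)
  put(as.character(n_rec), 8); put("1", 8); put(as.character(ns), 4)
  for (l in rec$lead_names) put(l, 16)
  for (i in seq_len(ns)) put("", 80)              # transducer
  for (i in seq_len(ns)) put("uV", 8)
  for (i in seq_len(ns)) put(.edf_num(-pmax[i]), 8)
  for (i in seq_len(ns)) put(.edf_num(pmax[i]), 8)
  for (i in seq_len(ns)) put("-32767", 8)
  for (i in seq_len(ns)) put("32767", 8)
  for (i in seq_len(ns)) put("", 80)              # prefiltering
  for (i in seq_len(ns)) put(as.character(fs), 8)
  for (i in seq_len(ns)) put("", 32)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

# numbers must fit the 8-char EDF ASCII fields
.edf_num <- function(x) {
  s <- formatC(x, format = "g", digits = 6, width = -1)
  if (nchar(s) > 8) s <- formatC(x, format = "g", digits = 4, width = -1)
  s
}
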