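#' EEG recording objects
#'
#' A recording is one subject's leads x samples signal matrix in microvolts,
#' with its sampling rate and lead names.
#'
#' @param subject_id subject identifier.
#' @param fs sampling rate in Hz (> 0).
#' @param data numeric matrix, one row per lead, in microvolts.
#' @param lead_names character vector matching the rows of `data`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(subject_id, fs, data, lead_names) {
  fs <- as.numeric(fs)
  if (!is.finite(fs) || fs <= 0) stop("sampling rate must be > 0, got ", fs)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  lead_names <- as.character(lead_names)
  if (length(lead_names) != nrow(data))
    stop("lead_names length (", length(lead_names),
         ") does not match data rows (", nrow(data), ")")
  if (anyDuplicated(lead_names))
    stop("duplicate lead name: ", lead_names[duplicated(lead_names)][1L])
  if (!all(is.finite(data)))
    stop("recording contains non-finite samples (subject ", subject_id, ")")
  rownames(data) <- lead_names
  structure(list(subject_id = as.character(subject_id), fs = fs,
                 data = data, lead_names = lead_names),
            class = "eeg_recording")
}

# trusted internal constructor: skips validation passes on data already
# known finite (used between preprocessing stages)
.recording <- function(subject_id, fs, data, lead_names) {
  structure(list(subject_id = subject_id, fs = fs, data = data,
                 lead_names = lead_names),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> subject ", x$subject_id, ": ", nrow(x$data),
      " leads x ", ncol(x$data), " samples @ ", x$fs, " Hz (",
      round(ncol(x$data) / x$fs, 1), " s)\n", sep = "")
  invisible(x)
}

#' Read an EEG recording
#'
#' Two on-disk dialects are supported and dispatched on file extension:
#' `.edf` (16-bit European Data Format) and a delimited lead x sample matrix
#' (`.csv`/`.tsv`, one row per lead, no header) accompanied by a JSON
#' sidecar `<path>.json` with members `subject_id`, `fs` and `lead_names`.
#' The delimited dialect round-trips bit-exactly and is used for synthetic
#' fixtures; EDF is limited by its 16-bit quantization.
#'
#' Rows are validated against, and reordered to, the montage lead order:
#' recordings are never trusted to be in montage order.  A recording may
#' contain only a subset of montage leads (e.g. already reduced to scalp
#' leads), but every recorded lead must exist in the montage.
#'
#' @param path recording file path.
#' @param montage an `eeg_montage` defining lead order.
#' @return An `eeg_recording` with rows in montage order.
#' @export
read_recording <- function(path, montage) {
  stopifnot(inherits(montage, "eeg_montage"))
  if (!file.exists(path)) stop("recording file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  rec <- if (ext == "edf") read_edf(path) else .read_delim_recording(path)
  if (length(bad <- setdiff(rec$lead_names, montage$leads)))
    stop("recorded lead not present in montage: ", bad[1L])
  ord <- intersect(montage$leads, rec$lead_names)
  eeg_recording(rec$subject_id, rec$fs, rec$data[ord, , drop = FALSE], ord)
}

.read_delim_recording <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing JSON sidecar: ", side)
  meta <- jsonlite::fromJSON(side)
  for (f in c("subject_id", "fs", "lead_names"))
    if (is.null(meta[[f]])) stop("sidecar missing field '", f, "': ", side)
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  eeg_recording(meta$subject_id, meta$fs, m, meta$lead_names)
}

#' @rdname read_recording
#' @param rec an `eeg_recording`.
#' @param digits significant digits written in the delimited dialect; the
#'   default 17 preserves doubles exactly.
#' @export
write_recording <- function(rec, path, digits = 17) {
  stopifnot(inherits(rec, "eeg_recording"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") return(write_edf(rec, path))
  sep <- if (ext == "tsv") "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(rec$data)))
    writeLines(paste(format(rec$data[i, ], digits = digits,
                            scientific = TRUE, trim = TRUE),
                     collapse = sep), con)
  jsonlite::write_json(
    list(subject_id = rec$subject_id, fs = rec$fs,
         lead_names = rec$lead_names),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a subjects table
#'
#' The subjects CSV has columns `subject_id`, `lesion_side` (`left` or
#' `right`; for bilateral lesions the analyst must pre-resolve the side by
#' the worse-affected limb), `fim_admission` and `fim_discharge` (FIM-motor,
#' 13-91 points), `uefm` (Upper Extremity Fugl-Meyer, 0-66), `cst_injury`
#' (percent corticospinal tract lesion overlap, 0-100), and recording paths
#' `rec_baseline`, `rec_visit2`, `rec_visit3` (visits 2-3 may be blank).
#'
#' @param path CSV file path.
#' @return A data frame of validated subject records, one row per subject.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("subjects file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "lesion_side", "fim_admission", "fim_discharge",
            "uefm", "cst_injury")
  if (length(bad <- setdiff(need, names(d))))
    stop("subjects table missing column '", bad[1L], "'")
  for (v in c("rec_baseline", "rec_visit2", "rec_visit3"))
    if (is.null(d[[v]])) d[[v]] <- NA_character_
  d$subject_id <- as.character(d$subject_id)
  if (anyDuplicated(d$subject_id))
    stop("duplicate subject_id: ", d$subject_id[duplicated(d$subject_id)][1L])
  validate_subjects(d)
  d
}

#' @rdname read_subjects
#' @param subjects a subjects data frame.
#' @export
validate_subjects <- function(subjects) {
  chk <- function(v, lo, hi, what) {
    x <- as.numeric(subjects[[v]])
    bad <- which(!is.finite(x) | x < lo | x > hi)
    if (length(bad))
      stop("subject ", subjects$subject_id[bad[1L]], ": ", what, " = ",
           subjects[[v]][bad[1L]], " outside [", lo, ", ", hi, "]")
  }
  chk("fim_admission", 13, 91, "FIM-motor admission")
  chk("fim_discharge", 13, 91, "FIM-motor discharge")
  chk("uefm", 0, 66, "UEFM")
  chk("cst_injury", 0, 100, "CST injury %")
  bad <- which(!subjects$lesion_side %in% c("left", "right"))
  if (length(bad))
    stop("subject ", subjects$subject_id[bad[1L]],
         ": lesion_side must be 'left' or 'right', got '",
         subjects$lesion_side[bad[1L]], "'")
  invisible(subjects)
}

#' @rdname read_subjects
#' @export
write_subjects <- function(subjects, path) {
  validate_subjects(subjects)
  utils::write.csv(subjects, path, row.names = FALSE, na = "")
  invisible(path)
}
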