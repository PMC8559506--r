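#' Restrict a recording to analyzable scalp leads
#'
#' Drops the montage's excluded (cheek/neck) leads from a recording,
#' preserving lead order.  On a 256-lead dense-array montage with 64
#' excluded leads this retains the 192 analyzable leads.
#'
#' @param rec an `eeg_recording`.
#' @param montage an `eeg_montage`.
#' @return The reduced `eeg_recording`.
#' @export
select_scalp_leads <- function(rec, montage) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(montage, "eeg_montage"))
  keep <- setdiff(rec$lead_names, montage$excluded)
  if (!length(keep)) stop("all leads are excluded by the montage")
  if (length(keep) == length(rec$lead_names)) return(rec)
  .recording(rec$subject_id, rec$fs, rec$data[keep, , drop = FALSE], keep)
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean signal across leads.  The operation
#' is idempotent and leaves each sample column with zero mean.
#'
#' @param rec an `eeg_recording` with at least two leads.
#' @return The re-referenced `eeg_recording`.
#' @export
average_rereference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L)
    stop("average reference needs at least 2 leads")
  d <- rec$data - rep(colMeans(rec$data), each = nrow(rec$data))
  .recording(rec$subject_id, rec$fs, d, rec$lead_names)
}

#' Zero-phase low-pass filter
#'
#' Forward-backward (zero-phase) application of a Butterworth low-pass
#' filter of the given order.  The default 4th-order filter at 50 Hz has a
#' passband flat to well under 1% up to 30 Hz at a 1,000 Hz sampling rate,
#' and monotone attenuation above the cutoff.
#'
#' @param rec an `eeg_recording`.
#' @param cutoff_hz cutoff frequency in Hz; must be below the Nyquist
#'   frequency `fs/2`.
#' @param order filter order (per pass).
#' @return The filtered `eeg_recording`.
#' @export
lowpass_filter <- function(rec, cutoff_hz = 50, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (cutoff_hz >= nyq)
    stop("cutoff (", cutoff_hz, " Hz) must be below Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  d <- t(apply(rec$data, 1L, function(x) signal::filtfilt(bf, x)))
  rownames(d) <- rec$lead_names
  .recording(rec$subject_id, rec$fs, d, rec$lead_names)
}

#' Segment a recording into detrended 1-s epochs
#'
#' Cuts the recording into non-overlapping epochs of `epoch_s` seconds
#' (`floor` rule: the trailing remainder is dropped) and removes the
#' per-epoch, per-lead least-squares linear trend (slope and intercept).
#'
#' @param rec an `eeg_recording`.
#' @param epoch_s epoch length in seconds; `epoch_s * fs` must be a whole
#'   number of samples.
#' @return An object of class `eeg_epochs`: list with `subject_id`, `fs`,
#'   `data` (array samples x leads x epochs), `lead_names` and
#'   `kept_epoch_indices`.
#' @export
epoch_and_detrend <- function(rec, epoch_s = 1.0) {
  stopifnot(inherits(rec, "eeg_recording"))
  nsp <- epoch_s * rec$fs
  if (abs(nsp - round(nsp)) > 1e-9)
    stop("epoch length times sampling rate must be an integer sample count")
  nsp <- as.integer(round(nsp))
  k <- ncol(rec$data) %/% nsp
  if (k < 1L) stop("recording shorter than one epoch (", epoch_s, " s)")
  x <- rec$data[, seq_len(k * nsp), drop = FALSE]
  a <- aperm(array(x, dim = c(nrow(x), nsp, k)), c(2L, 1L, 3L))
  a <- .detrend_epochs(a)
  structure(list(subject_id = rec$subject_id, fs = rec$fs, data = a,
                 lead_names = rec$lead_names,
                 kept_epoch_indices = seq_len(k)),
            class = "eeg_epochs")
}

# Remove the least-squares line (intercept and slope) from every column of
# every epoch: x - mean - slope * (t - mean(t)), with the slope from the
# closed-form normal equations.
.detrend_epochs <- function(a) {
  nsp <- dim(a)[1L]
  d <- dim(a)
  dim(a) <- c(nsp, d[2L] * d[3L])
  ct <- seq_len(nsp) - (nsp + 1) / 2
  stt <- sum(ct^2)
  mu <- colMeans(a)
  slope <- drop(crossprod(ct, a)) / stt
  a <- a - rep(mu, each = nsp) - outer(ct, slope)
  dim(a) <- d
  a
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<eeg_epochs> subject ", x$subject_id, ": ", d[3L], " epochs x ",
      d[2L], " leads x ", d[1L], " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Amplitude-threshold epoch rejection
#'
#' Drops every epoch in which any lead's peak absolute amplitude exceeds
#' the threshold.  This is the pipeline's deterministic artifact-handling
#' stage (in place of manual inspection and ICA): high-amplitude transients
#' such as muscle or movement artifact are removed wholesale with the
#' epoch.
#'
#' @param ep an `eeg_epochs` object.
#' @param threshold_uv rejection threshold in microvolts (> 0); `Inf`
#'   disables rejection.
#' @return The `eeg_epochs` restricted to retained epochs, with
#'   `kept_epoch_indices` updated.
#' @export
reject_epochs <- function(ep, threshold_uv = 100) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (!is.numeric(threshold_uv) || threshold_uv <= 0)
    stop("threshold_uv must be > 0")
  d <- dim(ep$data)
  m <- ep$data
  dim(m) <- c(d[1L] * d[2L], d[3L])
  peak <- apply(abs(m), 2L, max)
  keep <- peak <= threshold_uv
  if (!any(keep))
    stop("all ", d[3L], " epochs exceed ", threshold_uv,
         " uV; review the rejection threshold")
  ep$data <- ep$data[, , keep, drop = FALSE]
  ep$kept_epoch_indices <- ep$kept_epoch_indices[keep]
  ep
}

#' Flip lead signals so the left hemisphere is ipsilesional
#'
#' For right-hemisphere-lesion subjects, every lead's signal is swapped
#' with its left-right mirror homologue (midline leads are unchanged), so
#' that after flipping the left hemisphere is the ipsilesional hemisphere
#' for all subjects.  Left-lesion subjects pass through unchanged.  The
#' operation is an involution.
#'
#' @param ep an `eeg_epochs` object.
#' @param montage an `eeg_montage` whose mirror map covers all leads of
#'   `ep`.
#' @param lesion_side `"left"` or `"right"`.
#' @return The (possibly) flipped `eeg_epochs`.
#' @export
flip_to_ipsilesional_left <- function(ep, montage, lesion_side) {
  stopifnot(inherits(ep, "eeg_epochs"), inherits(montage, "eeg_montage"))
  lesion_side <- match.arg(lesion_side, c("left", "right"))
  if (lesion_side == "left") return(ep)
  if (length(bad <- setdiff(ep$lead_names, names(montage$mirror))))
    stop("mirror map does not cover lead: ", bad[1L])
  hom <- unname(montage$mirror[ep$lead_names])
  if (length(bad <- setdiff(hom, ep$lead_names)))
    stop("mirror homologue not present in data: ", bad[1L])
  # lead i receives the signal recorded at its homologue
  idx <- match(hom, ep$lead_names)
  ep$data <- ep$data[, idx, , drop = FALSE]
  ep
}

#' Full preprocessing chain
#'
#' Applies the fixed pipeline order: scalp-lead selection, common average
#' reference, optional zero-phase low-pass filtering, epoching with linear
#' detrending, amplitude-threshold epoch rejection, and lesion-side
#' flipping.
#'
#' @param rec an `eeg_recording`.
#' @param montage an `eeg_montage`.
#' @param lesion_side `"left"` or `"right"`.
#' @param lowpass_hz low-pass cutoff in Hz, or `NULL` to skip filtering
#'   (e.g. for synthetic recordings already band-limited below the
#'   cutoff).
#' @param epoch_s epoch length in seconds.
#' @param reject_uv epoch rejection threshold in microvolts.
#' @return An `eeg_epochs` object ready for spectral estimation.
#' @export
preprocess_recording <- function(rec, montage, lesion_side = "left",
                                 lowpass_hz = 50, epoch_s = 1.0,
                                 reject_uv = 100) {
  rec <- select_scalp_leads(rec, montage)
  if (nrow(rec$data) < 2L) stop("average reference needs at least 2 leads")
  nsp <- epoch_s * rec$fs
  if (abs(nsp - round(nsp)) > 1e-9)
    stop("epoch length times sampling rate must be an integer sample count")
  nsp <- as.integer(round(nsp))
  if (ncol(rec$data) < nsp)
    stop("recording shorter than one epoch (", epoch_s, " s)")
  if (!is.null(lowpass_hz)) {
    rec <- lowpass_filter(average_rereference(rec), lowpass_hz)
    core <- preprocess_core(rec$data, nsp, reject_uv, FALSE)
  } else {
    core <- preprocess_core(rec$data, nsp, reject_uv, TRUE)
  }
  ep <- structure(list(subject_id = rec$subject_id, fs = rec$fs,
                       data = core$data, lead_names = rec$lead_names,
                       kept_epoch_indices = core$kept),
                  class = "eeg_epochs")
  flip_to_ipsilesional_left(ep, montage, lesion_side)
}
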