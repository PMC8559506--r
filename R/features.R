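#' Seed (iM1) coherence map
#'
#' For every non-seed analyzable lead and every frequency band, the
#' seed-coherence value: the mean over the montage's seed leads of the
#' band-averaged magnitude-squared coherence between seed lead and target
#' lead.  The alternative `"avg_signal"` aggregation computes coherence
#' between the average seed Fourier coefficient and the target instead;
#' the default per-seed mean is robust to phase cancellation across seed
#' leads.
#'
#' @param cs a `cross_spectra` object covering the montage's seed and
#'   target leads.
#' @param montage an `eeg_montage`.
#' @param scheme a `band_scheme`.
#' @param aggregate `"mean"` (mean of the per-seed coherences) or
#'   `"avg_signal"` (coherence of the averaged seed signal).
#' @return A numeric matrix targets x bands (class `seed_coherence_map`)
#'   with the target region labels in `attr(, "region")`.
#' @export
seed_coherence_map <- function(cs, montage, scheme = band_scheme(),
                               aggregate = c("mean", "avg_signal")) {
  stopifnot(inherits(cs, "cross_spectra"), inherits(montage, "eeg_montage"))
  aggregate <- match.arg(aggregate)
  if (length(bad <- setdiff(montage$seed, cs$lead_names)))
    stop("seed lead missing from spectra: ", bad[1L])
  targets <- setdiff(intersect(analysis_leads(montage), cs$lead_names),
                     montage$seed)
  si <- match(montage$seed, cs$lead_names)
  ti <- match(targets, cs$lead_names)
  nb <- band_bins(scheme)
  auto <- vapply(seq_along(cs$lead_names), function(l) Re(cs$S[l, l, ]),
                 numeric(length(cs$freqs)))          # freqs x leads
  cohbins <- matrix(NA_real_, length(cs$freqs), length(ti))
  if (aggregate == "mean") {
    for (j in seq_along(ti)) {
      cpb <- vapply(si, function(s) {
        num <- Mod(cs$S[s, ti[j], ])^2
        den <- auto[, s] * auto[, ti[j]]
        ifelse(den > 0, pmin(1, num / den), NA_real_)
      }, numeric(length(cs$freqs)))
      cohbins[, j] <- rowMeans(cpb)
    }
  } else {
    saa <- apply(cs$S[si, si, , drop = FALSE], 3L, function(m) Re(mean(m)))
    for (j in seq_along(ti)) {
      sat <- apply(cs$S[si, ti[j], , drop = FALSE], 3L, mean)
      den <- saa * auto[, ti[j]]
      cohbins[, j] <- ifelse(den > 0, pmin(1, Mod(sat)^2 / den), NA_real_)
    }
  }
  out <- t(vapply(nb, function(b) colMeans(cohbins[b, , drop = FALSE]),
                  numeric(length(ti))))              # bands x targets
  out <- t(out)
  dimnames(out) <- list(targets, names(nb))
  structure(out, region = montage$region[targets],
            n_epochs = cs$n_epochs, class = c("seed_coherence_map", "matrix"))
}

# Fast path used per subject when building feature matrices: computes only
# seed-row cross spectra (seeds x targets) plus auto spectra, avoiding the
# full leads x leads matrix.  Numerically identical to seed_coherence_map()
# on the full cross-spectral matrix.
.seed_map_from_spectra <- function(es, montage, scheme,
                                   aggregate = "mean") {
  nb <- band_bins(scheme)
  nf <- length(es$freqs)
  nl <- length(es$lead_names)
  k <- es$n_epochs
  if (k < 2L) stop("coherence needs at least 2 epochs")
  if (length(bad <- setdiff(montage$seed, es$lead_names)))
    stop("seed lead missing from spectra: ", bad[1L])
  targets <- setdiff(intersect(analysis_leads(montage), es$lead_names),
                     montage$seed)
  si <- match(montage$seed, es$lead_names)
  ti <- match(targets, es$lead_names)
  cohbins <- matrix(NA_real_, nf, length(ti))
  for (f in seq_len(nf)) {
    zf <- es$z[f, , , drop = TRUE]
    dim(zf) <- c(nl, k)
    auto <- rowMeans(Mod(zf)^2)
    if (aggregate == "mean") {
      sst <- (zf[si, , drop = FALSE] %*% Conj(t(zf[ti, , drop = FALSE]))) / k
      den <- outer(auto[si], auto[ti])
      cf <- ifelse(den > 0, pmin(1, Mod(sst)^2 / den), NA_real_)
      cohbins[f, ] <- colMeans(cf)
    } else {
      za <- colMeans(zf[si, , drop = FALSE])
      saa <- mean(Mod(za)^2)
      sat <- (zf[ti, , drop = FALSE] %*% Conj(za)) / k
      den <- saa * auto[ti]
      cohbins[f, ] <- ifelse(den > 0, pmin(1, Mod(sat)^2 / den), NA_real_)
    }
  }
  out <- t(vapply(nb, function(b) colMeans(cohbins[b, , drop = FALSE]),
                  numeric(length(ti))))
  out <- t(out)
  dimnames(out) <- list(targets, names(nb))
  structure(out, region = montage$region[targets], n_epochs = k,
            class = c("seed_coherence_map", "matrix"))
}

.flatten_map <- function(map) {
  # lead-major, band-minor column order: LEAD:BAND
  leads <- rownames(map); bands <- colnames(map)
  v <- as.vector(t(map))
  names(v) <- paste(rep(leads, each = length(bands)), bands, sep = ":")
  v
}

#' Build the seed-coherence design matrix for a cohort
#'
#' One row per subject, one column per (target lead, band) pair, holding
#' the subject's iM1 seed-coherence value from the baseline recording.
#' Each recording is preprocessed (scalp-lead selection, common average
#' reference, optional low-pass, 1-s epochs with detrending, amplitude
#' rejection, lesion-side flipping) before spectral estimation, so the
#' columns of the matrix always refer to ipsilesional-left lead names.
#' Column order is deterministic: lead-major in montage order, band-minor.
#'
#' @param subjects a subjects data frame (see [read_subjects()]) with
#'   readable `rec_baseline` paths, or a `synthetic_cohort` whose
#'   recordings are in memory.
#' @param montage an `eeg_montage`.
#' @param scheme a `band_scheme`.
#' @param visit which recording column to use: `"baseline"`, `"visit2"` or
#'   `"visit3"`.
#' @param lowpass_hz,reject_uv,window,aggregate preprocessing and spectral
#'   options, see [preprocess_recording()], [epoch_spectra()],
#'   [seed_coherence_map()].
#' @return A numeric matrix of class `feature_matrix` (subjects x
#'   features), values in `[0, 1]`, with column metadata (lead, band,
#'   region) in `attr(, "meta")`.
#' @export
build_feature_matrix <- function(subjects, montage, scheme = band_scheme(),
                                 visit = "baseline", lowpass_hz = 50,
                                 reject_uv = 100,
                                 window = "rectangular",
                                 aggregate = "mean") {
  rows <- .cohort_rows(subjects, montage, scheme, visit,
                       lowpass_hz, reject_uv, window,
                       kind = "coherence", aggregate = aggregate)
  .assemble_features(rows, montage, scheme)
}

#' Build the relative-power design matrix for a cohort
#'
#' The comparison ("power") model's design: one column per (lead, band)
#' pair over all analyzable leads (seed leads included), holding relative
#' band power from the same preprocessing chain as the coherence features.
#'
#' @inheritParams build_feature_matrix
#' @return A `feature_matrix` of relative power values.
#' @export
build_power_matrix <- function(subjects, montage, scheme = band_scheme(),
                               visit = "baseline", lowpass_hz = 50,
                               reject_uv = 100, window = "rectangular") {
  rows <- .cohort_rows(subjects, montage, scheme, visit,
                       lowpass_hz, reject_uv, window, kind = "power")
  .assemble_features(rows, montage, scheme)
}

.cohort_rows <- function(subjects, montage, scheme, visit, lowpass_hz,
                         reject_uv, window, kind, aggregate = "mean") {
  cohort <- NULL
  if (inherits(subjects, "synthetic_cohort")) {
    cohort <- subjects
    subjects <- cohort$subjects
  }
  reccol <- paste0("rec_", visit)
  lapply(seq_len(nrow(subjects)), function(i) {
    sid <- subjects$subject_id[i]
    tryCatch({
      rec <- if (!is.null(cohort)) {
        .cohort_recording(cohort, sid, visit)
      } else {
        p <- subjects[[reccol]][i]
        if (is.na(p) || !nzchar(p)) stop("no ", visit, " recording path")
        read_recording(p, montage)
      }
      side <- subjects$lesion_side[i]
      # Flipping commutes with every preprocessing stage; applying it to
      # the raw recording (when the excluded set is mirror-symmetric)
      # keeps mirrored twins bit-identical through the summation order of
      # the average reference.
      if (side == "right" &&
          setequal(unname(montage$mirror[montage$excluded]),
                   montage$excluded)) {
        idx <- match(unname(montage$mirror[rec$lead_names]),
                     rec$lead_names)
        if (!anyNA(idx)) {
          rec <- .recording(rec$subject_id, rec$fs,
                                        rec$data[idx, , drop = FALSE],
                                        rec$lead_names)
          rownames(rec$data) <- rec$lead_names
          side <- "left"
        }
      }
      ep <- preprocess_recording(rec, montage,
                                 lesion_side = side,
                                 lowpass_hz = lowpass_hz,
                                 reject_uv = reject_uv)
      es <- epoch_spectra(ep, f_max = scheme$f_max, window = window)
      if (kind == "coherence") {
        map <- .seed_map_from_spectra(es, montage, scheme, aggregate)
        list(id = sid, values = .flatten_map(map),
             region = attr(map, "region"))
      } else {
        leads <- intersect(analysis_leads(montage), es$lead_names)
        li <- match(leads, es$lead_names)
        nf <- length(es$freqs)
        pxx <- vapply(li, function(l) {
          zl <- es$z[, l, , drop = TRUE]
          dim(zl) <- c(nf, es$n_epochs)
          rowMeans(Mod(zl)^2)
        }, numeric(nf))
        tot <- colSums(pxx[seq_len(scheme$f_max), , drop = FALSE])
        if (any(tot <= 0)) stop("zero total power")
        rp <- t(vapply(band_bins(scheme), function(b)
          colSums(pxx[b, , drop = FALSE]) / tot, numeric(length(li))))
        rp <- t(rp)
        dimnames(rp) <- list(leads, scheme$bands$name)
        list(id = sid, values = .flatten_map(rp),
             region = montage$region[leads])
      }
    }, error = function(e)
      stop("feature extraction failed for subject ", sid, " (", visit,
           "): ", conditionMessage(e), call. = FALSE))
  })
}

.assemble_features <- function(rows, montage, scheme) {
  cols <- names(rows[[1L]]$values)
  x <- t(vapply(rows, function(r) {
    if (!identical(names(r$values), cols))
      stop("inconsistent feature columns across subjects (subject ",
           r$id, ")")
    r$values
  }, numeric(length(cols))))
  rownames(x) <- vapply(rows, `[[`, "", "id")
  meta <- data.frame(
    column = cols,
    lead = sub(":[^:]*$", "", cols),
    band = sub("^.*:", "", cols),
    stringsAsFactors = FALSE)
  meta$region <- unname(montage$region[meta$lead])
  structure(x, meta = meta, class = c("feature_matrix", "matrix"))
}

#' Motor-recovery outcome vector
#'
#' The outcome is the FIM-motor change score, discharge minus admission
#' (points on the 13-91 scale, so the change is bounded by +-78).
#'
#' @param subjects a subjects data frame or `synthetic_cohort`.
#' @return Named numeric vector of change scores with cohort `mean` and
#'   `sd` attributes.
#' @export
outcome_vector <- function(subjects) {
  if (inherits(subjects, "synthetic_cohort")) subjects <- subjects$subjects
  if (any(!is.finite(subjects$fim_admission)) ||
      any(!is.finite(subjects$fim_discharge)))
    stop("missing FIM-motor score")
  d <- subjects$fim_discharge - subjects$fim_admission
  if (any(abs(d) > 78)) stop("FIM-motor change outside the +-78 scale bound")
  structure(stats::setNames(d, subjects$subject_id),
            mean = mean(d), sd = stats::sd(d))
}

#' Read / write a feature matrix as CSV plus metadata JSON
#'
#' The CSV has `subject_id` as its first column and one `LEAD:BAND` column
#' per feature; a companion `<path>.meta.json` records per-column lead,
#' band and region labels.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV path.
#' @return `read_features()` returns the `feature_matrix`.
#' @export
write_features <- function(fm, path) {
  d <- data.frame(subject_id = rownames(fm), check.names = FALSE)
  d <- cbind(d, as.data.frame(unclass(fm), check.names = FALSE))
  utils::write.csv(d, path, row.names = FALSE)
  jsonlite::write_json(attr(fm, "meta"), paste0(path, ".meta.json"),
                       digits = NA)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  x <- as.matrix(d[, -1L, drop = FALSE])
  rownames(x) <- d[[1L]]
  metapath <- paste0(path, ".meta.json")
  meta <- if (file.exists(metapath)) jsonlite::fromJSON(metapath) else NULL
  structure(x, meta = meta, class = c("feature_matrix", "matrix"))
}
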