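#' Simple linear comparison model
#'
#' Ordinary least squares of the outcome on a single clinical predictor
#' (CST injury percent, or baseline UEFM), the benchmark against which the
#' coherence model is compared.  Reports the slope, intercept, R-squared,
#' two-sided t-test p-value for the slope, raw residuals, and the
#' Shapiro-Wilk p-value for residual normality (a reported diagnostic
#' only; no transformation is applied on failure).
#'
#' @param x numeric predictor, one value per subject (non-constant).
#' @param y numeric outcome.
#' @return An object of class `linear_fit`.
#' @export
simple_linear_model <- function(x, y) {
  if (length(x) != length(y)) stop("length(x) != length(y)")
  if (length(y) < 3L) stop("need at least 3 subjects")
  if (stats::sd(x) == 0) stop("constant predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r2 = sm$r.squared,
    p_value = sm$coefficients[2L, 4L],
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    normality_p = stats::shapiro.test(stats::residuals(fit))$p.value,
    n = length(y)),
    class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "<linear_fit> n = %d: y = %.3f + %.3f x,  R2 = %.1f%%, p = %.3g\n",
    x$n, x$intercept, x$slope, 100 * x$r2, x$p_value))
  cat(sprintf("  Shapiro-Wilk residual normality p = %.3g\n", x$normality_p))
  invisible(x)
}

#' Corticospinal tract lesion load
#'
#' Percentage overlap between a binary lesion mask and a binary CST
#' template on the same voxel grid.  The default denominator is the
#' template voxel count, so a lesion covering the whole tract scores 100%
#' ("percent CST injury"); the lesion-denominator variant is available by
#' flag.  Masks may be 3-D arrays or paths to NIfTI files.
#'
#' @param lesion,template binary 3-D arrays or NIfTI file paths.
#' @param denominator `"template"` (default) or `"lesion"`.
#' @return Overlap percentage in `[0, 100]`.
#' @export
cst_overlap <- function(lesion, template,
                        denominator = c("template", "lesion")) {
  denominator <- match.arg(denominator)
  lesion <- .read_mask(lesion)
  template <- .read_mask(template)
  if (!identical(dim(lesion), dim(template)))
    stop("lesion and template masks are on different grids")
  denom <- if (denominator == "template") sum(template) else sum(lesion)
  if (denom == 0) stop("empty ", denominator, " mask")
  100 * sum(lesion & template) / denom
}

.read_mask <- function(m) {
  if (is.character(m)) m <- RNifti::readNifti(m)
  m <- as.array(m)
  if (!all(m %in% c(0, 1))) stop("mask is not binary")
  storage.mode(m) <- "integer"
  m
}

#' Residualized coherence prediction
#'
#' Does seed coherence carry information about motor recovery beyond a
#' clinical covariate?  Fits the simple linear model of the outcome on the
#' covariate, extracts its raw residuals, and runs the full LOOCV
#' elastic-net machinery on (features, residuals).
#'
#' @param x feature matrix (subjects x features).
#' @param y outcome vector.
#' @param covariate numeric covariate (e.g. CST injury or baseline UEFM).
#' @param ... passed to [coh_enet()].
#' @return An object of class `residual_coh_model`: list with the
#'   `covariate_fit` (`linear_fit`) and the residual `model` (`coh_enet`).
#' @export
residual_coherence_model <- function(x, y, covariate, ...) {
  cf <- simple_linear_model(covariate, y)
  if (sum(cf$residuals^2) <= 1e-12 * sum((y - mean(y))^2))
    stop("covariate explains the outcome exactly; residual TSS is zero")
  structure(list(covariate_fit = cf,
                 model = coh_enet(x, cf$residuals, ...)),
            class = "residual_coh_model")
}

#' @export
print.residual_coh_model <- function(x, ...) {
  cat("Covariate model:\n"); print(x$covariate_fit)
  cat("Coherence model on raw residuals:\n"); print(x$model)
  invisible(x)
}

#' Per-visit seed-coherence maps for a cohort
#'
#' Convenience wrapper used by the serial-change analysis: reads each
#' subject's recording for one visit, preprocesses it, and computes the
#' seed-coherence map.  Subjects without a recording for that visit are
#' skipped.
#'
#' @param subjects a subjects data frame (see [read_subjects()]).
#' @param montage an `eeg_montage`.
#' @param scheme a `band_scheme`.
#' @param visit `"baseline"`, `"visit2"` or `"visit3"`.
#' @param lowpass_hz,reject_uv preprocessing options.
#' @return Named list (by subject id) of `seed_coherence_map` objects.
#' @export
visit_coherence_maps <- function(subjects, montage,
                                 scheme = band_scheme(),
                                 visit = "baseline", lowpass_hz = 50,
                                 reject_uv = 100) {
  col <- paste0("rec_", visit)
  have <- which(!is.na(subjects[[col]]) & nzchar(subjects[[col]]))
  maps <- lapply(have, function(i) {
    rec <- read_recording(subjects[[col]][i], montage)
    ep <- preprocess_recording(rec, montage, subjects$lesion_side[i],
                               lowpass_hz = lowpass_hz,
                               reject_uv = reject_uv)
    seed_coherence_map(cross_spectra(epoch_spectra(ep,
                                                   f_max = scheme$f_max)),
                       montage, scheme)
  })
  stats::setNames(maps, subjects$subject_id[have])
}

#' Serial coherence change between visits
#'
#' For each configured (region, band) seed-coherence pair, computes the
#' per-subject change from baseline to a later visit, its median and
#' range, a paired t-test of the change against zero, and (when an
#' outcome interval change is supplied) the Pearson correlation between
#' coherence change and recovery.  Region values are the mean
#' seed-coherence over the montage leads carrying that region label.
#' Statistics are suppressed (deltas still emitted) when fewer than 3
#' subjects have both visits; a zero-variance change is reported as
#' no-change with an undefined t-test.
#'
#' @param baseline,visit named lists (by subject id) of
#'   `seed_coherence_map` objects for the two time points; subjects are
#'   matched by name.
#' @param montage an `eeg_montage` supplying region labels.
#' @param pairs data frame with columns `region` and `band`; defaults to
#'   the three high-beta pairs iM1-SMA, iM1-iPAR and iM1-iPMv.
#' @param outcome optional named numeric vector of outcome change over the
#'   same interval (e.g. FIM-motor change), for the correlation.
#' @return An object of class `serial_change`: list with per-subject
#'   `deltas` (long data frame) and per-pair `stats`.
#' @export
serial_coherence_change <- function(baseline, visit, montage,
                                    pairs = data.frame(
                                      region = c("SMA", "iPAR", "iPMv"),
                                      band = "high_beta"),
                                    outcome = NULL) {
  ids <- intersect(names(baseline), names(visit))
  if (!length(ids)) stop("no subjects present at both visits")
  reg_val <- function(map, region, band) {
    leads <- names(which(attr(map, "region") == region))
    leads <- intersect(leads, rownames(map))
    if (!length(leads)) return(NA_real_)
    mean(map[leads, band])
  }
  deltas <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    b0 <- vapply(ids, function(i)
      reg_val(baseline[[i]], pairs$region[k], pairs$band[k]), 0)
    b1 <- vapply(ids, function(i)
      reg_val(visit[[i]], pairs$region[k], pairs$band[k]), 0)
    data.frame(subject_id = ids, region = pairs$region[k],
               band = pairs$band[k], baseline = b0, visit = b1,
               delta = b1 - b0, row.names = NULL)
  }))
  stats_tab <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    d <- deltas[deltas$region == pairs$region[k] &
                deltas$band == pairs$band[k], ]
    d <- d[is.finite(d$delta), ]
    n <- nrow(d)
    out <- data.frame(region = pairs$region[k], band = pairs$band[k],
                      n = n, median = NA_real_, min = NA_real_,
                      max = NA_real_, mean_baseline = NA_real_,
                      mean_visit = NA_real_, t = NA_real_, p = NA_real_,
                      r = NA_real_, r_p = NA_real_)
    if (n == 0L) return(out)
    out$median <- stats::median(d$delta)
    out$min <- min(d$delta); out$max <- max(d$delta)
    out$mean_baseline <- mean(d$baseline)
    out$mean_visit <- mean(d$visit)
    if (n >= 3L) {
      if (stats::sd(d$delta) > 0) {
        tt <- stats::t.test(d$visit, d$baseline, paired = TRUE)
        out$t <- unname(tt$statistic); out$p <- tt$p.value
      }                          # sd == 0: no-change, t undefined
      if (!is.null(outcome)) {
        oc <- outcome[d$subject_id]
        if (sum(is.finite(oc)) >= 3L && stats::sd(d$delta) > 0 &&
            stats::sd(oc, na.rm = TRUE) > 0) {
          ct <- stats::cor.test(d$delta, oc)
          out$r <- unname(ct$estimate); out$r_p <- ct$p.value
        }
      }
    }
    out
  }))
  rownames(stats_tab) <- NULL
  structure(list(deltas = deltas, stats = stats_tab),
            class = "serial_change")
}

#' @export
print.serial_change <- function(x, ...) {
  cat("Serial seed-coherence change (visit - baseline):\n")
  print(x$stats, digits = 3)
  invisible(x)
}
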