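#' Frequency band schemes
#'
#' The default scheme partitions the integer frequency bins 1-30 Hz into
#' five classical bands: delta 1-3, theta 4-7, alpha 8-12, low beta 13-19
#' and high beta 20-30 Hz (inclusive integer bins).  The partition property
#' (non-overlapping bands whose union is 1..30) is what makes relative band
#' powers sum to one; custom schemes must also be partitions of a
#' contiguous `1..f_max` range.
#'
#' @param bands a data frame with columns `name`, `f_lo`, `f_hi` (inclusive
#'   integer Hz bounds).
#' @return An object of class `band_scheme`.
#' @export
band_scheme <- function(bands = data.frame(
                          name = c("delta", "theta", "alpha",
                                   "low_beta", "high_beta"),
                          f_lo = c(1L, 4L, 8L, 13L, 20L),
                          f_hi = c(3L, 7L, 12L, 19L, 30L))) {
  stopifnot(is.data.frame(bands),
            all(c("name", "f_lo", "f_hi") %in% names(bands)))
  bands$name <- as.character(bands$name)
  if (anyDuplicated(bands$name)) stop("duplicate band name")
  if (any(bands$f_lo != round(bands$f_lo)) ||
      any(bands$f_hi != round(bands$f_hi)))
    stop("band bounds must be integers (Hz bins)")
  if (any(bands$f_lo > bands$f_hi)) stop("band with f_lo > f_hi")
  all_bins <- sort(unlist(Map(seq, bands$f_lo, bands$f_hi)))
  if (anyDuplicated(all_bins)) stop("bands overlap")
  if (!identical(as.integer(all_bins),
                 seq.int(min(all_bins), max(all_bins))))
    stop("bands must tile a contiguous frequency range without gaps")
  if (min(all_bins) < 1L) stop("bands must start at 1 Hz or above")
  structure(list(bands = bands, f_max = max(all_bins)),
            class = "band_scheme")
}

#' @rdname band_scheme
#' @param scheme a `band_scheme`.
#' @return `band_bins()` returns a named list of integer bin vectors.
#' @export
band_bins <- function(scheme) {
  stopifnot(inherits(scheme, "band_scheme"))
  stats::setNames(Map(seq, scheme$bands$f_lo, scheme$bands$f_hi),
                  scheme$bands$name)
}

#' @export
print.band_scheme <- function(x, ...) {
  cat("<band_scheme>",
      paste(sprintf("%s %d-%d Hz", x$bands$name, x$bands$f_lo, x$bands$f_hi),
            collapse = ", "), "\n")
  invisible(x)
}

#' Per-epoch Fourier spectra at integer frequency bins
#'
#' Computes, for every epoch and lead, the discrete Fourier coefficients at
#' integer Hz bins `1..f_max`.  One-second epochs give exactly 1 Hz bin
#' spacing (`fs / N` with `N = fs` samples).  The stored coefficient is
#' `Z(f) = FFT(x)[f + 1] / N`; the corresponding one-sided power convention
#' is `P(f) = 2 |Z(f)|^2`, under which power summed over all positive bins
#' equals the epoch variance (Parseval).  Any fixed convention cancels in
#' coherence and relative power.
#'
#' @param ep an `eeg_epochs` object with 1-s epochs.
#' @param f_max highest integer bin to retain (default 30 Hz).
#' @param window `"rectangular"` (default, matching a bare FFT of
#'   detrended epochs) or `"hann"`.
#' @return An object of class `epoch_spectra`: complex array
#'   `f_max x leads x epochs` plus metadata.
#' @export
epoch_spectra <- function(ep, f_max = 30L, window = c("rectangular", "hann")) {
  stopifnot(inherits(ep, "eeg_epochs"))
  window <- match.arg(window)
  d <- dim(ep$data)
  n <- d[1L]
  if (abs(n - ep$fs) > 1e-9)
    stop("epoch length (", n, " samples) incompatible with 1 Hz resolution ",
         "at fs = ", ep$fs, " Hz")
  if (f_max >= n / 2)
    stop("f_max (", f_max, " Hz) must be below the Nyquist frequency")
  x <- ep$data
  dim(x) <- c(n, d[2L] * d[3L])
  if (window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
    x <- x * w
  }
  z <- stats::mvfft(x)[2L:(f_max + 1L), , drop = FALSE] / n
  dim(z) <- c(f_max, d[2L], d[3L])
  structure(list(freqs = seq_len(f_max), z = z, fs = ep$fs,
                 lead_names = ep$lead_names, n_epochs = d[3L],
                 window = window),
            class = "epoch_spectra")
}

#' Epoch-averaged cross-spectral matrix
#'
#' Averages `Z_x(f) * Conj(Z_y(f))` over epochs for every lead pair and
#' integer frequency bin, yielding the cross-spectral matrix `S_xy(f)`.
#' The matrix is Hermitian in its lead indices at every frequency and its
#' diagonal (the auto-spectra) is real and non-negative.
#'
#' @param es an `epoch_spectra` object with at least 2 epochs.
#' @return An object of class `cross_spectra`: complex array
#'   `leads x leads x freqs`, epoch count, and metadata.
#' @export
cross_spectra <- function(es) {
  stopifnot(inherits(es, "epoch_spectra"))
  if (es$n_epochs < 2L)
    stop("cross-spectral averaging needs at least 2 epochs")
  nf <- length(es$freqs)
  nl <- length(es$lead_names)
  s <- array(complex(real = 0), dim = c(nl, nl, nf),
             dimnames = list(es$lead_names, es$lead_names, NULL))
  for (f in seq_len(nf)) {
    zf <- es$z[f, , , drop = TRUE]
    dim(zf) <- c(nl, es$n_epochs)
    sf <- zf %*% Conj(t(zf)) / es$n_epochs
    # enforce exact Hermitian symmetry / real diagonal against rounding
    sf <- (sf + Conj(t(sf))) / 2
    s[, , f] <- sf
  }
  structure(list(freqs = es$freqs, S = s, n_epochs = es$n_epochs,
                 lead_names = es$lead_names),
            class = "cross_spectra")
}

#' Magnitude-squared coherence between two leads
#'
#' `C_xy(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f))`, the squared correlation
#' coefficient of the two leads' Fourier coefficients across epochs, in
#' `[0, 1]` at every frequency bin.  Values approaching 1 indicate
#' consistent phase and amplitude ratios across epochs.  With a single
#' epoch the estimator is identically 1 and an error is raised.  Bins where
#' either lead has zero power yield `NA` with a warning rather than
#' fabricating a coherence value.
#'
#' @param cs a `cross_spectra` object.
#' @param x,y lead names or indices.
#' @return Named numeric vector of per-bin coherence values.
#' @export
coherence <- function(cs, x, y) {
  stopifnot(inherits(cs, "cross_spectra"))
  if (cs$n_epochs < 2L)
    stop("coherence is degenerate (identically 1) with fewer than 2 epochs")
  ix <- if (is.character(x)) match(x, cs$lead_names) else as.integer(x)
  iy <- if (is.character(y)) match(y, cs$lead_names) else as.integer(y)
  if (is.na(ix) || is.na(iy)) stop("unknown lead in coherence pair")
  sxx <- Re(cs$S[ix, ix, ])
  syy <- Re(cs$S[iy, iy, ])
  sxy <- cs$S[ix, iy, ]
  denom <- sxx * syy
  out <- rep(NA_real_, length(cs$freqs))
  ok <- denom > 0
  if (!all(ok))
    warning("zero-power bin(s) flagged as missing: f = ",
            paste(cs$freqs[!ok], collapse = ", "))
  out[ok] <- pmin(1, Mod(sxy[ok])^2 / denom[ok])
  names(out) <- cs$freqs
  out
}

#' Band average of per-bin values
#'
#' Unweighted arithmetic mean over a band's inclusive integer bins.
#' Missing (flagged) bins propagate to a missing band value.
#'
#' @param values numeric vector indexed by integer frequency bin (names or
#'   positions `1..f_max`).
#' @param bins integer vector of bins, e.g. one element of [band_bins()].
#' @return A scalar.
#' @export
band_average <- function(values, bins) {
  if (max(bins) > length(values)) stop("band references a bin beyond f_max")
  mean(values[bins])
}

#' Relative band power per lead
#'
#' Power in each band divided by total power over the scheme's full
#' frequency range (1-30 Hz by default).  Per lead, the five band values
#' sum to 1 because the default bands partition the range.
#'
#' @param cs a `cross_spectra` object.
#' @param scheme a `band_scheme`.
#' @return Numeric matrix leads x bands of relative power values in
#'   `[0, 1]`.
#' @export
relative_power <- function(cs, scheme = band_scheme()) {
  stopifnot(inherits(cs, "cross_spectra"))
  nb <- band_bins(scheme)
  if (scheme$f_max > max(cs$freqs))
    stop("scheme needs bins up to ", scheme$f_max, " Hz; spectra stop at ",
         max(cs$freqs))
  nl <- length(cs$lead_names)
  pxx <- vapply(seq_len(nl), function(l) Re(cs$S[l, l, ]),
                numeric(length(cs$freqs)))           # freqs x leads
  tot <- colSums(pxx[seq_len(scheme$f_max), , drop = FALSE])
  if (any(tot <= 0))
    stop("zero total power for lead: ",
         cs$lead_names[which(tot <= 0)[1L]])
  rp <- vapply(nb, function(b)
    colSums(pxx[b, , drop = FALSE]) / tot, numeric(nl))
  rownames(rp) <- cs$lead_names
  rp
}
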