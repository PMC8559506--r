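#' Closed-form coherence of the common-source model
#'
#' Two leads observing a shared band-limited source through couplings
#' `c_i`, `c_j` plus independent noise have magnitude-squared coherence
#' `C = (SNR_i / (1 + SNR_i)) * (SNR_j / (1 + SNR_j))` with
#' `SNR_k = c_k^2 * source_power / noise_k` (all powers per frequency
#' bin).  This is the analytic oracle against which the spectral
#' estimator is validated; with SNR 1 on both leads the true coherence is
#' 0.25.  Zero noise on both leads with nonzero couplings returns the
#' boundary value 1 exactly.
#'
#' @param c_i,c_j source couplings of the two leads.
#' @param source_power per-bin source power (> 0).
#' @param noise_i,noise_j per-bin noise powers (>= 0).
#' @return True coherence in `[0, 1]`.
#' @export
oracle_coherence <- function(c_i, c_j, source_power, noise_i, noise_j) {
  if (source_power <= 0) stop("source_power must be > 0")
  if (c_i == 0 || c_j == 0) return(0)
  if (noise_i == 0 && noise_j == 0) return(1)
  snr_i <- c_i^2 * source_power / noise_i   # Inf when noise_i == 0
  snr_j <- c_j^2 * source_power / noise_j
  gi <- if (is.infinite(snr_i)) 1 else snr_i / (1 + snr_i)
  gj <- if (is.infinite(snr_j)) 1 else snr_j / (1 + snr_j)
  gi * gj
}

#' Synthetic cohort generator specification
#'
#' Defines the data-generating conditions for a synthetic stroke-EEG
#' cohort: recordings are sums of independent white lead noise and
#' band-limited Gaussian common sources, each source shared between the
#' montage's seed leads and one planted target lead, so that the true
#' seed-coherence of every (lead, band) pair is analytically known.  The
#' outcome (FIM-motor change) is generated linearly from the true
#' coherence values at the planted support plus Gaussian noise whose
#' variance is solved from the target signal fraction.  Defaults mirror
#' the cohort shape and clinical summary statistics of an inpatient
#' rehabilitation stroke cohort: 27 subjects, a 256-lead net with 192
#' analyzable leads, 180 one-second epochs, outcome 33.8 +- 14.1 points,
#' CST injury 45.2 +- 35.9 %, admission FIM-motor 37.9 +- 11.9, UEFM
#' 43.7 +- 19.8, and a 16/27 right-lesion fraction.
#'
#' @param montage an `eeg_montage`.
#' @param n_subjects cohort size.
#' @param fs sampling rate in Hz (whole number; 250 Hz retains the full
#'   1-30 Hz analysis range with headroom above the low-pass cutoff).
#' @param duration_s recording length in seconds (= number of 1-s epochs).
#' @param scheme a `band_scheme`.
#' @param true_support data frame with columns `lead`, `band` and `beta`
#'   (raw relative effect weights); default plants one (lead, band) pair
#'   in each of the five bands over distinct scalp regions, with
#'   alternating effect signs.
#' @param kappa_range range of per-subject true seed-coherence values at
#'   planted pairs, drawn uniformly; the upper bound must stay below
#'   `seed_coh_factor`.
#' @param seed_coh_factor per-bin SNR factor `SNR/(1+SNR)` of the seed
#'   leads on each planted source.
#' @param noise_sd_uv white lead-noise standard deviation in microvolts.
#' @param signal_fraction target population fraction of outcome variance
#'   explained by the planted features, in `[0, 1]`.
#' @param outcome_mean,outcome_sd population mean and SD of the outcome.
#' @param outcome_noise_sd optional explicit outcome noise SD; when `NULL`
#'   it is solved from `signal_fraction` and `outcome_sd`.
#' @param p_right probability of a right-sided lesion.
#' @param fim_admission_mean,fim_admission_sd,cst_mean,cst_sd,uefm_mean,uefm_sd
#'   clinical covariate distributions (truncated to their scales).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(montage = standard_montage(),
                           n_subjects = 27L, fs = 250, duration_s = 180,
                           scheme = band_scheme(),
                           true_support = NULL,
                           kappa_range = c(0.05, 0.55),
                           seed_coh_factor = 0.6,
                           noise_sd_uv = 10,
                           signal_fraction = 0.6,
                           outcome_mean = 33.8, outcome_sd = 14.1,
                           outcome_noise_sd = NULL,
                           p_right = 16 / 27,
                           fim_admission_mean = 37.9,
                           fim_admission_sd = 11.9,
                           cst_mean = 45.2, cst_sd = 35.9,
                           uefm_mean = 43.7, uefm_sd = 19.8) {
  stopifnot(inherits(montage, "eeg_montage"),
            inherits(scheme, "band_scheme"))
  if (abs(fs - round(fs)) > 1e-9) stop("fs must be a whole number of Hz")
  if (fs <= 2 * scheme$f_max)
    stop("fs must exceed twice the highest analysis frequency (",
         scheme$f_max, " Hz)")
  if (duration_s < 2) stop("need at least 2 one-second epochs")
  if (is.null(true_support)) true_support <- default_support(montage, scheme)
  stopifnot(is.data.frame(true_support),
            all(c("lead", "band") %in% names(true_support)))
  if (is.null(true_support$beta))
    true_support$beta <- rep_len(c(1, -1), nrow(true_support))
  if (length(bad <- setdiff(true_support$lead,
                            setdiff(analysis_leads(montage), montage$seed))))
    stop("planted lead must be a non-seed analyzable lead: ", bad[1L])
  if (length(bad <- setdiff(true_support$band, scheme$bands$name)))
    stop("planted band not in scheme: ", bad[1L])
  if (seed_coh_factor <= 0 || seed_coh_factor >= 1)
    stop("seed_coh_factor must be in (0, 1)")
  if (kappa_range[2L] >= seed_coh_factor)
    stop("kappa_range upper bound must stay below seed_coh_factor (",
         "implied target coupling would be infinite)")
  if (kappa_range[1L] < 0) stop("negative coherence is impossible")
  if (signal_fraction < 0 || signal_fraction > 1)
    stop("signal_fraction must be in [0, 1]")
  if (signal_fraction == 1 && is.null(outcome_noise_sd))
    outcome_noise_sd <- 0
  structure(list(
    montage = montage, n_subjects = as.integer(n_subjects), fs = fs,
    duration_s = duration_s, scheme = scheme, true_support = true_support,
    kappa_range = kappa_range, seed_coh_factor = seed_coh_factor,
    noise_sd_uv = noise_sd_uv, signal_fraction = signal_fraction,
    outcome_mean = outcome_mean, outcome_sd = outcome_sd,
    outcome_noise_sd = outcome_noise_sd, p_right = p_right,
    fim_admission_mean = fim_admission_mean,
    fim_admission_sd = fim_admission_sd,
    cst_mean = cst_mean, cst_sd = cst_sd,
    uefm_mean = uefm_mean, uefm_sd = uefm_sd),
    class = "generator_spec")
}

#' @rdname generator_spec
#' @details `default_support()` plants one pair per band: a frontal lead
#'   in delta, a temporal lead in theta, a contralesional
#'   temporal-parietal lead in alpha, an ipsilesional parietal lead in low
#'   beta and an SMA lead in high beta (the first montage lead of each
#'   region), echoing the spatial spread of recovery-predictive
#'   connections reported for stroke cohorts.
#' @export
default_support <- function(montage, scheme = band_scheme()) {
  want <- c(delta = "frontal", theta = "temporal", alpha = "cTP",
            low_beta = "iPAR", high_beta = "SMA")
  want <- want[intersect(names(want), scheme$bands$name)]
  eligible <- setdiff(analysis_leads(montage), montage$seed)
  lead <- vapply(want, function(r) {
    cand <- eligible[montage$region[eligible] == r]
    if (!length(cand)) cand <- eligible
    cand[1L]
  }, "")
  data.frame(lead = unname(lead), band = names(want),
             beta = rep_len(c(1, -1), length(want)),
             stringsAsFactors = FALSE)
}

# couplings from the nominal per-subject coherence kappa:
# seed factor g_s fixed; target factor g_t = kappa / g_s;
# coupling c = sqrt(g / (1 - g)) with unit per-bin source/noise power ratio
.coupling_from_factor <- function(g) sqrt(g / (1 - g))

#' Simulate one subject's recording
#'
#' Builds the leads x samples signal: independent white Gaussian noise on
#' every lead, plus one band-limited Gaussian source per planted support
#' entry, shared between the seed leads and the planted target lead.
#' Sources are synthesized per epoch directly in the frequency domain
#' (independent complex-Gaussian coefficients on the band's integer bins),
#' so the band limits are exact, cross-band coherence is exactly zero, and
#' the per-bin SNRs — hence the true coherences — are analytically
#' controlled.  For right-lesion subjects the lead rows are mirror-permuted,
#' so that [flip_to_ipsilesional_left()] restores the canonical
#' left-lateralized topography.
#'
#' @param spec a `generator_spec`.
#' @param kappa numeric vector of true seed-coherence values, one per row
#'   of `spec$true_support`.
#' @param lesion_side `"left"` or `"right"`.
#' @param subject_id identifier stored in the recording.
#' @return An `eeg_recording` over all montage leads.
#' @export
simulate_recording <- function(spec, kappa = NULL, lesion_side = "left",
                               subject_id = "S001") {
  stopifnot(inherits(spec, "generator_spec"))
  sup <- spec$true_support
  if (is.null(kappa)) kappa <- rep(mean(spec$kappa_range), nrow(sup))
  if (length(kappa) != nrow(sup))
    stop("kappa must have one value per planted support entry")
  lesion_side <- match.arg(lesion_side, c("left", "right"))
  mont <- spec$montage
  n <- as.integer(round(spec$fs))            # samples per 1-s epoch
  k <- as.integer(spec$duration_s)
  leads <- mont$leads
  nl <- length(leads)
  # sample-major workspace: lead signals are contiguous columns
  xt <- matrix(stats::rnorm(nl * n * k, sd = spec$noise_sd_uv), n * k, nl)
  bins <- band_bins(spec$scheme)
  # per-bin "Z-power" of white noise is sd^2 / N; sources use the same
  # per-bin power so coupling^2 equals the per-bin SNR
  amp <- spec$noise_sd_uv / sqrt(n)
  c_seed <- .coupling_from_factor(spec$seed_coh_factor)
  si <- match(mont$seed, leads)
  # alternating projection polarity across the seed set: magnitude-squared
  # coherence is sign-invariant, but the summed coupling seen by the
  # common average reference collapses from 7c to c, keeping the
  # reference-induced leak onto unplanted leads below the estimator's
  # bias floor (dipolar sources project with mixed polarity anyway)
  s_sign <- rep_len(c(1, -1), length(si))
  for (e in seq_len(nrow(sup))) {
    b <- bins[[sup$band[e]]]
    g_t <- kappa[e] / spec$seed_coh_factor
    if (g_t >= 1) stop("kappa implies an impossible target coupling")
    c_t <- .coupling_from_factor(g_t)
    v <- matrix(complex(real = 0), n, k)
    nb <- length(b)
    eps <- matrix(complex(real = stats::rnorm(nb * k, sd = sqrt(0.5)),
                          imaginary = stats::rnorm(nb * k, sd = sqrt(0.5))),
                  nb, k)
    v[b + 1L, ] <- amp * eps
    v[n + 1L - b, ] <- Conj(amp * eps)
    src <- Re(stats::mvfft(v, inverse = TRUE))      # n x k, per-bin power amp^2
    src <- as.vector(src)
    ti <- match(sup$lead[e], leads)
    xt[, ti] <- xt[, ti] + c_t * src
    xt[, si] <- xt[, si] + src %o% (s_sign * c_seed)
  }
  if (lesion_side == "right") {
    # lead l carries what the canonical (left-lateralized) layout puts at
    # its mirror homologue
    idx <- match(unname(mont$mirror[leads]), leads)
    xt <- xt[, idx, drop = FALSE]
  }
  eeg_recording(subject_id, spec$fs, t(xt), leads)
}

# Exact true seed-coherence features implied by the generative model,
# including within-band dilution when several sources share a band on the
# seed leads.  Returns the n_support-length vector for one subject.
.true_support_features <- function(spec, kappa) {
  sup <- spec$true_support
  g_s <- spec$seed_coh_factor
  c_s2 <- g_s / (1 - g_s)                    # seed coupling^2 (per-bin SNR)
  vapply(seq_len(nrow(sup)), function(e) {
    same_band <- which(sup$band == sup$band[e])
    g_t <- kappa[e] / g_s
    c_t2 <- g_t / (1 - g_t)
    s_ss <- 1 + length(same_band) * c_s2     # in units of per-bin noise power
    s_tt <- 1 + c_t2
    (c_s2 * c_t2) / (s_ss * s_tt)
  }, 0)
}

#' Simulate a full synthetic cohort
#'
#' Draws per-subject true coherences and lesion sides, builds the
#' recordings, computes the exact model-implied seed-coherence features,
#' and generates the outcome `fim_change = mean + sum(beta * feature) +
#' noise`, with effect weights rescaled so that the population signal
#' fraction matches its target and the noise SD solved from the
#' remainder.  FIM admission/discharge pairs realize the change within the
#' 13-91 scale; CST injury and UEFM are drawn independently of the
#' outcome (their predictive R-squared is therefore ~0 by construction).
#'
#' @param spec a `generator_spec`.
#' @param seed integer random seed; the cohort is a pure function of
#'   (spec, seed).
#' @param force_side optionally `"left"` or `"right"` to force every
#'   subject's lesion side (used by mirror-symmetry tests); clinical draws
#'   are unchanged.
#' @param write_dir optional directory: recordings (delimited dialect),
#'   `subjects.csv`, `montage.json` and a ground-truth `manifest.json`
#'   are written there and the subjects table gains the file paths.
#' @param materialize keep all recordings in memory (`TRUE`, default) or
#'   regenerate them on demand from the stored per-subject seeds
#'   (`FALSE`; bit-identical, and preferable for large cohorts where the
#'   full set of recordings would not fit comfortably in memory).
#' @return An object of class `synthetic_cohort`: list with `spec`,
#'   `subjects` (a subjects data frame), `recordings` (list of named
#'   per-visit lists), and `truth` (support with scaled effects, kappa and
#'   exact feature matrices, outcome noise SD).
#' @export
simulate_cohort <- function(spec, seed = 1L, force_side = NULL,
                            write_dir = NULL, materialize = TRUE) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(seed)
  n <- spec$n_subjects
  sup <- spec$true_support
  ns <- nrow(sup)
  ids <- sprintf("S%03d", seq_len(n))
  kappa <- matrix(stats::runif(n * ns, spec$kappa_range[1L],
                               spec$kappa_range[2L]), n, ns,
                  dimnames = list(ids, paste(sup$lead, sup$band, sep = ":")))
  side <- ifelse(stats::runif(n) < spec$p_right, "right", "left")
  if (!is.null(force_side))
    side <- rep(match.arg(force_side, c("left", "right")), n)
  feats <- t(vapply(seq_len(n), function(i)
    .true_support_features(spec, kappa[i, ]), numeric(ns)))
  dimnames(feats) <- dimnames(kappa)

  beta_raw <- sup$beta
  lp <- drop(feats %*% beta_raw)
  sf <- spec$signal_fraction
  if (ns == 0L || all(beta_raw == 0) || sf == 0) {
    lp_c <- rep(0, n)
    beta_scaled <- rep(0, ns)
    noise_sd <- if (!is.null(spec$outcome_noise_sd)) spec$outcome_noise_sd
                else spec$outcome_sd
  } else {
    if (stats::sd(lp) == 0)
      stop("planted linear predictor is constant; cannot realize a ",
           "positive signal fraction")
    scale <- sqrt(sf) * spec$outcome_sd / stats::sd(lp)
    beta_scaled <- beta_raw * scale
    lp_c <- (lp - mean(lp)) * scale
    noise_sd <- if (!is.null(spec$outcome_noise_sd)) spec$outcome_noise_sd
                else sqrt(1 - sf) * spec$outcome_sd
  }
  eps <- stats::rnorm(n, 0, noise_sd)
  delta <- spec$outcome_mean + lp_c + eps
  for (i in which(abs(delta) > 78)) {       # redraw scale-infeasible noise
    ok <- FALSE
    for (try in 1:100) {
      eps[i] <- stats::rnorm(1, 0, noise_sd)
      delta[i] <- spec$outcome_mean + lp_c[i] + eps[i]
      if (abs(delta[i]) <= 78) { ok <- TRUE; break }
    }
    if (!ok) stop("target signal fraction unreachable within the FIM ",
                  "scale bounds; reduce outcome_mean/outcome_sd")
  }
  adm <- stats::rnorm(n, spec$fim_admission_mean, spec$fim_admission_sd)
  adm <- pmin(pmax(adm, pmax(13, 13 - delta)), pmin(91, 91 - delta))
  cst <- pmin(pmax(stats::rnorm(n, spec$cst_mean, spec$cst_sd), 0), 100)
  uefm <- pmin(pmax(stats::rnorm(n, spec$uefm_mean, spec$uefm_sd), 0), 66)
  subj_seed <- sample.int(.Machine$integer.max - 1L, n)

  recs <- NULL
  if (materialize) {
    recs <- vector("list", n)
    names(recs) <- ids
    for (i in seq_len(n)) {
      set.seed(subj_seed[i])
      recs[[i]] <- simulate_recording(spec, kappa[i, ], side[i], ids[i])
    }
  }
  subjects <- data.frame(
    subject_id = ids, lesion_side = side,
    fim_admission = adm, fim_discharge = adm + delta,
    uefm = uefm, cst_injury = cst,
    rec_baseline = NA_character_, rec_visit2 = NA_character_,
    rec_visit3 = NA_character_, stringsAsFactors = FALSE)
  cohort <- structure(list(
    spec = spec, subjects = subjects,
    recordings = if (materialize) list(baseline = recs) else list(),
    truth = list(support = cbind(sup, beta_scaled = beta_scaled),
                 kappa = kappa, true_features = feats,
                 outcome_noise_sd = noise_sd, lp = lp_c,
                 signal_fraction = sf, seed = seed,
                 subject_seeds = stats::setNames(subj_seed, ids),
                 lesion_side = stats::setNames(side, ids))),
    class = "synthetic_cohort")
  if (!is.null(write_dir)) cohort <- .write_cohort(cohort, write_dir)
  cohort
}

# regenerate one subject's recording of a lazy cohort (bit-identical to
# the materialized one: same per-subject seed and parameters)
.cohort_recording <- function(cohort, id, visit = "baseline") {
  r <- cohort$recordings[[visit]][[id]]
  if (!is.null(r)) return(r)
  if (visit != "baseline")
    stop("no ", visit, " recording in cohort")
  tr <- cohort$truth
  if (is.null(tr$subject_seeds[id]) || is.na(tr$subject_seeds[id]))
    stop("no baseline recording in cohort")
  set.seed(tr$subject_seeds[[id]])
  simulate_recording(cohort$spec, tr$kappa[id, ], tr$lesion_side[[id]], id)
}

.write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_montage(cohort$spec$montage, file.path(dir, "montage.json"))
  for (visit in names(cohort$recordings)) {
    for (id in names(cohort$recordings[[visit]])) {
      p <- file.path(dir, paste0(id, "_", visit, ".csv"))
      write_recording(cohort$recordings[[visit]][[id]], p)
      cohort$subjects[cohort$subjects$subject_id == id,
                      paste0("rec_", visit)] <- p
    }
  }
  write_subjects(cohort$subjects, file.path(dir, "subjects.csv"))
  tr <- cohort$truth
  jsonlite::write_json(
    list(support = tr$support, kappa = tr$kappa,
         true_features = tr$true_features,
         outcome_noise_sd = tr$outcome_noise_sd,
         signal_fraction = tr$signal_fraction, seed = tr$seed),
    file.path(dir, "manifest.json"), digits = NA)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> n =", nrow(x$subjects), "subjects,",
      length(x$spec$montage$leads), "leads,",
      x$spec$duration_s, "epochs @", x$spec$fs, "Hz\n")
  cat("planted support:",
      paste(x$truth$support$lead, x$truth$support$band, sep = ":",
            collapse = " "), "\n")
  cat(sprintf("outcome: mean %.1f, signal fraction %.2f, noise sd %.2f\n",
              x$spec$outcome_mean, x$truth$signal_fraction,
              x$truth$outcome_noise_sd))
  invisible(x)
}
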