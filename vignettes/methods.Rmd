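---
title: "Methods: seed-coherence prediction of early post-stroke motor recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-coherence prediction of early post-stroke motor recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecoh)
```

## The problem

Individuals admitted to inpatient rehabilitation early after stroke vary
enormously in how much motor function they regain by discharge.
Structural markers (corticospinal tract lesion load) and bedside clinical
scores (baseline Fugl-Meyer) predict recovery over months, but perform
poorly over the few weeks of an inpatient stay.  This package implements
a data-driven alternative: resting-state EEG is recorded around
admission, the synchronization (magnitude-squared coherence) between
leads overlying ipsilesional primary motor cortex (iM1) and every other
scalp lead is computed in five classical frequency bands, and a sparse
penalized regression predicts the FIM-motor change score from those
hundreds of coherence features, with leave-one-out cross-validation
(LOOCV) guarding against the optimism that many-features/few-subjects
designs invite.

The package covers the full chain — file formats, preprocessing,
spectral estimation, feature construction, the penalized solver, the
clinical comparison models and serial-change statistics — plus a
synthetic cohort generator with analytically known ground truth, so that
every stage can be validated end to end without access to patient data.

## Preprocessing

A recording enters as a leads x samples matrix in microvolts with its
montage (lead names, scalp positions, left-right mirror pairs, excluded
cheek/neck leads, the 7-lead iM1 seed set, coarse region labels).  The
fixed pipeline order is:

1. **Scalp-lead selection** — cheek/neck leads are removed (a 256-lead
   net keeps 192 analyzable leads).
2. **Common average reference** — every sample's cross-lead mean is
   subtracted; idempotent, and it commutes with lesion-side flipping.
3. **Zero-phase low-pass filter** — a forward-backward 4th-order
   Butterworth at 50 Hz (configurable; the passband is flat to well
   under 1% through 30 Hz at a 1 kHz sampling rate).  The filter family
   and order are this package's choice; zero-phase application avoids
   phase distortion that would contaminate coherence.
4. **Epoching with detrending** — non-overlapping 1-s epochs (the
   trailing remainder is dropped — a floor rule), each epoch's per-lead
   least-squares line removed.  Linear (not mean-only) detrending is
   used because slow drift otherwise leaks into the delta band.
5. **Amplitude-based epoch rejection** — any epoch whose peak absolute
   amplitude on any lead exceeds 100 µV (default) is dropped whole.
   This deterministic rule replaces manual artifact inspection and ICA:
   it is reproducible and testable, at the cost of not removing
   stereotyped ocular/cardiac components.  The threshold is a
   conventional clinical-EEG cut for gross artifact.
6. **Lesion-side flipping** — for right-hemisphere lesions every lead is
   swapped with its mirror homologue, so the left hemisphere is always
   ipsilesional.  Bilateral lesions are outside the data model: the
   subjects table must already carry the analyst's side assignment (by
   the worse-affected limb).

Filtering precedes epoching so that filter edge artifacts do not sit
inside epochs.  `preprocess_recording()` fuses stages 2, 4 and 5 in
compiled code for speed; a test asserts bit-level equality with the
composed step-wise operations.

## Spectral estimation

Each 1-s epoch is Fourier transformed (no taper by default; Hann
available), giving exactly 1 Hz bin spacing.  The stored coefficient is
`Z(f) = FFT(x)[f+1]/N`; one-sided power `2|Z(f)|^2` then satisfies
Parseval against the epoch variance.  Any fixed convention cancels in
the two derived quantities:

* **Magnitude-squared coherence** between leads x and y at bin f:
  `C_xy(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f))`, with `S_xy(f)` the
  epoch-averaged cross-spectrum.  `C` lies in [0, 1], is invariant to
  per-lead rescaling, and with K independent epochs has a small-sample
  bias floor of about `1/K` for independent signals (about 0.0056 at
  K = 180) — the practical "zero" of every coherence map.
* **Relative band power** per lead: band power divided by total
  1-30 Hz power; the five default bands partition bins 1-30, so the
  five values sum to one.

The band scheme is delta 1-3, theta 4-7, alpha 8-12, low beta 13-19,
high beta 20-30 Hz (inclusive integer bins).  Descriptions of the theta
band as starting at 3 Hz appear in the clinical literature; a
3-inclusive theta would overlap delta and break the partition property,
so 4-7 Hz is used (configurable).

Bins where a lead has exactly zero power yield missing values rather
than a fabricated 0 or 1, and missingness propagates through band
averages.

## Features and outcome

For every non-seed analyzable lead and band, the feature is the mean
over the seven seed leads of the band-averaged seed-to-lead coherence
(185 x 5 = 925 features on the dense-array montage).  Averaging the
seven coherences, rather than taking the coherence of the averaged seed
signal, is robust to phase cancellation across seed leads; the
averaged-signal variant is available.  Band-level (not per-bin) features
are the default granularity.  The outcome is the FIM-motor change score,
discharge minus admission (13-91 point scale).

## The penalized regression engine

The solver minimizes

```
(1/2n) ||y - X b||^2 + lambda * ( alpha ||b||_1 + (1-alpha)/2 ||b||_2^2 )
```

by cyclic coordinate descent with soft-threshold updates on a
standardized design (columns centered, population-SD scaled so
`x_j'x_j/n = 1`; constant columns dropped with a warning).  `alpha = 1`
is the lasso used for prediction; `alpha = 0.80` — an L2 weight of
0.2/2 — is the elastic-net setting used for interpretation, which keeps
groups of correlated leads instead of one arbitrary representative (a
seeded test demonstrates this grouping effect on near-duplicate
columns).

Numerical choices:

* Penalties are visited on a geometric grid from `lambda_max`
  (`max_j |x_j'y|/(n alpha)`, where the support is provably empty) down
  to a fraction of it; 100 points and ratio 1e-3 by default, ratio 1e-2
  when p >= n (tiny penalties are both ill-conditioned and never
  competitive under cross-validation there — the convention of the
  field's reference solvers).
* Warm starts along the grid; an active-set strategy iterates the
  current support and screens inactive coordinates through their KKT
  conditions using the maintained gradient.
* Convergence: the largest coefficient change in a sweep, relative to
  the RMS of the centered response, below `tol` (1e-5 default).  The
  objective is non-increasing across sweeps and is asserted as such.
* Non-convergence raises a condition object carrying the last iterate
  and objective trace.
* Coordinate order is the column order; the solver contains no
  randomness.

Penalty selection is by leave-one-out cross-validation: for every fold,
standardization and the entire path fit are recomputed from the n-1
retained subjects — nothing about the held-out subject touches
centering, scaling or selection.  The package reports

* `r2_cv = 1 - PRESS/TSS` at the selected penalty (primary; may be
  negative for uninformative designs, floored at zero only for
  display), and
* `r2_insample` at the same penalty (optimistic when p >> n; reported
  for completeness).

The default selection is the CV minimum with ties broken toward the
larger penalty; the 1-SE rule is available (`select = "1se"`).  The two
rules answer different questions: the minimum optimizes prediction
error, while the 1-SE rule targets the support itself.  Under p > n the
CV-minimum lasso is known to over-select — on synthetic cohorts below it
reliably includes all planted features but with tens of false positives
— so support-recovery analyses in this package use the 1-SE penalty and
prediction analyses the minimum.  A deliberate negative control (feature
screening on the full data before cross-validation) is kept in the test
suite to demonstrate the optimism that in-fold standardization/selection
avoids.

## Comparison and secondary analyses

* `simple_linear_model()` — OLS of the outcome on CST lesion load or
  baseline UEFM, with the slope t-test and a Shapiro-Wilk residual
  normality diagnostic (reported, never acted on automatically).
* `cst_overlap()` — percent overlap of a binary lesion mask with a CST
  template mask on the same voxel grid.  The denominator is the template
  voxel count, so "percent CST injury" reaches 100 when the whole tract
  is lesioned; a lesion-denominator variant exists.  No registration or
  atlas handling: masks must already be on a common grid.
* `residual_coherence_model()` — the full LOOCV lasso re-run on the raw
  residuals of a covariate model, asking whether coherence carries
  information beyond the covariate.
* `serial_coherence_change()` — per-subject change in region-level seed
  coherence between visits (default: the three high-beta pairs iM1-SMA,
  iM1-iPAR, iM1-iPMv), with paired t-tests and the correlation of
  coherence change with recovery.  Region membership comes from the
  montage's labels, never from hard-coded lead identities.

## The synthetic cohort generator

`generator_spec()` / `simulate_cohort()` emulate the study conditions:
27 subjects by default on a 256-lead montage (192 analyzable), 180
one-second epochs, outcome mean 33.8 and SD 14.1 points, CST injury
45.2 +- 35.9 %, admission FIM-motor 37.9 +- 11.9, UEFM 43.7 +- 19.8,
and a 16/27 right-lesion fraction.  The default sampling rate is 250 Hz:
the analysis range stops at 30 Hz, so full clinical-rate (1 kHz)
recordings would add nothing but memory — the rate is configurable where
realism of the file layer matters.

Each planted (lead, band) pair gets its own band-limited Gaussian
source, shared between the seed leads and that target lead and
synthesized per epoch directly in the frequency domain.  The source
projects onto the seven seed leads with alternating polarity — as
dipolar cortical sources do — which also keeps the summed coupling seen
by the common average reference small, so unplanted leads stay at the
estimator's bias floor.  This makes the
band limits exact, cross-band coherence exactly zero, and the true
coherence analytic:
`C = (SNR_s/(1+SNR_s)) * (SNR_t/(1+SNR_t))` per bin, with the
per-subject target coupling solved from a drawn "true coherence"
`kappa ~ U(0.05, 0.55)`.  The seed coupling factor defaults to 0.6;
much stronger seed sources would leak visibly into every lead through
the common average reference (the leak scales with the summed seed
couplings over the lead count) and distort the designed coherences.
With the defaults the leak contributes roughly the size of the `1/K`
bias floor at 64 leads and is second-order at 192.

The outcome is generated from the *model-implied* (true) features, not
the estimated ones: `fim_change = 33.8 + sum(beta * feature) + noise`,
with the effect weights rescaled so the population signal fraction hits
its target (0.6 by default) and the noise SD solved from the remainder.
Estimator noise and the re-referencing leak therefore attenuate what the
pipeline can recover — that attenuation is part of what the validation
measures, not something calibrated away.  Admission/discharge pairs are
drawn to realize each change score within the 13-91 scale (infeasible
outcome scales raise an error); CST injury and UEFM are drawn
independently of the outcome, so their predictive R^2 is near zero by
construction.

What the generator does **not** emulate: volume conduction and realistic
head geometry, 1/f background spectra, non-stationarity, ocular/cardiac
artifact morphology, and correlated clinical covariates.  Passing tests
demonstrate the pipeline's correctness and statistical behaviour under
controlled coherence structure — not that real EEG meets these
assumptions.

## Validation conditions and problem sizes

The end-to-end checks run on cohorts of n = 200 subjects, a 64-lead
grid montage (57 targets x 5 bands = 285 features), 180 epochs, five
planted features (one per band, spread over SMA, parietal,
temporal-parietal, temporal and frontal regions) and signal fraction
0.6 — large enough that support recovery is statistically reasonable,
which it is not at n = 27 with 925 features.  Twenty seeded replicates
are used for recovery and ten for the null guard (`r2_cv <= 0.1` in at
least 90% of replicates when all effects are zero); simulation fits use
a 50-point penalty grid, and estimator-level oracles use K = 2000
epochs (coherence within 0.02 of its closed form).

What the recovery replicates show, concretely: the 1-SE support
contains *all five* planted features in every replicate, and the
cross-validated R^2 averages about 0.53 against the planted 0.6 (the
gap is the estimator-noise attenuation discussed above).  The number of
spurious extra selections, however, varies widely across replicates —
typically between one and a dozen at the 1-SE penalty, and several tens
at the CV minimum.  This is the expected behaviour of cross-validated
lasso selection, which optimizes prediction error and does not control
false discoveries; procedures that would (e.g. stability selection) are
deliberately out of scope.  Selected supports should therefore be read
as "contains the signal plus a halo of noise features", with the
standardized-coefficient ranking (see `summary()`) separating the two
in practice.  The demonstration cohorts in the README use these same
conditions and are labelled as such.

## Known limitations

* Artifact handling is amplitude-thresholding only; ICA-style component
  removal is out of scope.
* No source localization or spatial filtering — scalp coherence is
  partly driven by volume conduction, and region labels are scalp-level
  conveniences, not anatomy.
* The EDF reader/writer covers plain 16-bit EDF with a uniform sampling
  rate; EDF+ annotations are not parsed.
* `cst_overlap()` assumes pre-registered masks on a common grid.
* With n in the tens and p in the hundreds, cross-validated R^2 has
  high variance; single-cohort values should be read with that in mind
  (the package reports the raw, possibly negative value alongside the
  floored one).
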