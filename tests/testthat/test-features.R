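test_that("the dense-array design has 925 seed-coherence columns", {
  # 192 analyzable leads minus 7 seed leads = 185 targets x 5 bands
  m <- standard_montage()
  spec <- generator_spec(montage = m, n_subjects = 1, fs = 64,
                         duration_s = 4)
  set.seed(32)
  rec <- simulate_recording(spec, lesion_side = "left")
  ep <- preprocess_recording(rec, m, "left", lowpass_hz = NULL)
  map <- seed_coherence_map(cross_spectra(epoch_spectra(ep)), m)
  expect_identical(dim(map), c(185L, 5L))
  expect_length(strokecoh:::.flatten_map(map), 925L)
})

test_that("feature matrices have deterministic shape, order and bounds", {
  m <- small_montage()
  spec <- generator_spec(montage = m, n_subjects = 5, fs = 64,
                         duration_s = 10)
  co <- simulate_cohort(spec, seed = 33)
  fm <- build_feature_matrix(co, m, lowpass_hz = NULL)
  expect_identical(dim(fm), c(5L, 285L))        # (64 - 7) targets x 5 bands
  expect_true(all(fm >= 0 & fm <= 1))
  expect_identical(rownames(fm), co$subjects$subject_id)
  meta <- attr(fm, "meta")
  expect_identical(meta$column, colnames(fm))
  # lead-major, band-minor ordering
  expect_identical(meta$band[1:5],
                   c("delta", "theta", "alpha", "low_beta", "high_beta"))
  expect_identical(length(unique(meta$lead)), 57L)
  expect_true(all(c("lead", "band", "region") %in% names(meta)))
})

test_that("identical recordings give identical feature rows", {
  m <- small_montage()
  spec <- generator_spec(montage = m, n_subjects = 2, fs = 64,
                         duration_s = 8)
  set.seed(34)
  rec <- simulate_recording(spec, lesion_side = "left", subject_id = "A")
  co <- simulate_cohort(spec, seed = 34)
  co$recordings$baseline$S001 <- rec
  co$recordings$baseline$S002 <- rec
  co$subjects$lesion_side[] <- "left"
  fm <- build_feature_matrix(co, m, lowpass_hz = NULL)
  expect_identical(fm[1, ], fm[2, ])
})

test_that("subject order permutes rows only, never columns", {
  m <- small_montage()
  spec <- generator_spec(montage = m, n_subjects = 4, fs = 64,
                         duration_s = 8)
  co <- simulate_cohort(spec, seed = 35)
  fm1 <- build_feature_matrix(co, m, lowpass_hz = NULL)
  perm <- c(3, 1, 4, 2)
  co2 <- co
  co2$subjects <- co$subjects[perm, ]
  fm2 <- build_feature_matrix(co2, m, lowpass_hz = NULL)
  expect_identical(colnames(fm2), colnames(fm1))
  expect_identical(fm2[seq_len(4), ], fm1[perm, ])
})

test_that("right-lesion cohorts land on ipsilesional-left lead names", {
  m <- small_montage()
  spec <- generator_spec(montage = m, n_subjects = 4, fs = 64,
                         duration_s = 60, kappa_range = c(0.35, 0.45))
  right <- simulate_cohort(spec, seed = 36, force_side = "right")
  fm <- build_feature_matrix(right, m, lowpass_hz = NULL)
  # planted features appear under the canonical (left-hemisphere) names
  planted <- paste(spec$true_support$lead, spec$true_support$band, sep = ":")
  expect_true(all(colMeans(fm[, planted]) > 0.2))
  # and the left-lesion twin produces the identical matrix
  left <- simulate_cohort(spec, seed = 36, force_side = "left")
  fml <- build_feature_matrix(left, m, lowpass_hz = NULL)
  expect_identical(fm[seq_len(4), ], fml[seq_len(4), ])
})

test_that("planted and unplanted features match oracle and bias floor", {
  # common-average referencing slightly attenuates the closed form; at 192
  # analyzable leads the leak term is second-order
  m <- standard_montage()
  spec <- generator_spec(montage = m, n_subjects = 1, fs = 64,
                         duration_s = 180)
  set.seed(37)
  kap <- rep(0.4, 5)
  rec <- simulate_recording(spec, kappa = kap, lesion_side = "left")
  ep <- preprocess_recording(rec, m, "left", lowpass_hz = NULL)
  es <- epoch_spectra(ep)
  map <- strokecoh:::.seed_map_from_spectra(es, m, band_scheme())
  for (i in seq_len(5)) {
    got <- map[spec$true_support$lead[i], spec$true_support$band[i]]
    expect_lt(abs(got - 0.4), 0.06)
  }
  # unplanted cells hover at the 1/K estimator bias floor
  un <- map[setdiff(rownames(map), spec$true_support$lead), ]
  expect_lt(mean(un), 3 / 180)
  expect_gt(mean(un), 0.5 / 180)
})

test_that("both seed aggregation variants agree with the full-matrix path", {
  m <- small_montage()
  spec <- generator_spec(montage = m, n_subjects = 1, fs = 64,
                         duration_s = 12)
  set.seed(38)
  rec <- simulate_recording(spec, lesion_side = "left")
  ep <- preprocess_recording(rec, m, "left", lowpass_hz = NULL)
  es <- epoch_spectra(ep)
  cs <- cross_spectra(es)
  for (agg in c("mean", "avg_signal")) {
    a <- seed_coherence_map(cs, m, aggregate = agg)
    b <- strokecoh:::.seed_map_from_spectra(es, m, band_scheme(),
                                            aggregate = agg)
    expect_equal(unclass(a), unclass(b), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("outcome vectors respect the FIM-motor scale", {
  d <- data.frame(subject_id = c("a", "b", "c"),
                  lesion_side = "left",
                  fim_admission = c(13, 37.9, 60),
                  fim_discharge = c(91, 71.7, 45),
                  uefm = 40, cst_injury = 20)
  y <- outcome_vector(d)
  expect_equal(as.numeric(y), c(78, 33.8, -15))   # bounds, means, negative ok
  expect_equal(unname(y["b"]), 33.8)
  d$fim_discharge[1] <- NA
  expect_error(outcome_vector(d), "missing FIM")
})

test_that("feature CSV round trip preserves values and metadata", {
  m <- small_montage()
  spec <- generator_spec(montage = m, n_subjects = 3, fs = 64,
                         duration_s = 8)
  co <- simulate_cohort(spec, seed = 39)
  fm <- build_feature_matrix(co, m, lowpass_hz = NULL)
  p <- withr::local_tempfile(fileext = ".csv")
  write_features(fm, p)
  back <- read_features(p)
  expect_equal(unclass(back), unclass(fm), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(colnames(back), colnames(fm))
  expect_identical(attr(back, "meta")$region, attr(fm, "meta")$region)
})

test_that("relative-power designs cover all analyzable leads and sum to one", {
  m <- small_montage()
  spec <- generator_spec(montage = m, n_subjects = 3, fs = 64,
                         duration_s = 8)
  co <- simulate_cohort(spec, seed = 40)
  pm <- build_power_matrix(co, m, lowpass_hz = NULL)
  expect_identical(dim(pm), c(3L, 64L * 5L))   # seed leads included
  sums <- colSums(matrix(pm[1, ], nrow = 5))   # 5 bands per lead
  expect_equal(unname(sums), rep(1, 64), tolerance = 1e-10)
})
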