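test_that("the closed-form coherence oracle matches its boundary cases", {
  expect_equal(oracle_coherence(1, 1, 1, 1, 1), 0.25)   # SNR 1 on both
  expect_equal(oracle_coherence(0, 1, 1, 1, 1), 0)
  expect_equal(oracle_coherence(1, 1, 1, 0, 0), 1)      # noiseless boundary
  expect_equal(oracle_coherence(1, 1, 1, 0, 1), 0.5)    # one clean lead
  expect_equal(oracle_coherence(2, 3, 0.5, 1, 2),
               (2 / 3) * ((9 * 0.25) / (1 + 9 * 0.25)))
  expect_error(oracle_coherence(1, 1, 0, 1, 1), "source_power")
})

test_that("recordings are reproducible and reflect their couplings", {
  m <- small_montage()
  spec <- generator_spec(montage = m, n_subjects = 1, fs = 64,
                         duration_s = 10)
  set.seed(47); a <- simulate_recording(spec, lesion_side = "left")
  set.seed(47); b <- simulate_recording(spec, lesion_side = "left")
  expect_identical(a$data, b$data)
  expect_error(simulate_recording(spec, kappa = rep(0.1, 2)),
               "one value per planted")
})

test_that("estimated seed coherence converges to the analytic oracle", {
  # long recording (K = 2000), raw epochs (no re-referencing) so the
  # closed form applies exactly
  m <- small_montage()
  spec <- generator_spec(montage = m, n_subjects = 1, fs = 64,
                         duration_s = 2000)
  kap <- c(0.10, 0.20, 0.30, 0.40, 0.50)
  set.seed(48)
  rec <- simulate_recording(spec, kappa = kap, lesion_side = "left")
  es <- epoch_spectra(epoch_and_detrend(rec))
  map <- strokecoh:::.seed_map_from_spectra(es, m, band_scheme())
  for (i in seq_len(5)) {
    got <- map[spec$true_support$lead[i], spec$true_support$band[i]]
    expect_lt(abs(got - kap[i]), 0.02)
  }
  # unplanted (lead, band) cells sit at the 1/K bias floor
  un <- map[setdiff(rownames(map), spec$true_support$lead), ]
  expect_lt(abs(mean(un) - 1 / 2000), 1 / 2000)
})

test_that("model-implied features account for within-band source dilution", {
  m <- small_montage()
  two <- data.frame(lead = c("E09", "E10"), band = "high_beta",
                    beta = c(1, -1))
  spec <- generator_spec(montage = m, n_subjects = 1, fs = 64,
                         duration_s = 10, true_support = two)
  f <- strokecoh:::.true_support_features(spec, c(0.4, 0.4))
  # two sources share the band on the seed leads: each feature is below
  # its nominal kappa by the dilution of the seed auto-spectrum
  expect_true(all(f < 0.4))
  expect_equal(f[1], f[2], tolerance = 1e-12)
  one <- generator_spec(montage = m, n_subjects = 1, fs = 64,
                        duration_s = 10,
                        true_support = two[1, ])
  expect_equal(strokecoh:::.true_support_features(one, 0.4), 0.4,
               tolerance = 1e-12)
})

test_that("a noiseless outcome is exactly linear in the true features", {
  m <- small_montage()
  spec <- generator_spec(montage = m, n_subjects = 30, fs = 64,
                         duration_s = 4, outcome_noise_sd = 0)
  co <- simulate_cohort(spec, seed = 49, materialize = FALSE)
  y <- outcome_vector(co)
  fit <- lm(y ~ co$truth$true_features)
  expect_gt(suppressWarnings(summary(fit))$r.squared, 1 - 1e-10)
})

test_that("the realized signal fraction matches its target at n = 200", {
  m <- small_montage()
  spec <- generator_spec(montage = m, n_subjects = 200, fs = 64,
                         duration_s = 4, signal_fraction = 0.6)
  co <- simulate_cohort(spec, seed = 50, materialize = FALSE)
  y <- outcome_vector(co)
  r2 <- summary(lm(y ~ co$truth$true_features))$r.squared
  expect_lt(abs(r2 - 0.6), 0.05)
  # outcome calibrated to the cohort summary statistics
  expect_lt(abs(mean(y) - 33.8), 3.5)
  expect_lt(abs(sd(y) - 14.1), 3)
})

test_that("cohorts respect the subjects schema and scale bounds", {
  m <- small_montage()
  spec <- generator_spec(montage = m, n_subjects = 27, fs = 64,
                         duration_s = 4)
  co <- simulate_cohort(spec, seed = 51, materialize = FALSE)
  s <- co$subjects
  expect_equal(nrow(s), 27)
  expect_silent(validate_subjects(s))
  expect_true(all(s$lesion_side %in% c("left", "right")))
  expect_true(all(s$fim_discharge >= 13 & s$fim_discharge <= 91))
  # lazy and materialized cohorts agree bit for bit
  com <- simulate_cohort(spec, seed = 51)
  expect_identical(strokecoh:::.cohort_recording(co, "S007")$data,
                   com$recordings$baseline$S007$data)
})

test_that("zero-effect generators carry no outcome signal", {
  m <- small_montage()
  sup0 <- default_support(m); sup0$beta <- 0
  spec <- generator_spec(montage = m, n_subjects = 100, fs = 64,
                         duration_s = 4, true_support = sup0)
  co <- simulate_cohort(spec, seed = 52, materialize = FALSE)
  y <- outcome_vector(co)
  expect_lt(summary(lm(y ~ co$truth$true_features))$r.squared, 0.1)
  expect_true(all(co$truth$support$beta_scaled == 0))
})

test_that("infeasible outcome scales are rejected", {
  m <- small_montage()
  expect_error(
    simulate_cohort(generator_spec(montage = m, n_subjects = 10, fs = 64,
                                   duration_s = 4, outcome_mean = 200,
                                   outcome_sd = 1), seed = 53,
                    materialize = FALSE),
    "unreachable")
})

test_that("generator specifications validate their physical limits", {
  m <- small_montage()
  expect_error(generator_spec(montage = m, fs = 50), "twice the highest")
  expect_error(generator_spec(montage = m, fs = 64,
                              kappa_range = c(0.1, 0.95)),
               "seed_coh_factor")
  expect_error(generator_spec(montage = m, fs = 64,
                              true_support = data.frame(lead = "nope",
                                                        band = "alpha")),
               "non-seed analyzable lead")
  expect_error(generator_spec(montage = m, fs = 64,
                              true_support = data.frame(lead = "E09",
                                                        band = "gamma")),
               "not in scheme")
})
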