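test_that("the simple linear model reproduces exact and null cases", {
  # lm warns about the exact fit; that is the point of the example
  f <- suppressWarnings(simple_linear_model(c(0, 1, 2), c(1, 3, 5)))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  # OLS residual identities
  set.seed(41)
  x <- rnorm(40); y <- 2 * x + rnorm(40)
  f2 <- simple_linear_model(x, y)
  expect_lt(abs(sum(f2$residuals)), 1e-9)
  expect_lt(abs(sum(f2$residuals * x)), 1e-9)
  expect_true(f2$normality_p > 0 && f2$normality_p <= 1)
  # independent noise: R2 near zero at n = 1000
  y0 <- rnorm(1000)
  expect_lt(simple_linear_model(rnorm(1000), y0)$r2, 0.01)
  expect_error(simple_linear_model(rep(1, 10), rnorm(10)), "constant")
})

test_that("the slope p-value agrees with a permutation p-value", {
  set.seed(42)
  n <- 15
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n)
  f <- simple_linear_model(x, y)
  r_obs <- abs(cor(x, y))
  perm <- replicate(2000, abs(cor(x, sample(y))))
  p_perm <- (1 + sum(perm >= r_obs)) / 2001
  expect_lt(abs(f$p_value - p_perm), 0.02)
})

test_that("CST overlap counts voxels over the template denominator", {
  template <- array(0L, c(8, 8, 6))
  template[3:6, 3:6, 2:5] <- 1L          # 64 voxels... trimmed below
  template[, , 6] <- 0L
  lesion_all <- template                 # lesion covering the whole tract
  expect_equal(cst_overlap(lesion_all, template), 100)
  lesion_none <- array(0L, dim(template)); lesion_none[1, 1, 1] <- 1L
  expect_equal(cst_overlap(lesion_none, template), 0)
  # 200-voxel template with 90 lesioned -> 45%
  t2 <- array(0L, c(10, 10, 4)); t2[seq_len(200)] <- 1L
  l2 <- array(0L, c(10, 10, 4)); l2[seq_len(90)] <- 1L
  expect_equal(cst_overlap(l2, t2), 45)
  # monotone under lesion growth
  l3 <- l2; l3[91:130] <- 1L
  expect_gte(cst_overlap(l3, t2), cst_overlap(l2, t2))
  # lesion-denominator variant
  expect_equal(cst_overlap(l2, t2, denominator = "lesion"), 100)
  expect_error(cst_overlap(l2, array(0L, c(10, 10, 4))), "empty template")
  expect_error(cst_overlap(l2, t2[, , 1:2]), "different grids")
  expect_error(cst_overlap(l2 * 2L, t2), "not binary")
})

test_that("CST overlap reads NIfTI masks from disk", {
  t2 <- array(0L, c(6, 6, 3)); t2[2:4, 2:4, 2] <- 1L
  l2 <- array(0L, c(6, 6, 3)); l2[2:3, 2:4, 2] <- 1L
  pt <- withr::local_tempfile(fileext = ".nii.gz")
  pl <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(t2), pt)
  RNifti::writeNifti(RNifti::asNifti(l2), pl)
  expect_equal(cst_overlap(pl, pt), 100 * 6 / 9)
})

test_that("residualizing against an uninformative covariate changes little", {
  set.seed(43)
  n <- 60; p <- 40
  xs <- matrix(runif(n * 3, 0.1, 0.6), n, 3)
  x <- cbind(xs, matrix(0.006 + rnorm(n * (p - 3), 0, 0.006), n, p - 3))
  colnames(x) <- paste0("F", 1:p)
  lp <- drop(scale(xs %*% c(20, -20, 20)))
  y <- 30 + 10 * lp + rnorm(n, sd = 8)
  raw <- coh_enet(x, y, nlambda = 40)
  rm_noise <- residual_coherence_model(x, y, covariate = rnorm(n),
                                       nlambda = 40)
  expect_lt(abs(rm_noise$model$r2_cv - raw$r2_cv), 0.1)
  # covariate equal to the planted signal removes the predictable part
  rm_sig <- residual_coherence_model(x, y, covariate = lp, nlambda = 40)
  expect_lt(rm_sig$model$r2_cv, 0.1)
  # degenerate: covariate = outcome leaves zero residual variance
  suppressWarnings(
    expect_error(residual_coherence_model(x, y, covariate = y), "TSS"))
})

test_that("residualizing equals centering when the covariate is orthogonal", {
  set.seed(44)
  n <- 40; p <- 20
  x <- matrix(rnorm(n * p), n, p); colnames(x) <- paste0("F", 1:p)
  y <- drop(x[, 1:2] %*% c(2, -2)) + rnorm(n)
  cov0 <- residuals(lm(rnorm(n) ~ y))     # constructed orthogonal to y
  rm0 <- residual_coherence_model(x, y, covariate = cov0, nlambda = 30)
  # slope of y ~ cov0 is ~0, so residuals are y - mean(y) up to numerics
  raw <- coh_enet(x, y - mean(y), nlambda = 30)
  expect_lt(abs(rm0$model$r2_cv - raw$r2_cv), 0.02)
})

mk_map <- function(vals, leads, regions, bands = "high_beta") {
  m <- matrix(vals, nrow = length(leads), ncol = length(bands),
              dimnames = list(leads, bands))
  structure(m, region = stats::setNames(regions, leads),
            class = c("seed_coherence_map", "matrix"))
}

test_that("serial change handles identical, hand-computed and planted cases", {
  leads <- c("P1", "P2", "S1")
  regs <- c("iPAR", "iPAR", "SMA")
  base <- lapply(1:4, function(i) mk_map(c(0.2, 0.3, 0.4), leads, regs))
  names(base) <- paste0("S", 1:4)
  # identical maps: zero deltas, t undefined, reported as no-change
  sc <- serial_coherence_change(base, base, small_montage(),
                                pairs = data.frame(region = c("iPAR", "SMA"),
                                                   band = "high_beta"))
  expect_true(all(sc$deltas$delta == 0))
  expect_true(all(is.na(sc$stats$t)))
  expect_equal(sc$stats$median, c(0, 0))
  # hand data: deltas (1,2,3) against recovery (2,4,6) correlate perfectly
  v2 <- lapply(1:3, function(i) mk_map(c(0.2, 0.3, 0.4) + i / 10,
                                       leads, regs))
  names(v2) <- paste0("S", 1:3)
  out <- serial_coherence_change(base[1:3], v2, small_montage(),
                                 pairs = data.frame(region = "iPAR",
                                                    band = "high_beta"),
                                 outcome = c(S1 = 2, S2 = 4, S3 = 6))
  expect_equal(sort(out$deltas$delta), c(0.1, 0.2, 0.3))
  expect_equal(out$stats$r, 1, tolerance = 1e-12)
  # fewer than 3 matched subjects: deltas emitted, stats suppressed
  small <- serial_coherence_change(base[1:2], v2[1:2], small_montage(),
                                   pairs = data.frame(region = "iPAR",
                                                      band = "high_beta"))
  expect_equal(nrow(small$deltas), 2)
  expect_true(is.na(small$stats$t))
})

test_that("a planted mean coherence increase is detected with good power", {
  # effect 0.04 against sd 0.05 at n = 27: the paired t-test should
  # reject at the 5% level in most seeded replicates
  set.seed(45)
  leads <- "S1"; regs <- "SMA"
  rejections <- vapply(1:40, function(r) {
    ids <- sprintf("S%02d", 1:27)
    base <- lapply(ids, function(i) mk_map(0.19, leads, regs))
    names(base) <- ids
    v2 <- lapply(ids, function(i)
      mk_map(0.19 + rnorm(1, 0.04, 0.05), leads, regs))
    names(v2) <- ids
    sc <- serial_coherence_change(base, v2, small_montage(),
                                  pairs = data.frame(region = "SMA",
                                                     band = "high_beta"))
    sc$stats$p < 0.05
  }, NA)
  expect_gte(mean(rejections), 0.7)
})
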