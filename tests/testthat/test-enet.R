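# The coordinate-descent solver is validated against closed forms
# (soft-thresholding on orthonormal designs, ridge), an independent
# objective-minimization oracle, and its own KKT conditions.

# orthonormal design in the population-standardization convention
# (columns centered, x_j'x_j / n = 1, mutually orthogonal)
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  x <- qr.Q(qr(cbind(1, matrix(rnorm(n * (p + 1)), n, p + 1))))[, 2:(p + 1)]
  x <- x * sqrt(n)
  colnames(x) <- paste0("V", seq_len(p))
  x
}

design_of <- function(x, y) {
  structure(list(x = x, y = y - mean(y), center = colMeans(x) * 0 ,
                 scale = rep(1, ncol(x)), y_mean = mean(y),
                 dropped = character(), n = nrow(x)),
            class = "standardized_design")
}

test_that("lasso on an orthonormal design soft-thresholds the OLS coefficients", {
  n <- 60
  x <- orthonormal_design(n, 3)
  # OLS coefficients exactly (2.0, 0.3, -1.2)
  y <- drop(x %*% c(2.0, 0.3, -1.2))
  d <- design_of(x, y)
  f <- enet_fit(d, lambda = 0.5, alpha = 1, tol = 1e-10)
  expect_equal(unname(f$beta_std), c(1.5, 0.0, -0.7), tolerance = 1e-8)
  # S(2.0, 0.5) = 1.5 in particular
  expect_equal(unname(f$beta_std[1]), 1.5, tolerance = 1e-8)
})

test_that("the alpha -> 0 limit matches the ridge closed form", {
  set.seed(18)
  x <- matrix(rnorm(10 * 4), 10, 4)
  y <- rnorm(10)
  d <- standardize_design(x, y)
  f <- enet_fit(d, lambda = 0.7, alpha = 1e-8, tol = 1e-12)
  closed <- unname(drop(solve(crossprod(d$x) + d$n * 0.7 * diag(4),
                              crossprod(d$x, d$y))))
  expect_equal(unname(f$beta_std), closed, tolerance = 1e-6)
})

test_that("coordinate descent matches a brute-force objective minimizer", {
  for (seed in 1:4) {
    set.seed(seed)
    x <- matrix(rnorm(10 * 4), 10, 4)
    y <- drop(x %*% c(1, -1, 0, 0.5)) + rnorm(10)
    d <- standardize_design(x, y)
    for (prm in list(c(0.3, 1), c(0.1, 0.8), c(0.6, 0.5))) {
      f <- enet_fit(d, lambda = prm[1], alpha = prm[2], tol = 1e-12)
      bf <- enet_bruteforce(d, prm[1], prm[2])
      expect_equal(unname(f$beta_std), bf, tolerance = 1e-6)
    }
  }
})

test_that("the objective is non-increasing across sweeps", {
  set.seed(19)
  x <- matrix(rnorm(30 * 12), 30, 12)
  y <- drop(x[, 1:3] %*% c(2, -2, 1)) + rnorm(30)
  d <- standardize_design(x, y)
  for (alpha in c(1, 0.8)) {
    f <- enet_fit(d, lambda = 0.05, alpha = alpha, tol = 1e-10)
    expect_gt(length(f$objective), 1)
    expect_true(all(diff(f$objective) <= 1e-12))
  }
})

test_that("lambda at or above lambda_max yields an empty support", {
  set.seed(20)
  x <- matrix(rnorm(25 * 8), 25, 8)
  y <- drop(x[, 1] * 3) + rnorm(25)
  d <- standardize_design(x, y)
  lmax <- max(abs(crossprod(d$x, d$y))) / d$n
  expect_identical(sum(enet_fit(d, lmax, 1)$beta_std != 0), 0L)
  expect_identical(sum(enet_fit(d, lmax * 2, 1)$beta_std != 0), 0L)
  g <- lambda_path(d, alpha = 1, nlambda = 40)
  expect_equal(g[1], lmax, tolerance = 1e-12)
  expect_true(all(diff(g) < 0))
  expect_length(g, 40)
})

test_that("KKT conditions hold at the solution within tolerance", {
  set.seed(21)
  x <- matrix(rnorm(40 * 15), 40, 15)
  y <- drop(x[, 1:4] %*% c(3, -1, 2, -2)) + rnorm(40)
  d <- standardize_design(x, y)
  for (prm in list(c(0.5, 1), c(0.2, 0.8))) {
    f <- enet_fit(d, prm[1], prm[2], tol = 1e-10)
    expect_lt(f$kkt, 1e-8)
  }
})

test_that("support grows monotonically along the path on orthonormal designs", {
  n <- 80
  x <- orthonormal_design(n, 10, seed = 22)
  y <- drop(x %*% c(3, -2.5, 2, -1.5, 1, -0.8, 0.5, -0.3, 0.2, -0.1))
  d <- design_of(x, y)
  g <- lambda_path(d, 1, nlambda = 60)
  b <- strokecoh:::.enet_path_std(d, g, 1, tol = 1e-10)
  sizes <- colSums(b != 0)
  expect_identical(sizes[1], 0)
  expect_true(all(diff(sizes) >= 0))
})

test_that("the small-penalty end of the path approaches OLS", {
  set.seed(23)
  n <- 50; p <- 5
  x <- matrix(rnorm(n * p), n, p)
  y <- drop(x %*% c(1, 2, -1, 0.5, -2)) + rnorm(n, sd = 0.3)
  d <- standardize_design(x, y)
  g <- lambda_path(d, 1, nlambda = 80, ratio = 1e-4)
  b <- strokecoh:::.enet_path_std(d, g, 1, tol = 1e-9)
  ols <- unname(drop(solve(crossprod(d$x), crossprod(d$x, d$y))))
  expect_equal(unname(b[, 80]), ols, tolerance = 1e-2)
})

test_that("standardization invariants and back-transform identity hold", {
  set.seed(24)
  x <- cbind(a = c(1, 2, 3, 4, 5), b = rnorm(5), const = rep(7, 5))
  y <- rnorm(5)
  expect_warning(d <- standardize_design(x, y), "const")
  expect_identical(d$dropped, "const")
  expect_lt(max(abs(colMeans(d$x))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(d$x^2)) - 1)), 1e-10)
  # predictions from back-transformed coefficients match standardized fit
  f <- enet_fit(d, lambda = 0.05, alpha = 1, tol = 1e-11)
  pred_std <- d$y_mean + drop(d$x %*% f$beta_std)
  pred_orig <- f$intercept + drop(x[, c("a", "b")] %*% f$beta)
  expect_lt(max(abs(pred_std - pred_orig)), 1e-10)
  expect_error(standardize_design(x[1:2, ], y[1:2]), "at least 3 rows")
})

test_that("non-convergence raises a condition carrying the trace", {
  set.seed(25)
  x <- matrix(rnorm(20 * 10), 20, 10)
  x[, 2] <- x[, 1] + 1e-8 * rnorm(20)     # nearly collinear
  y <- rnorm(20)
  d <- standardize_design(x, y)
  cond <- tryCatch(enet_fit(d, 1e-9, 1, tol = 1e-14, max_sweeps = 3L),
                   enet_no_convergence = function(e) e)
  expect_s3_class(cond, "enet_no_convergence")
  expect_length(cond$beta, 10)
  expect_true(length(cond$objective) >= 1)
})

test_that("the elastic net keeps groups of correlated features that the lasso splits", {
  set.seed(26)
  n <- 60
  z <- rnorm(n)
  x <- cbind(d1 = z + 0.02 * rnorm(n), d2 = z + 0.02 * rnorm(n),
             matrix(rnorm(n * 6), n, 6))
  colnames(x)[3:8] <- paste0("n", 1:6)
  y <- drop(2 * z) + rnorm(n, sd = 0.5)
  d <- standardize_design(x, y)
  f_lasso <- enet_fit(d, lambda = 0.25, alpha = 1, tol = 1e-10)
  f_enet <- enet_fit(d, lambda = 0.25, alpha = 0.8, tol = 1e-10)
  dup_lasso <- f_lasso$beta_std[c("d1", "d2")]
  dup_enet <- f_enet$beta_std[c("d1", "d2")]
  # lasso: essentially one representative carries the group
  expect_lt(min(abs(dup_lasso)) / max(abs(dup_lasso)), 0.1)
  # elastic net: both retained with comparable weight
  expect_true(all(dup_enet != 0))
  expect_gt(min(abs(dup_enet)) / max(abs(dup_enet)), 0.5)
})

test_that("the solver agrees with the reference elastic-net implementation", {
  set.seed(55)
  n <- 40; p <- 12
  x <- matrix(rnorm(n * p), n, p); colnames(x) <- paste0("V", 1:p)
  y <- drop(x[, 1:3] %*% c(2, -1, 1.5)) + rnorm(n)
  d <- standardize_design(x, y)
  # glmnet standardizes the response internally, which rescales its L2
  # weight by sd(y); map (lambda, alpha) so both solve the same objective
  sy <- sqrt(mean(d$y^2))
  for (prm in list(c(0.3, 1), c(0.15, 0.8))) {
    lam <- prm[1]; al <- prm[2]
    lg <- lam * al + lam * (1 - al) * sy
    f <- enet_fit(d, lam, al, tol = 1e-10)
    g <- glmnet::glmnet(d$x, d$y + d$y_mean, alpha = lam * al / lg,
                        lambda = lg, standardize = FALSE,
                        thresh = 1e-14)
    expect_equal(unname(f$beta_std), as.numeric(g$beta),
                 tolerance = 1e-5)
  }
})
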