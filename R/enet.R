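#' Standardize a regression design
#'
#' Centers every column of `X` to mean 0 and scales it to unit standard
#' deviation (population convention, `sqrt(mean((x - mean(x))^2))`, so that
#' `x_j'x_j / n = 1` exactly), and centers `y`.  Constant (zero-variance)
#' columns are dropped with a warning naming them.  The returned object
#' retains the centering/scaling metadata needed to back-transform
#' coefficients to the original scale, under which predictions of the
#' standardized fit are reproduced exactly.
#'
#' @param x numeric design matrix (n x p), n >= 3.
#' @param y numeric response of length n.
#' @return An object of class `standardized_design`: list with `x`, `y`
#'   (centered), `center`, `scale`, `y_mean`, `dropped`, `n`.
#' @export
standardize_design <- function(x, y) {
  .standardize(x, y, min_rows = 3L)
}

.standardize <- function(x, y, min_rows = 3L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < min_rows) stop("need at least ", min_rows, " rows, got ", n)
  if (length(y) != n) stop("length(y) != nrow(x)")
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr, "-")
  scl <- sqrt(colMeans(xc^2))
  keep <- scl > 0
  if (!all(keep)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    xc <- xc[, keep, drop = FALSE]
  }
  xs <- sweep(xc, 2L, scl[keep], "/")
  structure(list(x = xs, y = y - mean(y), center = ctr[keep],
                 scale = scl[keep], y_mean = mean(y),
                 dropped = colnames(x)[!keep], n = n),
            class = "standardized_design")
}

#' Elastic-net penalty grid
#'
#' Geometric grid of `nlambda` penalties from `lambda_max` (the smallest
#' penalty at which all coefficients are zero, `max_j |x_j'y| / (n alpha)`
#' on the standardized design) down to `ratio * lambda_max`.
#'
#' @param design a `standardized_design`.
#' @param alpha L1 mixing weight in (0, 1].
#' @param nlambda number of grid points.
#' @param ratio ratio of smallest to largest penalty.
#' @return Decreasing numeric vector of penalties.
#' @export
lambda_path <- function(design, alpha = 1, nlambda = 100L, ratio = 1e-3) {
  stopifnot(inherits(design, "standardized_design"))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (ncol(design$x) == 0L) return(0)
  lmax <- max(abs(crossprod(design$x, design$y))) / (design$n * alpha)
  if (lmax == 0) stop("degenerate design: y is orthogonal to every column")
  exp(seq(log(lmax), log(lmax * ratio), length.out = nlambda))
}

#' Single-penalty elastic-net fit by coordinate descent
#'
#' Solves `(1/2n) ||y - X beta||^2 + lambda (alpha |beta|_1 +
#' (1 - alpha)/2 |beta|_2^2)` on the standardized design by cyclic
#' coordinate descent with soft-thresholding updates, converged when the
#' largest coefficient change in a sweep falls below `tol`.  The objective
#' is non-increasing across sweeps; non-convergence raises an error whose
#' condition carries the last iterate and the per-sweep objective trace.
#'
#' @param design a `standardized_design`.
#' @param lambda penalty (>= 0).
#' @param alpha L1 mixing weight in (0, 1]; 1 is the lasso.
#' @param tol convergence tolerance: a sweep's largest coefficient change,
#'   relative to the root-mean-square of the centered response (the natural
#'   unit of standardized-scale coefficients), must fall below it.
#' @param max_sweeps sweep budget.
#' @param beta_init optional warm start (standardized scale).
#' @return An object of class `enet_fit`: standardized and original-scale
#'   coefficients, intercept, objective trace, sweep count and the maximum
#'   KKT violation at the solution.
#' @export
enet_fit <- function(design, lambda, alpha = 1, tol = 1e-5,
                     max_sweeps = 100000L, beta_init = NULL) {
  stopifnot(inherits(design, "standardized_design"))
  if (lambda < 0) stop("lambda must be >= 0")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  p <- ncol(design$x)
  if (is.null(beta_init)) beta_init <- numeric(p)
  fit <- enet_cd_gram(crossprod(design$x), drop(crossprod(design$x, design$y)),
                      sum(design$y^2), design$n, lambda, alpha,
                      beta_init, tol * .y_scale(design), as.integer(max_sweeps),
                      TRUE)
  if (!fit$converged[1L]) {
    cond <- structure(
      class = c("enet_no_convergence", "error", "condition"),
      list(message = paste0("coordinate descent did not converge in ",
                            max_sweeps, " sweeps"),
           call = sys.call(),
           beta = drop(fit$beta), objective = fit$objective[[1L]]))
    stop(cond)
  }
  bstd <- drop(fit$beta)
  names(bstd) <- colnames(design$x)
  borig <- bstd / design$scale
  structure(list(
    lambda = lambda, alpha = alpha,
    beta_std = bstd, beta = borig,
    intercept = design$y_mean - sum(borig * design$center),
    objective = fit$objective[[1L]], sweeps = fit$sweeps[1L],
    kkt = kkt_violation(design, bstd, lambda, alpha)),
    class = "enet_fit")
}

#' Karush-Kuhn-Tucker residual of an elastic-net solution
#'
#' For active coordinates the stationarity condition is
#' `x_j'(y - X beta)/n - lambda (1-alpha) beta_j = lambda alpha sign(beta_j)`;
#' for inactive coordinates the subgradient condition bounds the same
#' quantity by `lambda alpha` in magnitude.  Returns the largest violation
#' across coordinates (0 for an exact solution).
#'
#' @param design a `standardized_design`.
#' @param beta_std coefficients on the standardized scale.
#' @param lambda,alpha penalty parameters.
#' @return Scalar maximum KKT violation.
#' @export
kkt_violation <- function(design, beta_std, lambda, alpha) {
  if (length(beta_std) == 0L) return(0)
  grad <- drop(crossprod(design$x, design$y - design$x %*% beta_std)) /
    design$n - lambda * (1 - alpha) * beta_std
  active <- beta_std != 0
  v_act <- if (any(active))
    max(abs(grad[active] - lambda * alpha * sign(beta_std[active]))) else 0
  v_inact <- if (any(!active))
    max(0, max(abs(grad[!active])) - lambda * alpha) else 0
  max(v_act, v_inact)
}

# Warm-started path of standardized coefficient vectors (p x L)
.y_scale <- function(design) max(sqrt(mean(design$y^2)), .Machine$double.eps)

.enet_path_std <- function(design, lambda, alpha, tol = 1e-5,
                           max_sweeps = 100000L) {
  p <- ncol(design$x)
  if (p == 0L)
    return(matrix(0, 0L, length(lambda)))
  fit <- enet_cd_gram(crossprod(design$x),
                      drop(crossprod(design$x, design$y)),
                      sum(design$y^2), design$n, lambda, alpha,
                      numeric(p), tol * .y_scale(design),
                      as.integer(max_sweeps), FALSE)
  if (!all(fit$converged))
    stop("coordinate descent did not converge at lambda = ",
         lambda[which(!fit$converged)[1L]])
  rownames(fit$beta) <- colnames(design$x)
  fit$beta
}

#' Leave-one-out cross-validated prediction error along a penalty grid
#'
#' For every penalty, refits the elastic net on each `n - 1`-subject fold
#' (standardization recomputed strictly inside the fold, so no information
#' from the held-out subject leaks into centering, scaling or selection)
#' and records the squared prediction error on the held-out subject.
#' PRESS is the sum of these errors.  With a zero-column design the fold
#' prediction is the fold mean of `y` (intercept-only model).
#'
#' @param x design matrix (possibly with zero columns).
#' @param y response.
#' @param lambda decreasing penalty grid.
#' @param alpha L1 mixing weight.
#' @param tol,max_sweeps coordinate-descent controls.
#' @return List with `press` (sum of squared leave-one-out errors per
#'   penalty), `mse` (`press/n`), `se` (standard error of the mean squared
#'   error), and the `n x L` error matrix.
#' @export
loocv_press <- function(x, y, lambda = 0, alpha = 1, tol = 1e-5,
                        max_sweeps = 100000L) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  n <- length(y)
  if (n < 3L) stop("leave-one-out cross-validation needs n >= 3")
  L <- length(lambda)
  err2 <- matrix(0, n, L)
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (stats::sd(yi) == 0)
      warning("constant response in fold ", i, "; fold retained")
    if (ncol(x) == 0L) {
      err2[i, ] <- (y[i] - mean(yi))^2
      next
    }
    sdf <- .standardize(x[-i, , drop = FALSE], yi, min_rows = 2L)
    bstd <- .enet_path_std(sdf, lambda, alpha, tol, max_sweeps)
    z <- (x[i, names(sdf$center)] - sdf$center) / sdf$scale
    pred <- sdf$y_mean + drop(z %*% bstd)
    err2[i, ] <- (y[i] - pred)^2
  }
  mse <- colMeans(err2)
  list(press = colSums(err2), mse = mse,
       se = apply(err2, 2L, stats::sd) / sqrt(n), errors = err2)
}
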