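#' Cross-validated elastic-net prediction of motor recovery
#'
#' The pipeline's prediction engine: a linear model of the outcome (FIM-motor
#' change) on seed-coherence features, penalized by
#' `lambda (alpha |beta|_1 + (1 - alpha)/2 |beta|_2^2)` and fitted by cyclic
#' coordinate descent along a warm-started penalty path, with the penalty
#' chosen by leave-one-out cross-validation (LOOCV).  `alpha = 1` is the
#' lasso used for prediction; `alpha = 0.80` (an L2 weight of 0.2/2) is the
#' elastic-net setting used for interpretation, which retains groups of
#' correlated leads rather than picking one representative.
#'
#' Standardization and fitting are repeated from scratch inside every
#' leave-one-out fold, so the cross-validated R-squared
#' `1 - PRESS / TSS` is free of selection leakage.  It may be negative for
#' uninformative designs; the raw value is retained and floored at zero
#' only for display.  The in-sample R-squared at the selected penalty is
#' also reported; under many more features than subjects it is optimistic
#' and the cross-validated value is the primary measure.
#'
#' @param x numeric design matrix (subjects x features), typically a
#'   [build_feature_matrix()] result.
#' @param y numeric outcome, typically [outcome_vector()].
#' @param alpha L1 mixing weight in (0, 1]; 1 = lasso.
#' @param nlambda,lambda_min_ratio penalty grid controls, see
#'   [lambda_path()]; the default ratio is 1e-3, or 1e-2 when there are
#'   more features than subjects (where smaller penalties are both
#'   ill-conditioned and never competitive under cross-validation).
#' @param select `"min"` picks the penalty minimizing the LOOCV error
#'   (ties broken toward the larger penalty, i.e. the sparser model);
#'   `"1se"` picks the largest penalty within one standard error of the
#'   minimum, a sparser choice appropriate when the support itself is the
#'   object of interest.
#' @param tol,max_sweeps coordinate-descent controls.
#' @return An object of class `coh_enet` with components `beta` (original
#'   scale), `intercept`, `selected`, `lambda`, `lambda_min`,
#'   `lambda_1se`, `cv_curve`, `r2_cv` (raw), `r2_insample`, `path`
#'   (original-scale coefficients along the grid) and `feature_meta`.
#' @seealso [predict.coh_enet()], [plot.coh_enet()],
#'   [residual_coherence_model()]
#' @export
coh_enet <- function(x, y, alpha = 1, nlambda = 100L,
                     lambda_min_ratio = NULL, select = c("min", "1se"),
                     tol = 1e-5, max_sweeps = 100000L) {
  select <- match.arg(select)
  meta <- attr(x, "meta")
  x <- as.matrix(unclass(x))
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  n <- length(y)
  if (nrow(x) != n) stop("nrow(x) != length(y)")
  if (n < 3L) stop("need at least 3 subjects")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("zero outcome variance (TSS = 0)")
  if (is.null(lambda_min_ratio))
    lambda_min_ratio <- if (ncol(x) >= n) 1e-2 else 1e-3

  design <- if (ncol(x)) standardize_design(x, y) else NULL
  grid <- if (ncol(x)) lambda_path(design, alpha, nlambda, lambda_min_ratio)
          else 0
  cv <- loocv_press(x, y, lambda = grid, alpha = alpha, tol = tol,
                    max_sweeps = max_sweeps)
  i_min <- which.min(cv$mse)          # first index = larger lambda on ties
  within <- which(cv$mse <= cv$mse[i_min] + cv$se[i_min])
  i_1se <- min(within)                # grid is decreasing
  i_sel <- if (select == "min") i_min else i_1se

  if (ncol(x)) {
    bstd_path <- .enet_path_std(design, grid, alpha, tol, max_sweeps)
    path <- sweep(bstd_path, 1L, design$scale, "/")
    beta <- path[, i_sel]
    intercept <- design$y_mean - sum(beta * design$center)
    fitted <- drop(x[, rownames(path), drop = FALSE] %*% beta) + intercept
  } else {
    path <- matrix(0, 0L, 1L)
    beta <- numeric(0)
    intercept <- mean(y)
    fitted <- rep(intercept, n)
  }
  rss <- sum((y - fitted)^2)
  structure(list(
    alpha = alpha, lambda = grid,
    lambda_min = grid[i_min], lambda_1se = grid[i_1se],
    lambda_sel = grid[i_sel], select = select,
    beta = beta, intercept = intercept,
    selected = names(beta)[beta != 0],
    cv_curve = data.frame(lambda = grid, mse = cv$mse, se = cv$se),
    press = cv$press[i_sel],
    r2_cv = 1 - cv$press[i_sel] / tss,
    r2_insample = 1 - rss / tss,
    path = path, fitted = fitted, y = y, nobs = n, nvars = ncol(x),
    col_scale = if (ncol(x)) design$scale else numeric(0),
    feature_meta = meta, call = match.call()),
    class = "coh_enet")
}

#' @export
print.coh_enet <- function(x, ...) {
  cat("<coh_enet> ", if (x$alpha == 1) "lasso" else
      paste0("elastic net (alpha = ", x$alpha, ")"),
      ": n = ", x$nobs, ", p = ", x$nvars, "\n", sep = "")
  cat(sprintf("  lambda (%s) = %.4g; %d feature(s) selected\n",
              x$select, x$lambda_sel, length(x$selected)))
  cat(sprintf("  R2 (LOOCV) = %.1f%%   R2 (in-sample) = %.1f%%\n",
              100 * max(0, x$r2_cv), 100 * x$r2_insample))
  if (x$r2_cv < 0)
    cat(sprintf("  (raw cross-validated R2 = %.3f)\n", x$r2_cv))
  invisible(x)
}

#' @export
summary.coh_enet <- function(object, ...) {
  sel <- object$selected
  tab <- data.frame(feature = sel,
                    coefficient = unname(object$beta[sel]),
                    std_coefficient = unname(object$beta[sel] *
                                             object$col_scale[sel]))
  if (!is.null(object$feature_meta)) {
    m <- object$feature_meta
    idx <- match(sel, m$column)
    tab$lead <- m$lead[idx]
    tab$band <- m$band[idx]
    tab$region <- m$region[idx]
  }
  # rank by the standardized coefficient: original-scale magnitudes are
  # incomparable across features with very different variances
  tab <- tab[order(-abs(tab$std_coefficient)), ]
  rownames(tab) <- NULL
  structure(list(model = object, selected = tab),
            class = "summary.coh_enet")
}

#' @export
print.summary.coh_enet <- function(x, ...) {
  print(x$model)
  if (nrow(x$selected)) {
    cat("\nSelected features (by |standardized coefficient|):\n")
    print(x$selected, digits = 3)
  } else cat("\nNo features selected (empty support).\n")
  invisible(x)
}

#' @export
coef.coh_enet <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$beta)
}

#' @export
#' @rdname coh_enet
#' @param object,newx a fitted `coh_enet` and a new design matrix with the
#'   training columns.
#' @param ... unused.
predict.coh_enet <- function(object, newx, ...) {
  if (missing(newx)) return(object$fitted)
  newx <- as.matrix(unclass(newx))
  if (length(object$beta) == 0L)
    return(rep(object$intercept, nrow(newx)))
  drop(newx[, names(object$beta), drop = FALSE] %*% object$beta) +
    object$intercept
}

#' @export
residuals.coh_enet <- function(object, ...) object$y - object$fitted

#' @export
fitted.coh_enet <- function(object, ...) object$fitted

#' Diagnostic plots for a cross-validated elastic net
#'
#' Left panel: leave-one-out mean squared error (+- 1 SE band) against
#' `log(lambda)`, with the CV-minimum and 1-SE penalties marked.  Right
#' panel: original-scale coefficient paths along the penalty grid.
#'
#' @param x a `coh_enet`.
#' @param ... passed to `matplot` for the path panel.
#' @export
plot.coh_enet <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cc <- x$cv_curve
  ll <- log(cc$lambda)
  graphics::plot(ll, cc$mse, type = "l", xlab = "log(lambda)",
                 ylab = "LOOCV mean squared error", main = "CV curve")
  graphics::polygon(c(ll, rev(ll)),
                    c(cc$mse - cc$se, rev(cc$mse + cc$se)),
                    border = NA, col = grDevices::grey(0.85))
  graphics::lines(ll, cc$mse)
  graphics::abline(v = log(c(x$lambda_min, x$lambda_1se)),
                   lty = c(2, 3))
  if (nrow(x$path)) {
    graphics::matplot(log(x$lambda), t(x$path), type = "l", lty = 1,
                      xlab = "log(lambda)", ylab = "coefficient",
                      main = "Coefficient paths", ...)
    graphics::abline(v = log(x$lambda_sel), lty = 2)
  }
  invisible(x)
}

#' Export a fitted model as JSON
#'
#' Writes the mixing weight, penalty grid, CV curve, selected features
#' with back-transformed coefficients (and region/band metadata when the
#' design was a [build_feature_matrix()] result), and both R-squared
#' values.
#'
#' @param model a `coh_enet`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  s <- summary(model)$selected
  jsonlite::write_json(list(
    alpha = model$alpha,
    lambda_selected = model$lambda_sel,
    lambda_min = model$lambda_min,
    lambda_1se = model$lambda_1se,
    selection_rule = model$select,
    intercept = model$intercept,
    selected = s,
    cv_curve = model$cv_curve,
    r2_cv = model$r2_cv,
    r2_insample = model$r2_insample,
    n = model$nobs, p = model$nvars),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
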