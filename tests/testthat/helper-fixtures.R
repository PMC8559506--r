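# Shared fixtures and independent oracles for the test suite.

small_montage <- function() grid_montage(8, 8)

# A 4-lead toy montage with classical lead names, for mirror/flip tests.
toy_montage <- function() {
  eeg_montage(
    leads = c("C3", "C4", "Cz", "O1"),
    positions = rbind(c(-0.4, 0), c(0.4, 0), c(0, 0), c(-0.4, -0.9)),
    excluded = character(),
    mirror = c(C3 = "C4", C4 = "C3", Cz = "Cz", O1 = "O1"),
    seed = "C3")
}

# Directly epoched white-noise style data (bypasses preprocessing) for
# estimator-level tests: signals is a list of leads x samples matrices of
# equal size; returns an eeg_epochs with 1-s epochs of n samples.
epochs_from_matrix <- function(x, fs, lead_names = NULL) {
  if (is.null(lead_names)) lead_names <- paste0("L", seq_len(nrow(x)))
  k <- ncol(x) %/% fs
  a <- aperm(array(x[, seq_len(k * fs), drop = FALSE],
                   dim = c(nrow(x), fs, k)), c(2, 1, 3))
  structure(list(subject_id = "toy", fs = fs, data = a,
                 lead_names = lead_names, kept_epoch_indices = seq_len(k)),
            class = "eeg_epochs")
}

# Common-source pair: x = c1*s + n1, y = c2*s + n2 with white Gaussian
# source and noise, K epochs of n samples.  True per-bin coherence is
# oracle_coherence(c1, c2, 1, 1, 1) for unit variances.
common_source_pair <- function(k, n = 64, c1 = 1, c2 = 1) {
  s <- rnorm(k * n)
  x <- rbind(c1 * s + rnorm(k * n), c2 * s + rnorm(k * n))
  epochs_from_matrix(x, n)
}

# Independent objective-minimization oracle for the elastic net: smooth
# reformulation beta = u - v with u, v >= 0, solved by box-constrained
# L-BFGS-B.  Shares no code with the coordinate-descent solver.
enet_bruteforce <- function(design, lambda, alpha) {
  p <- ncol(design$x)
  n <- design$n
  xty <- drop(crossprod(design$x, design$y))
  xtx <- crossprod(design$x)
  obj <- function(u) {
    b <- u[1:p] - u[(p + 1):(2 * p)]
    drop(sum(design$y^2) - 2 * sum(b * xty) + b %*% xtx %*% b) / (2 * n) +
      lambda * (alpha * sum(u) + (1 - alpha) / 2 * sum(b^2))
  }
  gr <- function(u) {
    b <- u[1:p] - u[(p + 1):(2 * p)]
    g <- drop(xtx %*% b - xty) / n + lambda * (1 - alpha) * b
    c(g, -g) + lambda * alpha
  }
  o <- stats::optim(rep(0, 2 * p), obj, gr, method = "L-BFGS-B",
                    lower = 0, control = list(maxit = 5000, factr = 10))
  o$par[1:p] - o$par[(p + 1):(2 * p)]
}

# Support of a fitted coh_enet at its 1-SE penalty.
support_at_1se <- function(model) {
  i <- which(model$lambda == model$lambda_1se)[1]
  rownames(model$path)[model$path[, i] != 0]
}
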