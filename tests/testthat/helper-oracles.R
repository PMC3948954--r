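# Independent reference implementations used as oracles.

# Per-equation normal-equation solution of the mMVAR model, written directly
# from the model definition with explicit matrix inversion.
oracle_mmvar <- function(X, p, include_a0 = TRUE) {
  Tn <- nrow(X); k <- ncol(X)
  Y <- X[(p + 1):Tn, , drop = FALSE]
  lags <- do.call(cbind, lapply(seq_len(p), function(n)
    X[(p + 1 - n):(Tn - n), , drop = FALSE]))
  A0 <- matrix(0, k, k)
  Alags <- array(0, c(k, k, p))
  for (i in seq_len(k)) {
    Z <- if (include_a0) cbind(Y[, -i, drop = FALSE], lags, 1)
      else cbind(lags, 1)
    beta <- solve(t(Z) %*% Z) %*% t(Z) %*% Y[, i]
    off <- 0
    if (include_a0) {
      A0[i, setdiff(seq_len(k), i)] <- beta[seq_len(k - 1)]
      off <- k - 1
    }
    for (n in seq_len(p))
      Alags[i, , n] <- beta[off + (n - 1) * k + seq_len(k)]
  }
  list(A0 = A0, Alags = Alags)
}

# Brute-force sphere-mask voxel count: scan every voxel of the grid.
oracle_sphere_count <- function(center, radius, grid) {
  cnt <- 0L
  for (i in seq_len(grid$dim[1])) for (j in seq_len(grid$dim[2]))
    for (l in seq_len(grid$dim[3])) {
      mm <- grid$affine[1:3, ] %*% c(i, j, l, 1)
      if (sum((mm - center)^2) <= radius^2) cnt <- cnt + 1L
    }
  cnt
}

# Fisher's combined p for exactly two p-values has the closed form
# q (1 - log q) with q = p1 p2.
oracle_fisher2 <- function(p1, p2) {
  q <- p1 * p2
  q * (1 - log(q))
}

# mm coordinates of a mask's voxels (via the package's internal affine map).
voxel_to_mm_test <- function(mask) {
  cpgc:::voxel_to_mm(list(affine = mask$affine), mask$voxels)
}

# Standardized synthetic series shortcut.
white_ts <- function(Tn = 200, k = 4, tr = 2) {
  standardize(roi_ts(matrix(rnorm(Tn * k), Tn, k), tr = tr))
}
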