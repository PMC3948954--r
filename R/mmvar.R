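#' Fit the modified multivariate autoregressive (mMVAR) model
#'
#' Structural VAR with instantaneous cross-terms: each series x_i(t) is
#' regressed by least squares on the zero-lag values of every other series
#' (the instantaneous matrix A(0), whose diagonal is structurally zero so
#' that only cross-correlation, not autocorrelation, is modelled) and on p
#' lags of all series, A(1)..A(p), plus an intercept. Because zero-lag
#' cross-correlation is absorbed by A(0), the lagged coefficients are purged
#' of instantaneous-correlation leakage; causal structure lives in A(1)..A(p).
#'
#' Estimation is per-equation ordinary least squares with the
#' contemporaneous regressors included directly. This matches the model as
#' written and is deterministic; like any such structural regression it
#' carries simultaneity bias in A(0), which is documented rather than
#' corrected (inference on the lagged part is surrogate-based, see
#' [build_null()]).
#'
#' @param x A standardized `roi_ts` or T x k matrix (see [standardize()]).
#'   Fitting unstandardized data requires `allow_unstandardized = TRUE`.
#' @param p Model order (number of lags).
#' @param include_instantaneous Include the A(0) terms? `FALSE` gives the
#'   naive Granger variant used as a comparison baseline in calibration
#'   studies.
#' @param allow_unstandardized Skip the standardization check.
#' @return An `mmvar` object: `A0` (k x k, zero diagonal), `Alags` (list of
#'   p k x k matrices), `intercept`, `residuals` ((T-p) x k), `sigma`
#'   (residual covariance), `bic`, `order`, `nobs`.
#' @export
fit_mmvar <- function(x, p = cpgc_defaults()$order,
                      include_instantaneous = TRUE,
                      allow_unstandardized = FALSE) {
  ts <- as_roi_ts(x)
  X <- ts$data
  Tn <- nrow(X); k <- ncol(X)
  p <- as.integer(p)
  stopifnot(p >= 1L)
  if (k < 2L) stop("need at least 2 ROI series")
  if (Tn - p <= k * (p + 1))
    stop("too few time points (T = ", Tn, ") for k = ", k,
         " series at order ", p)
  if (!allow_unstandardized && !is_standardized(X))
    stop("series are not standardized; call standardize() first or set ",
         "allow_unstandardized = TRUE")

  fit <- mmvar_fit_cpp(X, p, include_instantaneous)
  labels <- colnames(X)
  dn <- list(labels, labels)
  A0 <- fit$A0; dimnames(A0) <- dn
  Alags <- lapply(seq_len(p), function(n) {
    A <- fit$Alags[, , n]
    dimnames(A) <- dn
    A
  })
  sigma <- fit$sigma; dimnames(sigma) <- dn
  nobs <- Tn - p
  nfree <- k * ((if (include_instantaneous) k - 1 else 0) + p * k + 1)
  ldet <- determinant(sigma, logarithm = TRUE)
  bic <- nobs * as.numeric(ldet$modulus) + nfree * log(nobs)

  structure(list(order = p, k = k, A0 = A0, Alags = Alags,
                 intercept = as.numeric(fit$intercept),
                 residuals = fit$residuals, sigma = sigma,
                 bic = bic, nobs = nobs,
                 include_instantaneous = include_instantaneous,
                 roi = labels),
            class = "mmvar")
}

#' @export
print.mmvar <- function(x, ...) {
  cat("mMVAR model: k = ", x$k, ", order ", x$order,
      if (!x$include_instantaneous) " (no instantaneous terms)",
      ", ", x$nobs, " usable frames, BIC ", signif(x$bic, 6), "\n", sep = "")
  invisible(x)
}

#' Select the model order by BIC
#'
#' Fits the mMVAR model at orders 1..`p_max` and returns the order
#' minimizing BIC = T' log det(Sigma) + n_free log T', where T' is the
#' number of usable frames and n_free the number of free coefficients.
#' Ties break toward the smaller order.
#'
#' @inheritParams fit_mmvar
#' @param p_max Largest order to consider.
#' @return Integer order; the BIC values are attached as attribute `"bic"`.
#' @export
select_order_bic <- function(x, p_max = cpgc_defaults()$order,
                             include_instantaneous = TRUE) {
  stopifnot(p_max >= 1L)
  bics <- vapply(seq_len(p_max), function(p)
    fit_mmvar(x, p, include_instantaneous = include_instantaneous)$bic,
    numeric(1))
  structure(which.min(bics), bic = bics)
}

#' Correlation-purged Granger causality matrix from a fitted model
#'
#' CPGC_ij = sum over lags n of a_ij(n)^2 for i != j: the squared lagged
#' coefficients summed across lags, with the diagonal defined as zero.
#' Entry (i, j) is the direct causal influence of ROI j (column) on ROI i
#' (row). Optionally normalized by the target's residual variance.
#'
#' @param model An `mmvar` fit.
#' @param normalize Divide row i by the residual variance of series i
#'   (a monotone variant; default off).
#' @return k x k nonnegative matrix with zero diagonal, rows = target ROI,
#'   columns = source ROI.
#' @export
cpgc_from_model <- function(model, normalize = FALSE) {
  stopifnot(inherits(model, "mmvar"))
  out <- Reduce(`+`, lapply(model$Alags, function(A) A^2))
  diag(out) <- 0
  if (normalize) out <- out / diag(model$sigma)
  out
}

#' Instantaneous (zero-lag) association matrix
#'
#' The off-diagonal elements of A(0) express each series as a function of
#' the zero-lag values of the others; they reflect instantaneous
#' cross-correlation. Note A(0) from the per-equation regression is not
#' symmetric; averaging with its transpose is available as an option.
#'
#' @param model An `mmvar` fit with instantaneous terms.
#' @param symmetrize Average A(0) with its transpose?
#' @return k x k matrix with zero diagonal.
#' @export
instantaneous_corr <- function(model, symmetrize = FALSE) {
  stopifnot(inherits(model, "mmvar"))
  if (!model$include_instantaneous)
    stop("model was fitted without instantaneous terms")
  A0 <- model$A0
  if (symmetrize) A0 <- (A0 + t(A0)) / 2
  diag(A0) <- 0
  A0
}
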