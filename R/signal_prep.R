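#' Band-pass filter ROI time series
#'
#' Ideal frequency-domain band-pass: the series is transformed with the FFT,
#' bins whose frequency falls outside `[low, high]` Hz are zeroed (DC
#' included whenever `low > 0`), and the series is transformed back. The
#' ideal mask makes the filter deterministic and exact at any series length,
#' with unit gain on retained bins and zero gain elsewhere; sinusoids that do
#' not sit exactly on an FFT bin incur only small leakage loss.
#'
#' @param ts A `roi_ts` or T x k matrix.
#' @param low,high Band edges in Hz; `0 <= low < high < 1/(2 TR)`.
#' @param tr Repetition time (only needed when `ts` is a bare matrix).
#' @return Filtered `roi_ts`.
#' @export
bandpass_filter <- function(ts, low = cpgc_defaults()$band[1],
                            high = cpgc_defaults()$band[2], tr = NULL) {
  ts <- as_roi_ts(ts, tr)
  nyquist <- 1 / (2 * ts$tr)
  if (!(low >= 0 && low < high))
    stop("band edges must satisfy 0 <= low < high")
  if (high >= nyquist)
    stop("high edge (", high, " Hz) must be below the Nyquist frequency (",
         nyquist, " Hz)")
  Tn <- nrow(ts$data)
  freq <- (seq_len(Tn) - 1) / (Tn * ts$tr)
  freq <- pmin(freq, 1 / ts$tr - freq)  # fold negative frequencies
  keep <- freq >= low & freq <= high
  spec <- mvfft(ts$data)
  spec[!keep, ] <- 0
  filtered <- Re(mvfft(spec, inverse = TRUE)) / Tn
  dimnames(filtered) <- dimnames(ts$data)
  ts$data <- filtered
  ts
}

#' Regress nuisance signals out of ROI time series
#'
#' Ordinary least-squares residualization against an intercept plus the
#' supplied confound columns (typically the six rigid-body motion
#' parameters, a linear drift term and white-matter/CSF signals). Residuals
#' are exactly orthogonal to every confound column and to the intercept.
#'
#' @param ts A `roi_ts` or T x k matrix.
#' @param confounds T x m numeric matrix (or NULL for intercept-only, i.e.
#'   demeaning). Column names are used in error messages.
#' @param tr Repetition time (only for bare matrices).
#' @return Residualized `roi_ts`.
#' @export
regress_nuisance <- function(ts, confounds = NULL, tr = NULL) {
  ts <- as_roi_ts(ts, tr)
  Tn <- nrow(ts$data)
  if (is.null(confounds)) {
    X <- matrix(1, Tn, 1, dimnames = list(NULL, "(intercept)"))
  } else {
    confounds <- as.matrix(confounds)
    stopifnot(nrow(confounds) == Tn)
    if (ncol(confounds) >= Tn)
      stop("more confounds than time points")
    if (is.null(colnames(confounds)))
      colnames(confounds) <- paste0("confound", seq_len(ncol(confounds)))
    X <- cbind("(intercept)" = 1, confounds)
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    stop("confound matrix is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  resid <- qr.resid(qrx, ts$data)
  dimnames(resid) <- dimnames(ts$data)
  ts$data <- resid
  ts
}

#' Framewise displacement from rigid-body motion parameters
#'
#' Per-frame scalar head-motion summary: the sum of the absolute
#' frame-to-frame differences of the three translations (mm) and of the
#' three rotations, the latter converted from degrees to arc length on a
#' sphere of radius `head_radius` mm (the approximate distance from the head
#' center to the cortex). The first frame has no predecessor and its FD is
#' defined as zero; the mean is taken over all frames including it.
#'
#' @param motion T x 6 matrix: translations x, y, z in mm then rotations
#'   alpha, beta, gamma in degrees (the standard realignment-parameter
#'   layout).
#' @param head_radius Sphere radius in mm for the degree-to-mm conversion.
#' @return An `fd_result`: list with per-frame `fd` (mm) and `mean_fd`.
#' @export
#' @examples
#' m <- matrix(0, 5, 6)
#' m[3, c(1, 4)] <- c(1, 1)  # 1 mm + 1 degree at one frame
#' framewise_displacement(m)$fd[3]  # 1 + 50 * pi / 180
framewise_displacement <- function(motion,
                                   head_radius = cpgc_defaults()$head_radius) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L) stop("motion trace needs at least 2 frames")
  if (ncol(motion) != 6L)
    stop("motion trace must have 6 columns (3 translations, 3 rotations)")
  stopifnot(head_radius > 0)
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius * pi / 180 * rowSums(d[, 4:6, drop = FALSE]))
  structure(list(fd = fd, mean_fd = mean(fd), head_radius = head_radius),
            class = "fd_result")
}

#' @export
print.fd_result <- function(x, ...) {
  cat("framewise displacement: ", length(x$fd), " frames, mean FD ",
      signif(x$mean_fd, 4), " mm\n", sep = "")
  invisible(x)
}

#' Preprocess one subject's ROI series
#'
#' The temporal portion of the preprocessing pipeline, in the fixed order
#' band-pass filter, nuisance regression, standardization. Confounds are the
#' six motion parameters, a linear drift term, and any supplied tissue
#' (white-matter/CSF) signals; global-signal regression (the across-ROI mean
#' or a supplied global trace) is an explicit switch, off by default.
#'
#' @param ts A `roi_ts` or T x k matrix.
#' @param motion Optional T x 6 motion-parameter matrix.
#' @param tissue Optional T x m matrix of tissue nuisance signals.
#' @param band Band edges in Hz (NULL to skip filtering).
#' @param global_signal Regress out a global signal?
#' @param global Optional explicit global-signal column; defaults to the
#'   row mean of the (filtered) ROI series when `global_signal` is TRUE.
#'   Prefer an externally estimated whole-brain signal: regressing the mean
#'   of the analyzed series out of themselves leaves the columns exactly
#'   collinear (they sum to zero), which no full-rank VAR can be fitted to.
#' @param linear_drift Include a linear drift regressor?
#' @param tr Repetition time (bare matrices only).
#' @details When a band-pass is applied, the confound columns are passed
#' through the same filter before the regression. Regressing raw broadband
#' confounds out of filtered data would reintroduce out-of-band components
#' that are identical across ROIs (the negated confound fit), a known
#' artifact of modular filter-then-regress pipelines; filtering the
#' confounds keeps the residuals inside the analysis band.
#' @return Standardized, cleaned `roi_ts`.
#' @export
prep_subject <- function(ts, motion = NULL, tissue = NULL,
                         band = cpgc_defaults()$band,
                         global_signal = cpgc_defaults()$global_signal,
                         global = NULL, linear_drift = TRUE, tr = NULL) {
  ts <- as_roi_ts(ts, tr)
  if (!is.null(band)) ts <- bandpass_filter(ts, band[1], band[2])
  Tn <- nrow(ts$data)
  conf <- NULL
  add <- function(conf, x, nm) {
    x <- as.matrix(x)
    if (is.null(colnames(x)))
      colnames(x) <- if (ncol(x) == 1L) nm else paste0(nm, seq_len(ncol(x)))
    cbind(conf, x)
  }
  if (!is.null(motion)) conf <- add(conf, motion, "motion")
  if (linear_drift) conf <- add(conf, seq_len(Tn) / Tn, "drift")
  if (!is.null(tissue)) conf <- add(conf, tissue, "tissue")
  if (isTRUE(global_signal)) {
    if (is.null(global)) global <- rowMeans(ts$data)
    conf <- add(conf, global, "global")
  }
  if (!is.null(conf) && !is.null(band)) {
    conf <- bandpass_filter(roi_ts(conf, tr = ts$tr), band[1], band[2])$data
    keep <- apply(conf, 2, sd) > 1e-12
    conf <- conf[, keep, drop = FALSE]
    if (ncol(conf) == 0L) conf <- NULL
  }
  ts <- regress_nuisance(ts, conf)
  standardize(ts)
}
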