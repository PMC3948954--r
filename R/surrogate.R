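#' Phase-randomized surrogate of a time series
#'
#' Replaces the Fourier phases of the series with independent uniform
#' phases while keeping the magnitude spectrum, so the surrogate has the
#' original power spectrum (hence autocorrelation) but no temporal relation
#' to any other series randomized independently. The DC bin (and the
#' Nyquist bin for even length) is left untouched, so the output is real
#' and the series mean is preserved.
#'
#' @param x Numeric vector, length >= 3.
#' @return Numeric vector of the same length.
#' @export
phase_randomize <- function(x) {
  x <- as.numeric(x)
  Tn <- length(x)
  if (Tn < 3L) stop("need at least 3 time points")
  F <- fft(x)
  m <- (Tn - 1) %/% 2
  phi <- runif(m, 0, 2 * pi)
  idx <- seq_len(m) + 1L
  F[idx] <- Mod(F[idx]) * exp(1i * phi)
  F[Tn + 2L - idx] <- Conj(F[idx])
  Re(fft(F, inverse = TRUE)) / Tn
}

#' Build the surrogate null ensemble of CPGC matrices
#'
#' Each surrogate independently phase-randomizes every ROI column,
#' standardizes, refits the mMVAR model at the same order and computes the
#' CPGC matrix. The resulting ensemble is the empirical null distribution
#' for every directed path of this subject: it preserves each series'
#' spectrum but destroys all between-series structure, both lagged and
#' zero-lag. Fully reproducible from the R random seed.
#'
#' @param x A standardized `roi_ts` or T x k matrix.
#' @param p Model order.
#' @param n_surr Number of surrogates (study default 10,000).
#' @param include_instantaneous Fit the A(0) terms (as for the observed
#'   data); `FALSE` builds the null for the naive Granger variant.
#' @return A `cpgc_null`: list with `values` (k x k x n_surr array), `n`,
#'   `order`, `roi`, `subject`.
#' @export
build_null <- function(x, p = cpgc_defaults()$order,
                       n_surr = cpgc_defaults()$n_surrogates,
                       include_instantaneous = TRUE) {
  ts <- as_roi_ts(x)
  n_surr <- as.integer(n_surr)
  stopifnot(n_surr >= 0L)
  k <- ncol(ts$data)
  labels <- colnames(ts$data)
  if (n_surr == 0L) {
    values <- array(numeric(0), dim = c(k, k, 0L))
  } else {
    # validate fit preconditions once with the observed series
    fit_mmvar(ts, p, include_instantaneous = include_instantaneous,
              allow_unstandardized = TRUE)
    values <- cpgc_null_cpp(ts$data, p, n_surr, include_instantaneous)
  }
  dimnames(values) <- list(labels, labels, NULL)
  structure(list(values = values, n = n_surr, order = p, roi = labels,
                 subject = ts$subject,
                 include_instantaneous = include_instantaneous),
            class = "cpgc_null")
}

#' @export
print.cpgc_null <- function(x, ...) {
  cat("CPGC surrogate null: ", x$n, " surrogates, k = ", length(x$roi),
      ", order ", x$order, "\n", sep = "")
  invisible(x)
}

#' Empirical p-value against a surrogate null
#'
#' Add-one empirical upper-tail p-value, p = (1 + #\{null >= observed\}) /
#' (1 + n), so that p is never zero and ties count against the observation.
#'
#' @param observed Observed scalar statistic.
#' @param null Numeric vector of null values (nonempty).
#' @return p-value in (0, 1].
#' @export
#' @examples
#' empirical_p(2, runif(999))  # 1/1000 when observed exceeds all nulls
empirical_p <- function(observed, null) {
  null <- as.numeric(null)
  if (length(null) == 0L) stop("empty null ensemble")
  stopifnot(length(observed) == 1L, is.finite(observed))
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' Per-path empirical p-values for a CPGC matrix
#'
#' @param observed k x k observed CPGC matrix.
#' @param null A `cpgc_null` for the same subject and ROI order.
#' @return k x k matrix of p-values (diagonal NA).
#' @export
cpgc_pvalues <- function(observed, null) {
  stopifnot(inherits(null, "cpgc_null"))
  k <- nrow(observed)
  stopifnot(ncol(observed) == k, dim(null$values)[1] == k)
  if (null$n == 0L) stop("empty null ensemble")
  p <- matrix(NA_real_, k, k, dimnames = dimnames(observed))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    p[i, j] <- empirical_p(observed[i, j], null$values[i, j, ])
  }
  p
}

#' Combine p-values with Fisher's method
#'
#' Statistic -2 sum log p, referred to the chi-square distribution with 2m
#' degrees of freedom (m = number of p-values).
#'
#' @param pvalues Vector of p-values in (0, 1].
#' @return List with `statistic`, `df` and `p.value`.
#' @export
#' @examples
#' fisher_combine(c(0.05, 0.05))
fisher_combine <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (length(pvalues) < 1L) stop("need at least one p-value")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stat <- -2 * sum(log(pvalues))
  df <- 2 * length(pvalues)
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Classify significant paths as uni- or bi-directional
#'
#' For each ROI pair: if both directions are significant at `alpha` the
#' pair is bi-directionally connected; if exactly one direction is, the
#' influence is unidirectional in that direction; otherwise none.
#'
#' @param group_p k x k matrix of per-path (combined) p-values; entry
#'   (i, j) is the path j -> i. Diagonal is ignored.
#' @param alpha Significance level (default 0.01).
#' @return A `path_classification`: list with logical `significant` matrix
#'   and a data frame `pairs` (one row per unordered ROI pair with its
#'   class in none/unidirectional/bidirectional).
#' @export
classify_paths <- function(group_p, alpha = cpgc_defaults()$alpha_within) {
  k <- nrow(group_p)
  stopifnot(ncol(group_p) == k)
  labels <- rownames(group_p)
  if (is.null(labels)) labels <- paste0("roi", seq_len(k))
  off <- upper.tri(group_p) | lower.tri(group_p)
  if (anyNA(group_p[off])) stop("group_p has missing off-diagonal entries")
  sig <- group_p < alpha
  diag(sig) <- FALSE

  pairs <- t(utils::combn(k, 2))
  cls <- character(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    ij <- sig[j, i]  # influence i -> j (target j, source i)
    ji <- sig[i, j]  # influence j -> i
    cls[r] <- if (ij && ji) "bidirectional"
      else if (ij) "unidirectional a->b"
      else if (ji) "unidirectional b->a"
      else "none"
  }
  structure(list(
    significant = sig, alpha = alpha,
    pairs = data.frame(roi_a = labels[pairs[, 1]],
                       roi_b = labels[pairs[, 2]],
                       class = cls, stringsAsFactors = FALSE)),
    class = "path_classification")
}

#' Within-group surrogate inference
#'
#' The full within-group inferential chain: for every subject, fit the
#' mMVAR model, build that subject's phase-randomized surrogate null and
#' convert each directed path's observed CPGC into an add-one empirical
#' p-value against the subject's own null; then combine the per-subject
#' p-values per path across the group with Fisher's method and threshold
#' the combined p at `alpha`.
#'
#' @param subjects List of standardized `roi_ts` (one per subject), all
#'   with the same ROI order.
#' @param p Model order.
#' @param n_surr Surrogates per subject.
#' @param alpha Within-group significance level.
#' @param include_instantaneous Fit A(0) terms (the correlation-purged
#'   model); `FALSE` runs the naive Granger baseline.
#' @return A `path_inference`: per-subject observed CPGC (k x k x n array),
#'   per-subject p-values, Fisher statistic and combined p matrices,
#'   significance mask and pair classification.
#' @export
within_group_inference <- function(subjects, p = cpgc_defaults()$order,
                                   n_surr = cpgc_defaults()$n_surrogates,
                                   alpha = cpgc_defaults()$alpha_within,
                                   include_instantaneous = TRUE) {
  stopifnot(length(subjects) >= 1L)
  labels <- colnames(as_roi_ts(subjects[[1]])$data)
  k <- length(labels)
  n <- length(subjects)
  observed <- array(NA_real_, c(k, k, n), dimnames = list(labels, labels, NULL))
  subj_p <- array(NA_real_, c(k, k, n), dimnames = list(labels, labels, NULL))
  for (s in seq_len(n)) {
    ts <- as_roi_ts(subjects[[s]])
    if (!identical(colnames(ts$data), labels))
      stop("subject ", s, " has a different ROI order")
    fit <- fit_mmvar(ts, p, include_instantaneous = include_instantaneous)
    obs <- cpgc_from_model(fit)
    null <- build_null(ts, p, n_surr,
                       include_instantaneous = include_instantaneous)
    observed[, , s] <- obs
    subj_p[, , s] <- cpgc_pvalues(obs, null)
  }
  fisher_stat <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  fisher_p <- fisher_stat
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    fc <- fisher_combine(subj_p[i, j, ])
    fisher_stat[i, j] <- fc$statistic
    fisher_p[i, j] <- fc$p.value
  }
  cls <- classify_paths(fisher_p, alpha)
  structure(list(observed = observed, subject_p = subj_p,
                 fisher_stat = fisher_stat, fisher_p = fisher_p,
                 significant = cls$significant, classification = cls,
                 alpha = alpha, order = p, n_surrogates = n_surr,
                 n_subjects = n, roi = labels,
                 include_instantaneous = include_instantaneous),
            class = "path_inference")
}

#' @export
print.path_inference <- function(x, ...) {
  cat("within-group path inference: ", x$n_subjects, " subjects, k = ",
      length(x$roi), ", order ", x$order, ", ", x$n_surrogates,
      " surrogates\n  significant paths at alpha = ", x$alpha, ": ",
      sum(x$significant), " of ", length(x$roi) * (length(x$roi) - 1),
      "\n", sep = "")
  invisible(x)
}

#' Export significant paths as an edge list
#'
#' @param inference A `path_inference`.
#' @return Data frame with source, target, mean CPGC, combined p and the
#'   pair's direction class, one row per significant directed path.
#' @export
significant_edges <- function(inference) {
  stopifnot(inherits(inference, "path_inference"))
  sig <- inference$significant
  idx <- which(sig, arr.ind = TRUE)
  labels <- inference$roi
  if (nrow(idx) == 0L)
    return(data.frame(source = character(0), target = character(0),
                      cpgc = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE))
  data.frame(
    source = labels[idx[, 2]], target = labels[idx[, 1]],
    cpgc = apply(inference$observed, c(1, 2), mean)[idx],
    p = inference$fisher_p[idx],
    stringsAsFactors = FALSE)
}
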