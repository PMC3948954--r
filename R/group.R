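#' Covariate-adjusted group contrast for one path
#'
#' One-way ANOVA on the per-subject CPGC values of a single directed path
#' with the gray-matter atrophy score entered as a covariate: the linear
#' model value ~ intercept + group + covariate is fitted and the group
#' effect reported as an F statistic (the squared t of the group
#' coefficient) with its p-value; the direction of the difference comes
#' from the sign of the group coefficient. A covariate with zero variance
#' (or none supplied) reduces exactly to the plain one-way ANOVA.
#'
#' @param values Per-subject CPGC values for the path.
#' @param group Factor or character with exactly two levels (e.g.
#'   patient/control), aligned with `values`.
#' @param covariate Optional per-subject numeric covariate.
#' @return List with `statistic` (F), `p.value`, `direction` (the label of
#'   the group with the larger adjusted mean) and `df`.
#' @export
ancova_path <- function(values, group, covariate = NULL) {
  values <- as.numeric(values)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  if (any(table(group) < 2L)) stop("each group needs at least 2 subjects")
  stopifnot(length(group) == length(values))
  if (sd(values) == 0) stop("path values are constant; degenerate model")
  g <- as.integer(group == levels(group)[2L])
  if (!is.null(covariate)) {
    covariate <- as.numeric(covariate)
    stopifnot(length(covariate) == length(values))
    if (any(!is.finite(covariate))) stop("covariate contains non-finite values")
    if (sd(covariate) == 0) covariate <- NULL  # drops out
  }
  X <- if (is.null(covariate)) cbind(1, g) else cbind(1, g, covariate)
  fit <- lm.fit(X, values)
  df_res <- length(values) - ncol(X)
  rss <- sum(fit$residuals^2)
  s2 <- rss / df_res
  XtXinv <- chol2inv(chol(crossprod(X)))
  se_g <- sqrt(s2 * XtXinv[2L, 2L])
  tval <- fit$coefficients[2L] / se_g
  Fval <- tval^2
  p <- pf(Fval, 1, df_res, lower.tail = FALSE)
  direction <- if (fit$coefficients[2L] >= 0)
    paste0(levels(group)[2L], ">", levels(group)[1L])
  else paste0(levels(group)[1L], ">", levels(group)[2L])
  list(statistic = unname(Fval), p.value = unname(p),
       direction = direction, df = c(1, df_res))
}

#' Masked between-group difference of causal paths
#'
#' Runs the covariate-adjusted contrast on every directed path and applies
#' the within-group significance masks: the increased set is the
#' intersection of paths with patient > control at `alpha` and the paths
#' significant within the patient group; the decreased set intersects
#' control > patient with the within-control significant paths. Paths
#' significant between groups but in neither mask are excluded.
#'
#' @param patient_cpgc,control_cpgc k x k x n arrays of per-subject CPGC
#'   matrices (as in `path_inference$observed`); ROI dimnames must agree.
#' @param patient_mask,control_mask Logical k x k within-group significance
#'   masks (or `path_inference` objects).
#' @param covariate Optional per-subject covariate, patients first then
#'   controls, in the array order.
#' @param alpha Between-group significance level (default 0.01).
#' @param labels Group labels, `c(patient, control)`.
#' @return A `group_diff`: per-path table plus `increased`/`decreased`
#'   logical masks and edge data frames.
#' @export
masked_group_difference <- function(patient_cpgc, control_cpgc,
                                    patient_mask, control_mask,
                                    covariate = NULL,
                                    alpha = cpgc_defaults()$alpha_between,
                                    labels = c("patient", "control")) {
  if (inherits(patient_mask, "path_inference"))
    patient_mask <- patient_mask$significant
  if (inherits(control_mask, "path_inference"))
    control_mask <- control_mask$significant
  k <- dim(patient_cpgc)[1]
  stopifnot(dim(control_cpgc)[1] == k, dim(patient_cpgc)[2] == k,
            all(dim(patient_mask) == c(k, k)),
            all(dim(control_mask) == c(k, k)))
  rn_p <- dimnames(patient_cpgc)[[1]]; rn_c <- dimnames(control_cpgc)[[1]]
  if (!is.null(rn_p) && !is.null(rn_c) && !identical(rn_p, rn_c))
    stop("ROI order differs between the two groups")
  n1 <- dim(patient_cpgc)[3]; n2 <- dim(control_cpgc)[3]
  group <- factor(rep(labels, c(n1, n2)), levels = labels)
  if (!is.null(covariate)) stopifnot(length(covariate) == n1 + n2)

  roi <- rn_p %||% paste0("roi", seq_len(k))
  Fmat <- matrix(NA_real_, k, k, dimnames = list(roi, roi))
  pmat <- Fmat
  dirmat <- matrix(NA_character_, k, k, dimnames = list(roi, roi))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    vals <- c(patient_cpgc[i, j, ], control_cpgc[i, j, ])
    a <- ancova_path(vals, group, covariate)
    Fmat[i, j] <- a$statistic
    pmat[i, j] <- a$p.value
    dirmat[i, j] <- a$direction
  }
  pat_gt <- pmat < alpha & dirmat == paste0(labels[1], ">", labels[2])
  con_gt <- pmat < alpha & dirmat == paste0(labels[2], ">", labels[1])
  pat_gt[is.na(pat_gt)] <- FALSE
  con_gt[is.na(con_gt)] <- FALSE
  increased <- pat_gt & patient_mask
  decreased <- con_gt & control_mask

  edge_df <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    data.frame(source = roi[idx[, 2]], target = roi[idx[, 1]],
               F = Fmat[idx], p = pmat[idx], stringsAsFactors = FALSE)
  }
  structure(list(F = Fmat, p = pmat, direction = dirmat,
                 increased = increased, decreased = decreased,
                 increased_edges = edge_df(increased),
                 decreased_edges = edge_df(decreased),
                 alpha = alpha, labels = labels),
            class = "group_diff")
}

#' @export
print.group_diff <- function(x, ...) {
  cat("masked group contrast at alpha = ", x$alpha, ": ",
      sum(x$increased), " increased, ", sum(x$decreased),
      " decreased path(s)\n", sep = "")
  invisible(x)
}

#' Connectivity-behavior correlation for one path
#'
#' Pearson correlation between per-subject CPGC values of a path and a
#' neuropsychological score, with the two-sided p-value from the t
#' transform with n-2 degrees of freedom.
#'
#' @param values Per-subject CPGC values.
#' @param scores Per-subject behavioral scores (same length, n >= 3).
#' @param measure Optional name of the behavioral measure.
#' @return List with `r`, `p.value`, `n`, `measure`.
#' @export
behavior_correlation <- function(values, scores, measure = NA_character_) {
  values <- as.numeric(values); scores <- as.numeric(scores)
  stopifnot(length(values) == length(scores))
  if (length(values) < 3L) stop("need at least 3 subjects")
  if (any(!is.finite(scores)) || any(!is.finite(values)))
    stop("non-finite values or scores")
  ct <- cor.test(values, scores, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value,
       n = length(values), measure = measure)
}

#' Motion quality control: mean FD vs path strength
#'
#' Correlates each path's per-subject CPGC values with the subjects' mean
#' framewise displacement and reports paths with p below `flag_alpha`.
#' Paths (or an FD vector) with zero variance are excluded and flagged as
#' undefined.
#'
#' @param mean_fds Per-subject mean FD (mm).
#' @param path_values Subjects x paths matrix, or a k x k x n array of
#'   per-subject CPGC matrices.
#' @param flag_alpha Flagging level (default 0.05).
#' @return Data frame with `path`, `r`, `p`, `flagged` (p < `flag_alpha`)
#'   and `defined`.
#' @export
qc_motion_correlation <- function(mean_fds, path_values, flag_alpha = 0.05) {
  mean_fds <- as.numeric(mean_fds)
  if (length(dim(path_values)) == 3L) {
    k <- dim(path_values)[1]
    roi <- dimnames(path_values)[[1]] %||% paste0("roi", seq_len(k))
    cols <- list(); nms <- character(0)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      cols[[length(cols) + 1L]] <- path_values[i, j, ]
      nms <- c(nms, paste0(roi[j], "->", roi[i]))
    }
    path_values <- do.call(cbind, cols)
    colnames(path_values) <- nms
  }
  path_values <- as.matrix(path_values)
  stopifnot(nrow(path_values) == length(mean_fds))
  nms <- colnames(path_values) %||% paste0("path", seq_len(ncol(path_values)))
  fd_const <- sd(mean_fds) == 0
  out <- lapply(seq_len(ncol(path_values)), function(jj) {
    v <- path_values[, jj]
    if (fd_const || sd(v) == 0)
      return(data.frame(path = nms[jj], r = NA_real_, p = NA_real_,
                        flagged = FALSE, defined = FALSE,
                        stringsAsFactors = FALSE))
    ct <- cor.test(mean_fds, v, method = "pearson")
    data.frame(path = nms[jj], r = unname(ct$estimate), p = ct$p.value,
               flagged = ct$p.value < flag_alpha, defined = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Two-sample t-test from summary statistics
#'
#' Two-tailed t-test computed from group means, SDs and sizes, as used for
#' demographic tables. Pooled-variance (Student) by default; Welch with
#' `equal_var = FALSE`.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param equal_var Pool the variances?
#' @return List with `statistic` (t), `df`, `p.value`.
#' @export
#' @examples
#' summary_stat_ttest(25.94, 1.65, 16, 28.56, 0.63, 16)
summary_stat_ttest <- function(mean1, sd1, n1, mean2, sd2, n2,
                               equal_var = TRUE) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  if (equal_var) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  list(statistic = t, df = df,
       p.value = 2 * pt(abs(t), df, lower.tail = FALSE))
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' Two-tailed Pearson chi-square; the Yates continuity correction is
#' applied when any expected count is below 5 (`continuity = "auto"`), or
#' can be forced on/off.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @param continuity "auto" (expected-count rule), "always" or "never".
#' @return List with `statistic`, `df`, `p.value`, `corrected`.
#' @export
#' @examples
#' contingency_chi2(matrix(c(10, 10, 6, 6), 2))  # identical groups: p = 1
contingency_chi2 <- function(tab, continuity = c("auto", "always", "never")) {
  continuity <- match.arg(continuity)
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has a zero margin; expected counts undefined")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  correct <- switch(continuity, auto = any(expected < 5),
                    always = TRUE, never = FALSE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value, corrected = correct)
}
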