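# Score distributions used to emulate a two-group aMCI-like cohort
# (means and SDs of the demographic/neuropsychological measures).
score_params <- function() {
  list(
    age            = list(patient = c(68.50, 7.77), control = c(67.19, 8.38)),
    education      = list(patient = c(10.06, 3.91), control = c(9.06, 3.64)),
    MMSE           = list(patient = c(25.94, 1.65), control = c(28.56, 0.63)),
    CVLT_immediate = list(patient = c(8.39, 1.23),  control = c(11.33, 1.86)),
    CVLT_short     = list(patient = c(9.13, 1.23),  control = c(13.00, 1.86)),
    CVLT_long      = list(patient = c(7.31, 1.43),  control = c(12.62, 1.36)),
    CDT            = list(patient = c(5.75, 0.54),  control = c(8.62, 1.36)))
}

companion_radius <- function(A) {
  k <- dim(A)[1]; p <- dim(A)[3]
  comp <- matrix(0, k * p, k * p)
  for (n in seq_len(p)) comp[1:k, ((n - 1) * k + 1):(n * k)] <- A[, , n]
  if (p > 1) comp[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Ground truth for a synthetic two-group cohort
#'
#' Defines the data-generating process: per-group lagged coefficient
#' tensors (the planted causal structure), an innovation mixing matrix that
#' induces zero-lag correlation without any lagged coupling, and optional
#' behavior coupling. Three scenario presets cover the test bed:
#'
#' * `"null"`: no cross coefficients, identity mixing; each node is an
#'   AR(1) with coefficient `ar`.
#' * `"instantaneous-only"`: all lagged coefficients zero; innovations are
#'   mixed to an equicorrelation structure of `mixing_corr` — pure
#'   instantaneous correlation with no causality, the case the
#'   correlation-purged estimator exists for.
#' * `"one-edge"`: AR(1) nodes plus a single lagged edge
#'   `edge[2] -> edge[1]` of size `edge_strength`, planted in the patient
#'   group only.
#'
#' Stationarity (companion-matrix spectral radius < 1) is checked at
#' construction for both groups.
#'
#' @param scenario Scenario preset.
#' @param k Number of nodes (default 6; 33 at study scale).
#' @param ar Diagonal AR(1) coefficient for temporally structured scenarios.
#' @param edge Planted edge as `c(target, source)` node indices.
#' @param edge_strength Lag-1 coefficient of the planted edge.
#' @param edge_jitter_sd Between-subject SD of the planted edge strength
#'   (gives subjects individual path strengths for behavior coupling).
#' @param mixing_corr Pairwise innovation correlation for
#'   `"instantaneous-only"`.
#' @param innovation_sd Innovation standard deviation.
#' @param behavior Optional behavior coupling: a list with elements
#'   `measure` (score column name, e.g. "MMSE") and `r` (target Pearson
#'   correlation between the planted path strength and the score across
#'   patients).
#' @return A `ground_truth` object.
#' @export
make_ground_truth <- function(scenario = c("null", "instantaneous-only",
                                           "one-edge"),
                              k = 6, ar = 0.3, edge = c(2L, 1L),
                              edge_strength = 0.4, edge_jitter_sd = 0.1,
                              mixing_corr = 0.6, innovation_sd = 1,
                              behavior = NULL) {
  scenario <- match.arg(scenario)
  k <- as.integer(k)
  stopifnot(k >= 2L)
  p <- 1L
  base <- array(0, c(k, k, p))
  mixing <- diag(k)
  edges <- data.frame(target = integer(0), source = integer(0),
                      lag = integer(0), group = character(0),
                      strength = numeric(0), stringsAsFactors = FALSE)
  if (scenario == "null") {
    for (i in seq_len(k)) base[i, i, 1] <- ar
  } else if (scenario == "instantaneous-only") {
    R <- matrix(mixing_corr, k, k); diag(R) <- 1
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("mixing correlation ", mixing_corr,
                           " is not positive definite for k = ", k)
    mixing <- t(chol(R))
  } else { # one-edge
    for (i in seq_len(k)) base[i, i, 1] <- ar
    stopifnot(length(edge) == 2L, edge[1] != edge[2],
              all(edge >= 1), all(edge <= k))
    edges <- data.frame(target = as.integer(edge[1]),
                        source = as.integer(edge[2]),
                        lag = 1L, group = "patient",
                        strength = edge_strength, stringsAsFactors = FALSE)
  }
  A <- list(patient = base, control = base)
  for (r in seq_len(nrow(edges)))
    A[[edges$group[r]]][edges$target[r], edges$source[r], edges$lag[r]] <-
      edges$strength[r]
  for (g in names(A)) {
    rad <- companion_radius(A[[g]])
    if (rad >= 1)
      stop("requested coefficients make the ", g,
           " system non-stationary (spectral radius ", signif(rad, 4), ")")
  }
  structure(list(scenario = scenario, k = k, p = p, A = A, mixing = mixing,
                 innovation_sd = innovation_sd, edges = edges,
                 edge_jitter_sd = edge_jitter_sd, behavior = behavior),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground truth: scenario '", x$scenario, "', k = ", x$k,
      ", ", nrow(x$edges), " planted differential edge(s)\n", sep = "")
  invisible(x)
}

#' Cohort configuration
#'
#' Acquisition and noise settings of the synthetic cohort. The defaults
#' reproduce the emulated study's dimensions: 16 subjects per group, 229
#' frames at TR 2 s.
#'
#' @param n_per_group Subjects per group.
#' @param n_frames Frames per subject.
#' @param tr Repetition time, seconds.
#' @param hrf Convolve the latent VAR signal with a canonical double-gamma
#'   hemodynamic response (peak 6 s, undershoot 16 s, ratio 6) sampled at TR?
#' @param drift_amplitude SD of the added linear drift component (in units
#'   of the signal SD).
#' @param global_amplitude SD of a shared global component added to every
#'   node (0 disables; used by global-signal sensitivity experiments).
#' @param translation_sd,rotation_sd Per-frame random-walk increments of
#'   the simulated motion trace (mm, degrees).
#' @param atrophy_shift Group shift of the atrophy covariate (patients
#'   lower by this many SD).
#' @param burn_in Initial VAR samples discarded before recording.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 16,
                          n_frames = cpgc_defaults()$n_frames,
                          tr = cpgc_defaults()$tr,
                          hrf = TRUE, drift_amplitude = 0.5,
                          global_amplitude = 0,
                          translation_sd = 0.03, rotation_sd = 0.02,
                          atrophy_shift = 0.5, burn_in = 200) {
  stopifnot(n_per_group >= 2, n_frames >= 20, tr > 0, burn_in >= 0)
  structure(list(n_per_group = as.integer(n_per_group),
                 n_frames = as.integer(n_frames), tr = tr, hrf = hrf,
                 drift_amplitude = drift_amplitude,
                 global_amplitude = global_amplitude,
                 translation_sd = translation_sd, rotation_sd = rotation_sd,
                 atrophy_shift = atrophy_shift,
                 burn_in = as.integer(burn_in)),
            class = "cohort_config")
}

#' Canonical double-gamma HRF sampled at TR
#'
#' @param tr Sampling interval, seconds.
#' @param duration Kernel length, seconds.
#' @return Numeric kernel, normalized to unit peak.
#' @export
canonical_hrf <- function(tr = cpgc_defaults()$tr, duration = 32) {
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

ar1_series <- function(n, phi = 0.5) {
  as.numeric(stats::filter(rnorm(n), phi, method = "recursive"))
}

#' Simulate one subject's ROI time series
#'
#' Iterates the group's VAR with Gaussian innovations mixed by the
#' zero-lag mixing matrix, discards the burn-in, optionally convolves each
#' node with the canonical HRF (then rescales each node to unit SD), and
#' adds the configured drift and global components. Also fabricates a
#' 6-parameter random-walk motion trace and two tissue (WM/CSF-like)
#' nuisance series.
#'
#' @param gt A `ground_truth`.
#' @param group `"patient"` or `"control"`.
#' @param cfg A `cohort_config`.
#' @param subject Subject id.
#' @param edge_strengths Optional vector of realized strengths for this
#'   subject's planted edges (defaults to the group values).
#' @return List with `ts` (a `roi_ts`), `motion`, `tissue`, `global`,
#'   `group`, `subject`, `edge_strengths`.
#' @export
simulate_subject <- function(gt, group = c("patient", "control"),
                             cfg = cohort_config(),
                             subject = NA_character_,
                             edge_strengths = NULL) {
  group <- match.arg(group)
  stopifnot(inherits(gt, "ground_truth"))
  k <- gt$k; p <- gt$p
  A <- gt$A[[group]]
  ge <- gt$edges[gt$edges$group == group, , drop = FALSE]
  if (!is.null(edge_strengths)) {
    stopifnot(length(edge_strengths) == nrow(ge))
    for (r in seq_len(nrow(ge)))
      A[ge$target[r], ge$source[r], ge$lag[r]] <- edge_strengths[r]
    rad <- companion_radius(A)
    if (rad >= 1) stop("subject-level coefficients are non-stationary")
  } else {
    edge_strengths <- ge$strength
  }
  Tn <- cfg$n_frames; burn <- cfg$burn_in
  total <- Tn + burn
  innov <- gt$mixing %*% matrix(rnorm(k * total, sd = gt$innovation_sd),
                                k, total)
  X <- matrix(0, total, k)
  for (t in seq_len(total)) {
    acc <- innov[, t]
    for (n in seq_len(p)) if (t > n) acc <- acc + A[, , n] %*% X[t - n, ]
    X[t, ] <- acc
  }
  if (isTRUE(cfg$hrf)) {
    h <- canonical_hrf(cfg$tr)
    if (burn < length(h))
      stop("burn_in must be at least the HRF kernel length (",
           length(h), " frames)")
    X <- apply(X, 2, function(col)
      stats::filter(col, h, method = "convolution", sides = 1))
    X <- X[!apply(is.na(X), 1, any), , drop = FALSE]
  }
  X <- X[(nrow(X) - Tn + 1):nrow(X), , drop = FALSE]
  X <- scale(X, center = TRUE, scale = apply(X, 2, sd))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  if (cfg$drift_amplitude > 0) {
    drift <- seq_len(Tn); drift <- (drift - mean(drift)) / sd(drift)
    X <- X + cfg$drift_amplitude * drift
  }
  global <- ar1_series(Tn, 0.6)
  global <- (global - mean(global)) / sd(global)
  if (cfg$global_amplitude > 0) X <- X + cfg$global_amplitude * global
  colnames(X) <- paste0("node", seq_len(k))

  motion <- cbind(
    apply(matrix(rnorm(Tn * 3, sd = cfg$translation_sd), Tn, 3), 2, cumsum),
    apply(matrix(rnorm(Tn * 3, sd = cfg$rotation_sd), Tn, 3), 2, cumsum))
  colnames(motion) <- c("dx", "dy", "dz", "alpha", "beta", "gamma")
  tissue <- cbind(wm = ar1_series(Tn, 0.5), csf = ar1_series(Tn, 0.5))

  list(ts = roi_ts(unclass(X), tr = cfg$tr, subject = subject),
       motion = motion, tissue = tissue, global = global,
       group = group, subject = subject, edge_strengths = edge_strengths)
}

#' Simulate a two-group cohort
#'
#' Generates `n_per_group` subjects per group via [simulate_subject()],
#' drawing each subject's planted edge strengths around the group value
#' (SD `edge_jitter_sd`, truncated at zero), plus a metadata table with
#' demographic and neuropsychological scores, a per-subject atrophy
#' covariate (patients shifted down by `atrophy_shift` SD) and the mean
#' framewise displacement of the fabricated motion trace. When the ground
#' truth requests behavior coupling, the patients' target score is
#' regenerated as a linear function of their realized planted path
#' strength plus noise, calibrated so the population correlation equals
#' the requested `r`.
#'
#' @param gt A `ground_truth`.
#' @param cfg A `cohort_config`.
#' @param seed Optional integer seed (restores full reproducibility).
#' @return A `cohort`: list with `subjects`, `meta`, `gt`, `cfg`.
#' @export
simulate_cohort <- function(gt, cfg = cohort_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(gt, "ground_truth"), inherits(cfg, "cohort_config"))
  n <- cfg$n_per_group
  sp <- score_params()
  subjects <- list()
  meta <- list()
  for (g in c("patient", "control")) {
    ge <- gt$edges[gt$edges$group == g, , drop = FALSE]
    for (s in seq_len(n)) {
      id <- sprintf("%s%02d", if (g == "patient") "P" else "C", s)
      strengths <- if (nrow(ge))
        pmax(0, ge$strength + rnorm(nrow(ge), sd = gt$edge_jitter_sd))
      else numeric(0)
      subj <- simulate_subject(gt, g, cfg, subject = id,
                               edge_strengths = strengths)
      subjects[[id]] <- subj
      row <- data.frame(subject = id, group = g,
                        sex = if (s <= round(n * 10 / 16)) "F" else "M",
                        stringsAsFactors = FALSE)
      for (m in names(sp)) {
        pars <- sp[[m]][[g]]
        row[[m]] <- rnorm(1, pars[1], pars[2])
      }
      row$atrophy <- rnorm(1) - if (g == "patient") cfg$atrophy_shift else 0
      row$mean_fd <- framewise_displacement(subj$motion)$mean_fd
      meta[[id]] <- row
    }
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL

  if (!is.null(gt$behavior) && nrow(gt$edges)) {
    b <- gt$behavior
    stopifnot(!is.null(b$measure), !is.null(b$r), abs(b$r) <= 1)
    pat <- meta$group == "patient"
    strengths <- vapply(subjects[meta$subject[pat]],
                        function(s) s$edge_strengths[1], numeric(1))
    z <- as.numeric(scale(strengths))
    score_std <- b$r * z + sqrt(1 - b$r^2) * rnorm(sum(pat))
    pars <- sp[[b$measure]][["patient"]]
    meta[[b$measure]][pat] <- pars[1] + pars[2] * score_std
  }
  structure(list(subjects = subjects, meta = meta, gt = gt, cfg = cfg),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("synthetic cohort: ", x$cfg$n_per_group, " + ", x$cfg$n_per_group,
      " subjects, ", x$cfg$n_frames, " frames x ", x$gt$k,
      " nodes, scenario '", x$gt$scenario, "'\n", sep = "")
  invisible(x)
}
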