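test_that("scenario presets build the advertised coefficient structure", {
  null_gt <- make_ground_truth("null", k = 5, ar = 0.3)
  off <- row(diag(5)) != col(diag(5))
  expect_true(all(null_gt$A$patient[, , 1][off] == 0))
  expect_equal(null_gt$mixing, diag(5))

  inst <- make_ground_truth("instantaneous-only", k = 6, mixing_corr = 0.6)
  expect_true(all(inst$A$patient == 0))
  expect_equal(inst$mixing %*% t(inst$mixing),
               {R <- matrix(0.6, 6, 6); diag(R) <- 1; R}, tolerance = 1e-12)

  one <- make_ground_truth("one-edge", k = 6, edge = c(2, 1),
                           edge_strength = 0.4)
  expect_equal(one$A$patient[2, 1, 1], 0.4)
  expect_equal(one$A$control[2, 1, 1], 0)
  expect_equal(one$A$patient[1, 2, 1], 0)
  expect_equal(nrow(one$edges), 1L)
})

test_that("non-stationary requests are rejected at construction", {
  expect_error(make_ground_truth("null", k = 3, ar = 1.05),
               "non-stationary")
})

test_that("instantaneous-only innovations have the requested correlation", {
  set.seed(61)
  gt <- make_ground_truth("instantaneous-only", k = 4, mixing_corr = 0.6)
  cfg <- cohort_config(n_per_group = 2, n_frames = 5000, hrf = FALSE,
                       drift_amplitude = 0)
  s <- simulate_subject(gt, "patient", cfg)
  cc <- cor(s$ts$data)
  expect_lt(max(abs(cc[upper.tri(cc)] - 0.6)), 0.05)
  # and essentially no lagged cross-correlation
  lag1 <- cor(s$ts$data[-1, 1], s$ts$data[-5000, 2])
  expect_lt(abs(lag1), 0.05)
})

test_that("subject simulation is deterministic and well-shaped", {
  gt <- make_ground_truth("one-edge", k = 6)
  cfg <- cohort_config(n_per_group = 16)
  set.seed(62); s1 <- simulate_subject(gt, "patient", cfg, subject = "P01")
  set.seed(62); s2 <- simulate_subject(gt, "patient", cfg, subject = "P01")
  expect_identical(s1$ts$data, s2$ts$data)
  expect_identical(s1$motion, s2$motion)
  expect_equal(dim(s1$ts$data), c(229L, 6L))
  expect_equal(dim(s1$motion), c(229L, 6L))
  expect_equal(colnames(s1$tissue), c("wm", "csf"))
  expect_equal(s1$ts$tr, 2)
})

test_that("the planted coefficient is recovered from long unblurred runs", {
  set.seed(63)
  gt <- make_ground_truth("one-edge", k = 4, edge_strength = 0.4)
  cfg <- cohort_config(n_per_group = 2, n_frames = 2000, hrf = FALSE,
                       drift_amplitude = 0)
  s <- simulate_subject(gt, "patient", cfg)
  fit <- fit_mmvar(standardize(s$ts), 1)
  # theoretical standardized coefficient a * sd(x1)/sd(x2) from the
  # stationary moments of x1 ~ AR(1) and x2 = .3 x2- + .4 x1- + e
  V1 <- 1 / (1 - 0.3^2)
  C12 <- 0.3 * 0.4 * V1 / (1 - 0.3^2)
  V2 <- (0.4^2 * V1 + 2 * 0.3 * 0.4 * C12 + 1) / (1 - 0.3^2)
  theo <- 0.4 * sqrt(V1 / V2)
  expect_lt(abs(fit$Alags[[1]][2, 1] - theo), 0.05)
  con <- simulate_subject(gt, "control", cfg)
  fitc <- fit_mmvar(standardize(con$ts), 1)
  expect_lt(abs(fitc$Alags[[1]][2, 1]), 0.05)
})

test_that("null-scenario series show no cross-correlation structure", {
  set.seed(64)
  gt <- make_ground_truth("null", k = 4)
  cfg <- cohort_config(n_per_group = 2, n_frames = 3000, hrf = FALSE,
                       drift_amplitude = 0)
  s <- simulate_subject(gt, "patient", cfg)
  X <- s$ts$data
  for (l in 0:3) {
    cc <- cor(X[(1 + l):nrow(X), 1], X[seq_len(nrow(X) - l), 2])
    expect_lt(abs(cc), 4 / sqrt(nrow(X) - l) + 0.02)
  }
  # own autocorrelation decays from the AR(1) value
  ac <- acf(X[, 1], lag.max = 3, plot = FALSE)$acf[-1]
  expect_lt(abs(ac[1] - 0.3), 0.06)
  expect_lt(abs(ac[3]), 0.1)
})

test_that("cohorts carry aligned metadata, scores and covariates", {
  gt <- make_ground_truth("one-edge", k = 6,
                          behavior = list(measure = "MMSE", r = 0.6))
  cfg <- cohort_config(n_per_group = 8, n_frames = 120)
  coh <- simulate_cohort(gt, cfg, seed = 65)
  expect_equal(length(coh$subjects), 16L)
  expect_equal(nrow(coh$meta), 16L)
  expect_setequal(coh$meta$group, c("patient", "control"))
  expect_true(all(c("MMSE", "CVLT_long", "CDT", "atrophy", "mean_fd")
                  %in% names(coh$meta)))
  expect_equal(coh$meta$subject, names(coh$subjects))
  # reproducibility from the seed
  coh2 <- simulate_cohort(gt, cfg, seed = 65)
  expect_identical(coh$subjects[[1]]$ts$data, coh2$subjects[[1]]$ts$data)
  expect_identical(coh$meta, coh2$meta)
})

test_that("behavior coupling and atrophy shift land near their targets", {
  set.seed(66)
  gt <- make_ground_truth("one-edge", k = 3,
                          behavior = list(measure = "MMSE", r = 0.6))
  cfg <- cohort_config(n_per_group = 16, n_frames = 24, burn_in = 0,
                       hrf = FALSE, atrophy_shift = 0.5)
  rs <- replicate(60, {
    coh <- simulate_cohort(gt, cfg)
    pat <- coh$meta$group == "patient"
    strengths <- vapply(coh$subjects[coh$meta$subject[pat]],
                        function(s) s$edge_strengths[1], numeric(1))
    cor(strengths, coh$meta$MMSE[pat])
  })
  expect_lt(abs(mean(rs) - 0.6), 0.08)

  shifts <- replicate(200, {
    coh <- simulate_cohort(gt, cohort_config(n_per_group = 16, n_frames = 24,
                                             burn_in = 0, hrf = FALSE,
                                             atrophy_shift = 0))
    pat <- coh$meta$group == "patient"
    t.test(coh$meta$atrophy[pat], coh$meta$atrophy[!pat])$p.value
  })
  expect_gt(ks.test(shifts, "punif")$p.value, 0.01)
})
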