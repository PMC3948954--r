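test_that("the group contrast reduces to one-way ANOVA without a covariate", {
  set.seed(51)
  vals <- rnorm(32)
  grp <- rep(c("patient", "control"), each = 16)
  a1 <- ancova_path(vals, grp)
  ref <- anova(lm(vals ~ factor(grp)))
  expect_equal(a1$statistic, ref$`F value`[1], tolerance = 1e-8)
  expect_equal(a1$p.value, ref$`Pr(>F)`[1], tolerance = 1e-8)
  # zero-variance covariate drops out
  a2 <- ancova_path(vals, grp, covariate = rep(3, 32))
  expect_equal(a2$statistic, a1$statistic, tolerance = 1e-8)
  # with a covariate it matches the linear-model F for the group term
  cov <- rnorm(32)
  a3 <- ancova_path(vals, grp, covariate = cov)
  ref3 <- summary(lm(vals ~ factor(grp) + cov))$coefficients
  expect_equal(a3$statistic, ref3[2, "t value"]^2, tolerance = 1e-8)
  expect_error(ancova_path(rep(1, 32), grp), "constant")
})

test_that("group-contrast p-values are uniform under the null", {
  set.seed(52)
  grp <- rep(c("patient", "control"), each = 16)
  cov <- rnorm(32)
  ps <- replicate(2000, ancova_path(rnorm(32), grp, cov)$p.value)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("power at a planted 1-SD shift matches the t-test closed form", {
  set.seed(53)
  grp <- rep(c("control", "patient"), each = 16)
  rej <- replicate(2000, {
    v <- rnorm(32) + (grp == "patient") * 1
    a <- ancova_path(v, grp)
    a$p.value < 0.01 && a$direction == "patient>control"
  })
  theo <- power.t.test(n = 16, delta = 1, sd = 1, sig.level = 0.01)$power
  expect_lt(abs(mean(rej) - theo), 0.05)
})

test_that("a covariate that carries the group difference absorbs it", {
  set.seed(54)
  grp <- rep(c("patient", "control"), each = 16)
  ps <- replicate(500, {
    cov <- rnorm(32) + (grp == "patient") * 2
    v <- cov + rnorm(32, sd = 0.5)   # group difference flows through cov
    ancova_path(v, grp, cov)$p.value
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("masked contrasts intersect ANOVA hits with within-group masks", {
  set.seed(55)
  k <- 4; n <- 16
  roi <- letters[1:4]
  base <- function() {
    a <- array(abs(rnorm(k * k * n, mean = 0.2, sd = 0.02)), c(k, k, n),
               dimnames = list(roi, roi, NULL))
    for (s in seq_len(n)) diag(a[, , s]) <- 0
    a
  }
  pat <- base(); con <- base()
  pat[2, 1, ] <- pat[2, 1, ] + 1    # huge patient>control difference
  pat[4, 3, ] <- pat[4, 3, ] + 1    # same, but will be masked out
  mask_none <- matrix(FALSE, k, k, dimnames = list(roi, roi))
  pat_mask <- mask_none; pat_mask[2, 1] <- TRUE
  con_mask <- mask_none
  gd <- masked_group_difference(pat, con, pat_mask, con_mask, alpha = 0.01)
  expect_true(gd$increased[2, 1])
  expect_false(gd$increased[4, 3])   # significant but not in the mask
  expect_equal(sum(gd$increased), 1L)
  expect_equal(sum(gd$decreased), 0L)
  expect_equal(gd$increased_edges$source, "a")
  expect_equal(gd$increased_edges$target, "b")
  # monotone in alpha: stricter sets nest inside looser ones
  full_mask <- !diag(k); dimnames(full_mask) <- list(roi, roi)
  g1 <- masked_group_difference(pat, con, full_mask, full_mask, alpha = 0.005)
  g2 <- masked_group_difference(pat, con, full_mask, full_mask, alpha = 0.01)
  expect_true(all(g2$increased[g1$increased]))
  expect_true(all(g2$decreased[g1$decreased]))
})

test_that("identical groups rarely yield any masked difference", {
  set.seed(56)
  k <- 6; n <- 16
  empty_cohorts <- replicate(20, {
    pat <- array(abs(rnorm(k * k * n, 0.2, 0.05)), c(k, k, n))
    con <- array(abs(rnorm(k * k * n, 0.2, 0.05)), c(k, k, n))
    full <- !diag(k)
    gd <- masked_group_difference(pat, con, full, full, alpha = 0.01)
    sum(gd$increased) + sum(gd$decreased) == 0
  })
  expect_gte(mean(empty_cohorts), 0.7)
})

test_that("behavior correlation matches first principles", {
  set.seed(57)
  v <- rnorm(16)
  exact <- behavior_correlation(v, 2 * v + 3)
  expect_equal(exact$r, 1, tolerance = 1e-12)
  expect_lt(exact$p.value, 1e-12)
  s <- rnorm(16)
  bc <- behavior_correlation(v, s, measure = "MMSE")
  r_direct <- cov(v, s) / (sd(v) * sd(s))
  expect_equal(bc$r, r_direct, tolerance = 1e-12)
  t_direct <- r_direct * sqrt(14 / (1 - r_direct^2))
  expect_equal(bc$p.value, 2 * pt(abs(t_direct), 14, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(behavior_correlation(1:2, 1:2), "at least 3")
  # type-I control at n = 16
  rej <- replicate(2000, behavior_correlation(rnorm(16), rnorm(16))$p.value < 0.05)
  expect_lt(abs(mean(rej) - 0.05),
            3 * sqrt(0.05 * 0.95 / 2000) + 0.01)
})

test_that("behavior coupling in the generator is recovered at target r", {
  set.seed(58)
  rs <- replicate(300, {
    strength <- pmax(0, 0.4 + rnorm(16, sd = 0.1))
    z <- as.numeric(scale(strength))
    score <- 0.6 * z + sqrt(1 - 0.36) * rnorm(16)
    cor(strength, score)
  })
  expect_lt(abs(mean(rs) - 0.6), 0.05)
})

test_that("motion QC flags only what it should", {
  set.seed(59)
  n <- 16
  fd <- abs(rnorm(n, 0.15, 0.05))
  paths <- matrix(rnorm(n * 50), n, 50)
  qc <- qc_motion_correlation(fd, paths)
  expect_true(all(qc$defined))
  expect_lt(mean(qc$flagged), 0.2)   # ~5% expected under independence
  # a path equal to FD correlates perfectly
  qc2 <- qc_motion_correlation(fd, cbind(exact = fd, noise = rnorm(n)))
  expect_equal(qc2$r[1], 1, tolerance = 1e-12)
  # constant FD is undefined, excluded rather than flagged
  qc3 <- qc_motion_correlation(rep(0.1, n), paths[, 1:3])
  expect_true(all(!qc3$defined))
  expect_true(all(!qc3$flagged))
})

test_that("summary-statistic t-test agrees with t.test on raw data", {
  set.seed(60)
  x <- rnorm(16, 10, 2); y <- rnorm(16, 12, 3)
  ref <- t.test(x, y, var.equal = TRUE)
  mine <- summary_stat_ttest(mean(x), sd(x), 16, mean(y), sd(y), 16)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
  refw <- t.test(x, y)
  minew <- summary_stat_ttest(mean(x), sd(x), 16, mean(y), sd(y), 16,
                              equal_var = FALSE)
  expect_equal(minew$statistic, unname(refw$statistic), tolerance = 1e-10)
  expect_equal(minew$p.value, refw$p.value, tolerance = 1e-10)
  same <- summary_stat_ttest(5, 1, 10, 5, 1, 10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
})

test_that("chi-square test handles correction, strong effects and margins", {
  even <- contingency_chi2(matrix(c(10, 10, 6, 6), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p.value, 1)
  expect_false(even$corrected)   # all expected counts >= 5
  strong <- contingency_chi2(matrix(c(10, 0, 0, 10), 2))
  expect_lt(strong$p.value, 0.01)
  ref <- suppressWarnings(chisq.test(matrix(c(10, 0, 0, 10), 2),
                                     correct = FALSE))
  expect_equal(strong$p.value, ref$p.value, tolerance = 1e-12)
  expect_false(strong$corrected)  # expected counts are exactly 5, not < 5
  small <- contingency_chi2(matrix(c(7, 2, 3, 8), 2))
  refs <- suppressWarnings(chisq.test(matrix(c(7, 2, 3, 8), 2),
                                      correct = TRUE))
  expect_equal(small$p.value, refs$p.value, tolerance = 1e-12)
  expect_error(contingency_chi2(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})
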