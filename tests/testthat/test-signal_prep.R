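test_that("band-pass keeps in-band sinusoids and kills out-of-band ones", {
  Tn <- 229; tr <- 2
  t <- seq_len(Tn) * tr
  amp_ratio <- function(f) {   # RMS gain
    x <- sin(2 * pi * f * t)
    y <- bandpass_filter(matrix(x, ncol = 1), 0.01, 0.08, tr = tr)$data
    sd(y) / sd(x)
  }
  expect_gt(amp_ratio(0.04), 0.9)   # mid-band
  expect_lt(amp_ratio(0.04), 1.1)
  expect_lt(amp_ratio(0.2), 0.1)    # stop band, 2.5x the high edge
  # below the band edge a 0.005 Hz tone completes only ~2.3 cycles in the
  # 458 s record, so part of its energy genuinely overlaps the pass band;
  # attenuation is bounded by spectral resolution, not by the filter
  expect_lt(amp_ratio(0.005), 0.2)
  # constant series: DC removed since low edge > 0
  const <- bandpass_filter(matrix(5, Tn, 1), 0.01, 0.08, tr = tr)$data
  expect_lt(max(abs(const)), 1e-10)
})

test_that("band-pass validates its edges", {
  x <- matrix(rnorm(100), ncol = 1)
  expect_error(bandpass_filter(x, 0.01, 0.25, tr = 2), "Nyquist")
  expect_error(bandpass_filter(x, 0.08, 0.01, tr = 2), "low < high")
})

test_that("nuisance regression leaves residuals orthogonal to confounds", {
  set.seed(21)
  Tn <- 229
  ts <- roi_ts(matrix(rnorm(Tn * 5), Tn, 5))
  conf <- cbind(matrix(rnorm(Tn * 6), Tn, 6),   # motion
                seq_len(Tn) / Tn,               # drift
                matrix(rnorm(Tn * 2), Tn, 2))   # tissue
  out <- regress_nuisance(ts, conf)
  for (j in seq_len(ncol(conf)))
    expect_lt(max(abs(crossprod(conf[, j], out$data))), 1e-8)
  expect_lt(max(abs(colSums(out$data))), 1e-8)  # intercept
  # correlations effectively zero as well
  expect_lt(max(abs(cor(conf, out$data))), 1e-6)
})

test_that("self-regression zeroes a series; empty confounds only demean", {
  set.seed(22)
  ts <- roi_ts(matrix(rnorm(300), 100, 3))
  out <- regress_nuisance(ts, ts$data[, 2, drop = FALSE])
  expect_lt(max(abs(out$data[, 2])), 1e-10)
  demeaned <- regress_nuisance(ts, NULL)
  expect_equal(demeaned$data, scale(ts$data, scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(regress_nuisance(ts, cbind(a = rnorm(100), a2 = 1:100 * 0)),
               "collinear")
})

test_that("ROI extraction averages voxels within each mask", {
  grid <- grid_spec(c(5, 5, 5), spacing = 3)
  Tn <- 7
  vol <- array(0, c(5, 5, 5, Tn))
  s1 <- rnorm(Tn); s2 <- rnorm(Tn)
  vol[2, 2, 2, ] <- s1
  vol[4, 4, 4, ] <- s2
  mk <- function(vox, nm) structure(
    list(dim = c(5L, 5L, 5L), affine = grid$affine,
         voxels = matrix(vox, ncol = 3, byrow = TRUE), roi = nm,
         empty = FALSE), class = "voxel_mask")
  one <- mk(c(2, 2, 2), "one")
  two <- mk(c(2, 2, 2, 4, 4, 4), "two")
  ts <- extract_roi_series(vol, list(one, two), tr = 2)
  expect_equal(unname(ts$data[, 1]), s1)
  expect_equal(unname(ts$data[, 2]), (s1 + s2) / 2)
  # constant volume gives constant series
  cvol <- array(3.5, c(5, 5, 5, 4))
  cts <- extract_roi_series(cvol, list(one), tr = 2)
  expect_true(all(cts$data == 3.5))
  empty <- mk(integer(0), "bad")
  expect_error(extract_roi_series(vol, list(empty)), "bad")
})

test_that("standardization has the closed form and is idempotent", {
  out <- standardize(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(unname(out$data[, 1]), c(-1, 0, 1))
  set.seed(23)
  ts <- standardize(roi_ts(matrix(rnorm(500), 100, 5)))
  expect_lt(max(abs(colMeans(ts$data))), 1e-12)
  expect_equal(unname(apply(ts$data, 2, sd)), rep(1, 5), tolerance = 1e-12)
  again <- standardize(ts)
  expect_equal(again$data, ts$data, tolerance = 1e-12)
  bad <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "flat")))
  bad[, 2] <- 7
  expect_error(standardize(bad), "flat")
})

test_that("framewise displacement follows the arc-length worked example", {
  m <- matrix(0, 6, 6)
  m[4, ] <- c(1, 0, 0, 1, 0, 0)  # 1 mm + 1 degree step at frame 4
  fd <- framewise_displacement(m)
  expect_equal(fd$fd[4], 1 + 50 * pi / 180)
  expect_equal(fd$fd[5], 1 + 50 * pi / 180)  # step back down
  expect_equal(fd$fd[1], 0)
  # translations only
  m2 <- matrix(0, 3, 6)
  m2[2, 1:3] <- c(0.1, 0.2, 0.3)
  expect_equal(framewise_displacement(m2)$fd[2], 0.6)
  # zero motion
  z <- framewise_displacement(matrix(0, 10, 6))
  expect_true(all(z$fd == 0))
  expect_equal(z$mean_fd, 0)
  expect_error(framewise_displacement(matrix(0, 1, 6)), "2 frames")
})

test_that("FD depends only on motion differences", {
  set.seed(24)
  m <- matrix(rnorm(60), 10, 6)
  offset <- matrix(rep(rnorm(6), each = 10), 10, 6)
  expect_equal(framewise_displacement(m)$fd,
               framewise_displacement(m + offset)$fd, tolerance = 1e-12)
})

test_that("prep pipeline output is standardized and in-band", {
  set.seed(25)
  Tn <- 229
  ts <- roi_ts(matrix(rnorm(Tn * 4), Tn, 4), tr = 2)
  motion <- matrix(rnorm(Tn * 6, sd = 0.05), Tn, 6)
  tissue <- matrix(rnorm(Tn * 2), Tn, 2)
  out <- prep_subject(ts, motion = motion, tissue = tissue)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  expect_equal(unname(apply(out$data, 2, sd)), rep(1, 4), tolerance = 1e-10)
  # residual spectrum stays inside the analysis band
  spec <- abs(mvfft(out$data))
  freq <- (seq_len(Tn) - 1) / (Tn * 2)
  freq <- pmin(freq, 1 / 2 - freq)
  out_of_band <- freq < 0.01 - 1e-9 | freq > 0.08 + 1e-9
  expect_lt(max(spec[out_of_band, ]) / max(spec), 1e-10)
})
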