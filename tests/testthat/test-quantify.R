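vs1 <- c(1, 1, 1)

test_that("SUV follows its defining ratio", {
  expect_equal(suv(5, 350, 70), 1)
  expect_equal(suv(0, 350, 70), 0)
  expect_equal(suv(5, 350, 140), 2 * suv(5, 350, 70))
  expect_error(suv(5, 0, 70), "positive")
})

test_that("recovery coefficients match direct ratios and a sort oracle", {
  gt <- array(runif(5^3, 1, 2), c(5, 5, 5))
  mask <- array(TRUE, c(5, 5, 5))
  # identity -> all RCs 1
  rc <- rc_metrics(gt, gt, mask, vs1)
  expect_equal(rc$rc_max, 1); expect_equal(rc$rc_median, 1)
  # scaling the prediction scales RC_max
  expect_equal(rc_metrics(0.9 * gt, gt, mask)$rc_max, 0.9)
  # median RC against an exhaustive sort on a 5^3 toy
  set.seed(1)
  p2 <- array(runif(125, 0.5, 3), c(5, 5, 5))
  med_oracle <- sort(c(p2))[63] / sort(c(gt))[63]
  expect_equal(rc_metrics(p2, gt, mask)$rc_median, med_oracle)
  # halves pattern suppresses the median; errors on degenerate input
  expect_true(is.na(rc_metrics(p2, gt, mask, pattern = "halves")$rc_median))
  expect_error(rc_metrics(p2, gt, array(FALSE, c(5, 5, 5))), "empty")
  expect_error(rc_metrics(p2, gt * 0, mask), "zero")
  # RCs invariant to a common positive rescale
  rc1 <- rc_metrics(p2, gt, mask, vs1)
  rc2 <- rc_metrics(10 * p2, 10 * gt, mask, vs1)
  expect_equal(rc1$rc_max, rc2$rc_max)
  expect_equal(rc1$rc_peak, rc2$rc_peak)
})

test_that("peak activity equals an exhaustive brute force on a 20^3 toy", {
  set.seed(2)
  vol <- array(runif(20^3, 0, 5), c(20, 20, 20))
  mask <- ball_mask(20, 6)
  vox <- c(2, 2, 2)
  got <- peak_activity(vol, mask, vox)
  # brute force: every mask voxel whose VOI fits; plain triple loop
  r <- (3 * 1000 / (4 * pi))^(1 / 3)
  best <- -Inf
  for (i in 1:20) for (j in 1:20) for (k in 1:20) {
    if (!mask[i, j, k]) next
    tot <- 0; cnt <- 0; bad <- FALSE
    for (di in -3:3) for (dj in -3:3) for (dk in -3:3) {
      if ((di * 2)^2 + (dj * 2)^2 + (dk * 2)^2 > r^2) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || jj < 1 || kk < 1 || ii > 20 || jj > 20 || kk > 20) { bad <- TRUE
      } else { tot <- tot + vol[ii, jj, kk]; cnt <- cnt + 1 }
    }
    if (!bad && cnt > 0) best <- max(best, tot / cnt)
  }
  expect_equal(got, best)
})

test_that("peak is diluted for tumours smaller than the VOI", {
  vox <- c(2, 2, 2)
  vol <- array(1, c(20, 20, 20))
  small <- ball_mask(20, 2.5, vox)          # ~0.5 ml hot sphere
  vol[small] <- 10
  expect_lt(peak_activity(vol, small, vox), 10)
  # uniform volume: peak equals the uniform value
  expect_equal(peak_activity(array(3, c(20, 20, 20)), ball_mask(20, 6), vox), 3)
  expect_error(peak_activity(vol, array(FALSE, c(20, 20, 20)), vox), "empty")
})

test_that("MSSIM is 1 on identity, symmetric, windowed as specified", {
  set.seed(3)
  x <- array(runif(12^3), c(12, 12, 12))
  y <- array(runif(12^3), c(12, 12, 12))
  expect_equal(as.numeric(mssim(x, x)), 1)
  expect_equal(as.numeric(mssim(x, y, ssim_config(L = 1))),
               as.numeric(mssim(y, x, ssim_config(L = 1))))
  expect_lte(as.numeric(mssim(x, y)), 1)
  # number of fully interior 7^3 windows in a 50^3 crop
  big <- array(0.5, c(50, 50, 50)); big[1] <- 0; big[2] <- 1
  expect_identical(attr(mssim(big, big), "n_windows"), 85184L)
  # luminance closed form on constant images (contrast/structure terms drop)
  a <- array(0.3, c(9, 9, 9)); b <- array(0.6, c(9, 9, 9))
  C1 <- (0.01 * 1)^2
  lum <- (2 * 0.3 * 0.6 + C1) / (0.3^2 + 0.6^2 + C1)
  expect_equal(as.numeric(mssim(a, b, ssim_config(L = 1))), lum, tolerance = 1e-10)
  expect_error(mssim(x, array(0, c(5, 5, 5))), "match")
})

test_that("sphericity oracles: sphere, cube, ellipsoid monotonicity", {
  expect_equal(sphericity(ball_mask(81, 30), vs1), 1, tolerance = 0.02)
  cube <- array(FALSE, c(110, 110, 110)); cube[6:105, 6:105, 6:105] <- TRUE
  expect_equal(sphericity(cube, vs1), (36 * pi)^(1 / 3) / 6, tolerance = 0.02)
  # elongating at fixed volume strictly decreases sphericity, and the
  # estimate converges towards the closed form with resolution
  s <- c(sphericity(ellipsoid_mask(81, c(30, 30, 30)), vs1),
         sphericity(ellipsoid_mask(81, c(24, 24, 46)), vs1),
         sphericity(ellipsoid_mask(81, c(20, 20, 66)), vs1))
  expect_true(all(diff(s) < 0))
  # closed-form prolate ellipsoid area for (24, 24, 46)
  a <- 24; c_ <- 46; e <- sqrt(1 - a^2 / c_^2)
  A <- 2 * pi * a^2 * (1 + c_ / (a * e) * asin(e))
  V <- 4 / 3 * pi * a^2 * c_
  target <- (36 * pi * V^2)^(1 / 3) / A
  fine <- sphericity(ellipsoid_mask(81, c(24, 24, 46)), vs1)
  coarse <- sphericity(ellipsoid_mask(41, c(24, 24, 46), c(2, 2, 2)), c(2, 2, 2))
  expect_lt(abs(fine - target), 0.02)
  expect_lte(abs(fine - target), abs(coarse - target) + 1e-3)
  expect_error(sphericity(array(FALSE, c(5, 5, 5)), vs1), "empty")
})

test_that("half-ratio analysis flags underestimation", {
  dm <- c(6, 6, 6)
  h <- array(FALSE, dm); h[1:3, , ] <- TRUE
  l <- array(FALSE, dm); l[4:6, , ] <- TRUE
  gt <- array(10, dm); gt[h] <- 20
  pred <- array(12, dm); pred[h] <- 18
  res <- halves_ratio_analysis(pred, gt, list(high = h, low = l))
  expect_equal(res$true_ratio, 2)
  expect_equal(res$predicted_ratio, 1.5)
  expect_true(res$underestimated)
  ident <- halves_ratio_analysis(gt, gt, list(high = h, low = l))
  expect_false(ident$underestimated)
  expect_error(halves_ratio_analysis(pred, gt, list(high = h, low = h & FALSE)),
               "non-empty")
})

test_that("binned RC summaries use four-segment averaging between 1 and 2 ml", {
  rep8 <- data.frame(
    volume_ml = c(6, 8, 1.1, 1.2, 1.3, 1.6, 1.8, 1.95),
    rc_max    = c(1.1, 0.9, 0.5, 0.7, 0.6, 0.8, 0.9, 1.0),
    rc_median = c(1.0, 0.8, 0.4, 0.6, 0.5, 0.7, 0.8, 0.9),
    rc_peak   = c(1.0, 1.0, 0.5, 0.5, 0.6, 0.7, 0.8, 0.9))
  s <- binned_rc_summary(rep8)
  big_max <- s[s$bin == ">=5ml" & s$metric == "rc_max", ]
  expect_equal(big_max$mean, 1.0)
  expect_equal(big_max$sd, sd(c(1.1, 0.9)))
  # hand-computed segments: [1,1.25): .5,.7 ; [1.25,1.5): .6 ; [1.5,1.75): .8 ;
  # [1.75,2]: .9,1.0
  seg <- c(mean(c(0.5, 0.7)), 0.6, 0.8, mean(c(0.9, 1.0)))
  got <- s[s$bin == "1-2ml" & s$metric == "rc_max", ]
  expect_equal(got$mean, mean(seg))
  # segment averaging differs from the pooled mean when unbalanced
  pooled <- mean(c(0.5, 0.7, 0.6, 0.8, 0.9, 1.0))
  expect_false(isTRUE(all.equal(got$mean, pooled)))
  # all-ones cohort: every summary is 1 with zero spread
  ones <- data.frame(volume_ml = c(6, 1.1, 1.3, 1.6, 1.9),
                     rc_max = 1, rc_median = 1, rc_peak = 1)
  s1 <- binned_rc_summary(ones)
  expect_true(all(abs(s1$mean - 1) < 1e-12))
  # empty segment warns
  gap <- data.frame(volume_ml = c(1.1, 1.9), rc_max = c(0.5, 0.9),
                    rc_median = NA, rc_peak = NA)
  expect_warning(binned_rc_summary(gap), "empty")
})

test_that("tumour detection is monotone in its threshold", {
  mask <- ball_mask(10, 3)
  pred <- array(1, c(10, 10, 10)); pred[mask] <- 2.2
  expect_false(detect_tumour(array(1, c(10, 10, 10)), mask, 1))
  expect_true(detect_tumour(pred, mask, 1, factor = 1.5))
  dets <- vapply(c(1.2, 1.8, 2.4, 3), function(f)
    detect_tumour(pred, mask, 1, factor = f), logical(1))
  expect_true(all(diff(as.integer(dets)) <= 0))
})
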