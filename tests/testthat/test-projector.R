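gd <- c(48L, 48L, 4L)
vs <- c(2, 2, 2)
geom <- sinogram_geometry(gd, vs, 84L)

test_that("forward projection conserves mass across angles and is linear", {
  img <- array(0, gd)
  img[20, 30, 2] <- 5; img[35, 12, 3] <- 2
  sino <- forward_project(img, NULL, geom)
  per_angle <- apply(sino, 2, sum)
  expect_lt(max(abs(per_angle - mean(per_angle))) / mean(per_angle), 1e-10)
  # zero activity -> zero sinogram; doubling doubles
  expect_true(all(forward_project(array(0, gd), NULL, geom) == 0))
  expect_equal(forward_project(2 * img, NULL, geom), 2 * sino)
})

test_that("projector pair is an exact adjoint", {
  set.seed(1)
  x <- array(runif(prod(gd)), gd)
  y <- array(runif(geom$n_bins * geom$n_angles * gd[3]),
             c(geom$n_bins, geom$n_angles, gd[3]))
  lhs <- sum(forward_project(x, NULL, geom) * y)
  rhs <- sum(x * petrestore:::backproject_volume(y, geom))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("attenuation factors lie in (0, 1] and attenuate the sinogram", {
  mu <- array(0.005, gd)
  att <- attenuation_factors(mu, geom)
  expect_true(all(att > 0) && all(att <= 1))
  img <- cylinder_volume(gd, 10, 3)
  expect_true(all(forward_project(img, mu, geom) <= forward_project(img, NULL, geom)))
  expect_error(forward_project(img, array(0.005, c(10, 10, 2)), geom), "match")
})

test_that("image PSF blur has the specified FWHM and preserves mass", {
  gdi <- c(41L, 41L, 41L); vsi <- c(2.09, 2.09, 2.03)
  d <- array(0, gdi); d[21, 21, 21] <- 1
  b <- apply_image_psf(d, psf_spec(4.5), vsi)
  expect_lt(abs(sum(b) - 1), 1e-3)
  measure_fwhm <- function(prof, vox) {
    p <- prof / max(prof); idx <- which(p >= 0.5)
    lo <- min(idx); hi <- max(idx)
    xl <- lo - 1 + (0.5 - p[lo - 1]) / (p[lo] - p[lo - 1])
    xr <- hi + (0.5 - p[hi]) / (p[hi + 1] - p[hi])
    (xr - xl) * vox
  }
  expect_lt(abs(measure_fwhm(b[, 21, 21], 2.09) - 4.5) / 4.5, 0.05)
  expect_lt(abs(measure_fwhm(b[21, 21, ], 2.03) - 4.0) / 4.0, 0.05)
  # zero-FWHM flag is the identity; negative FWHM rejected
  expect_identical(apply_image_psf(d, psf_spec(0, 0), vsi), d)
  expect_error(psf_spec(-1), "non-negative")
})

test_that("count scaling hits the prompt budget exactly", {
  img <- cylinder_volume(gd, 10, 3)
  trues <- forward_project(img, NULL, geom)
  acq <- acquisition_spec(total_prompts = 1e8, trues_fraction = 0.352)
  sc <- scale_and_contaminate(trues, acq)
  expect_equal(sum(sc$expected), 1e8)
  expect_equal(sum(sc$trues_scale * trues), 0.352 * 1e8)
  # trues_fraction 1 -> no background
  sc1 <- scale_and_contaminate(trues, acquisition_spec(1e6, 1))
  expect_equal(sc1$background, 0)
  expect_equal(sum(sc1$expected), 1e6)
  # halving the prompts halves every expectation
  sc_half <- scale_and_contaminate(trues, acquisition_spec(5e7, 0.352))
  expect_equal(sc_half$expected, sc$expected / 2)
  expect_error(scale_and_contaminate(trues * 0, acq), "zero")
})

test_that("Poisson sampling is reproducible and statistically consistent", {
  expected <- array(10, c(100, 100, 10))  # total 1e6
  c1 <- poisson_sample(expected, seed = 5)
  expect_identical(c1, poisson_sample(expected, seed = 5))
  expect_lt(abs(sum(c1) - 1e6), 5 * sqrt(1e6))
  expect_true(all(poisson_sample(expected * 0, 1) == 0))
  expect_error(poisson_sample(expected - 20, 1), "non-negative")
})

test_that("NEC algebra matches the acquisition constants", {
  # 35.2M trues in 100M prompts -> 12.4M noise-equivalent counts
  expect_equal(compute_nec(3.52e7, 1e8), 1.239e7, tolerance = 1e-3)
  expect_equal(compute_nec(1e6, 1e6), 1e6)
  expect_equal(compute_nec(0, 1e6), 0)
  expect_error(compute_nec(1, 0), "positive")
})

test_that("the multi-scanner PSF sampler keeps the axial ratio fixed", {
  expect_equal(psf_spec(4.5)$fwhm_axial, 4.0, tolerance = 1e-9)
  expect_equal(psf_spec(4.7)$fwhm_axial, 4.178, tolerance = 1e-3)
  expect_equal(psf_spec(4.0)$fwhm_axial, 3.556, tolerance = 1e-3)
  set.seed(42)
  draws <- replicate(200, {
    p <- sample_psf_dataset2()
    c(p$fwhm_transaxial, p$fwhm_axial)
  })
  expect_equal(draws[2, ], draws[1, ] / 1.125)
  expect_lt(abs(mean(draws[1, ]) - 4.5), 0.1)
  expect_lt(abs(sd(draws[1, ]) - 0.2), 0.07)
})
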