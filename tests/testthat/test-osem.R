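vs <- c(2, 2, 2)

test_that("MLEM converges to the noiseless cylinder fixed point", {
  gd <- c(32L, 32L, 2L)
  geom <- sinogram_geometry(gd, vs, 84L)
  cyl <- cylinder_volume(gd, 10, 5)
  sino <- forward_project(cyl, NULL, geom)
  x <- osem_reconstruct(sino, NULL, 0,
                        recon_config(n_iterations = 200L, n_subsets = 1L,
                                     psf = psf_spec(0, 0)), geom)
  expect_true(all(x >= 0))
  repro <- forward_project(x, NULL, geom)
  expect_lt(abs(sum(repro) - sum(sino)) / sum(sino), 0.01)
})

test_that("one-subset OSEM equals a hand-rolled MLEM update by update", {
  gd <- c(32L, 32L, 1L)
  geom <- sinogram_geometry(gd, vs, 84L)
  set.seed(2)
  act <- array(0, gd); act[10:20, 12:22, 1] <- runif(121, 1, 3)
  mu <- array(0.002, gd)
  psf <- psf_spec(4.5)
  y <- poisson_sample(forward_project(apply_image_psf(act, psf, vs), mu, geom) * 50,
                      seed = 3)
  x_osem <- osem_reconstruct(y, mu, 0,
                             recon_config(n_iterations = 5L, n_subsets = 1L, psf = psf),
                             geom)
  att <- attenuation_factors(mu, geom)
  sens <- apply_image_psf(petrestore:::backproject_volume(att, geom), psf, vs)
  ok <- sens > 1e-8 * max(sens)
  x <- array(1, gd)
  for (it in 1:5) {
    fp <- forward_project(apply_image_psf(x, psf, vs), NULL, geom) * att
    bp <- apply_image_psf(petrestore:::backproject_volume((y / (fp + 1e-12)) * att,
                                                          geom), psf, vs)
    upd <- array(0, gd); upd[ok] <- bp[ok] / sens[ok]
    x <- x * upd
  }
  expect_equal(x, x_osem, tolerance = 1e-12)
})

test_that("one OSEM iteration is the sequence of its subset updates", {
  gd <- c(32L, 32L, 1L)
  geom <- sinogram_geometry(gd, vs, 84L)
  set.seed(4)
  act <- array(0, gd); act[12:22, 10:20, 1] <- runif(121, 1, 3)
  y <- poisson_sample(forward_project(act, NULL, geom) * 30, seed = 5)
  cfg <- recon_config(n_iterations = 1L, n_subsets = 21L, psf = psf_spec(0, 0))
  x_osem <- osem_reconstruct(y, NULL, 0, cfg, geom)
  # replay the interleaved subsets manually
  x <- array(1, gd)
  for (k in 1:21) {
    idx <- seq(k, geom$n_angles, by = 21)
    sens <- petrestore:::backproject_volume(
      array(1, c(geom$n_bins, length(idx), gd[3])), geom, idx)
    ok <- sens > 1e-8 * max(sens)
    fp <- petrestore:::project_volume(x, geom, idx)
    bp <- petrestore:::backproject_volume(y[, idx, , drop = FALSE] / (fp + 1e-12),
                                          geom, idx)
    upd <- array(0, gd); upd[ok] <- bp[ok] / sens[ok]
    x <- x * upd
  }
  expect_equal(x, x_osem, tolerance = 1e-12)
})

test_that("MLEM increases the Poisson log-likelihood monotonically", {
  gd <- c(24L, 24L, 1L)
  geom <- sinogram_geometry(gd, vs, 84L)
  set.seed(6)
  act <- array(0, gd); act[8:16, 8:16, 1] <- runif(81, 1, 4)
  y <- poisson_sample(forward_project(act, NULL, geom) * 40, seed = 7)
  x <- array(1, gd)
  sens <- petrestore:::backproject_volume(
    array(1, c(geom$n_bins, geom$n_angles, gd[3])), geom)
  ok <- sens > 1e-8 * max(sens)
  ll <- numeric(12)
  for (it in 1:12) {
    fp <- forward_project(x, NULL, geom)
    ll[it] <- poisson_loglik(y, fp + 1e-12)
    bp <- petrestore:::backproject_volume(y / (fp + 1e-12), geom)
    upd <- array(0, gd); upd[ok] <- bp[ok] / sens[ok]
    x <- x * upd
  }
  expect_true(all(diff(ll) > -1e-6))
})

test_that("sensitivity is flat without attenuation and subset-additive", {
  gd <- c(32L, 32L, 2L)
  geom <- sinogram_geometry(gd, vs, 84L)
  cfg <- recon_config(n_subsets = 21L, psf = psf_spec(0, 0))
  full <- make_sensitivity(seq_len(geom$n_angles), NULL, geom, cfg, vs)
  # central field of view flat within 2%
  centre <- full[12:21, 12:21, ]
  expect_lt((max(centre) - min(centre)) / mean(centre), 0.02)
  # higher attenuation decreases sensitivity voxelwise
  att_lo <- attenuation_factors(array(0.002, gd), geom)
  att_hi <- attenuation_factors(array(0.004, gd), geom)
  s_lo <- make_sensitivity(seq_len(geom$n_angles), att_lo, geom, cfg, vs)
  s_hi <- make_sensitivity(seq_len(geom$n_angles), att_hi, geom, cfg, vs)
  expect_true(all(s_hi <= s_lo + 1e-12))
  # subset sensitivities sum to the full sensitivity
  subs <- petrestore:::subset_angles(geom, 21L)
  parts <- Reduce(`+`, lapply(subs, make_sensitivity, att = att_lo, geom = geom,
                              cfg = cfg, voxel_size = vs))
  expect_equal(parts, s_lo, tolerance = 1e-10)
  expect_error(make_sensitivity(integer(0), NULL, geom, cfg, vs), "empty")
})

test_that("an all-zero prompt sinogram reconstructs to zero", {
  gd <- c(24L, 24L, 1L)
  geom <- sinogram_geometry(gd, vs, 84L)
  y <- array(0, c(geom$n_bins, geom$n_angles, gd[3]))
  x <- osem_reconstruct(y, NULL, 0,
                        recon_config(n_iterations = 2L, n_subsets = 21L,
                                     psf = psf_spec(0, 0)), geom)
  expect_true(all(x == 0))
})

test_that("subset count must divide the angle count", {
  gd <- c(24L, 24L, 1L)
  geom <- sinogram_geometry(gd, vs, 80L)
  y <- array(1, c(geom$n_bins, geom$n_angles, gd[3]))
  expect_error(osem_reconstruct(y, NULL, 0, recon_config(n_subsets = 21L), geom),
               "divide")
})
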