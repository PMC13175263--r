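vs <- c(2.09, 2.09, 2.03)

test_that("torso phantom organs are placed and masks are disjoint", {
  torso <- make_torso_phantom(c(64, 64, 32), vs)
  expect_identical(dim(torso$activity), c(64L, 64L, 32L))
  expect_true(all(torso$activity >= 0) && all(is.finite(torso$activity)))
  expect_true(all(torso$attenuation >= 0))
  # left lung disjoint from heart / ribs / spine, verified voxelwise
  expect_false(any(torso$lung_mask & torso$masks$heart))
  expect_false(any(torso$lung_mask & torso$masks$ribs))
  expect_false(any(torso$lung_mask & torso$masks$spine))
  # paper-scale grid also supported
  big <- make_torso_phantom(c(344, 344, 127), vs)
  expect_identical(dim(big$activity), c(344L, 344L, 127L))
})

test_that("zero organ activities give an identically zero activity volume", {
  tab <- default_organ_table()
  tab$activity <- 0
  torso <- make_torso_phantom(c(32, 32, 16), vs, organ_table = tab)
  expect_true(all(torso$activity == 0))
})

test_that("too-small grids are rejected", {
  expect_error(make_torso_phantom(c(8, 8, 4), vs), "too small")
})

test_that("tumour shapes hit their target volume and are reproducible", {
  # 0.18 ml at the study voxel size is about 20 voxels
  sp <- tumour_spec("uniform", 0.18, 20, seed = 7)
  m <- sample_tumour_shape(sp, vs)
  expect_true(abs(attr(m, "n_voxels") - 20) <= 2)
  expect_identical(c(sample_tumour_shape(sp, vs)), c(m))
  # achieved volumes track targets across the range
  for (v in c(0.05, 1.33, 12, 60)) {
    mm <- sample_tumour_shape(tumour_spec("uniform", v, 20, seed = 3), vs)
    expect_lt(abs(attr(mm, "volume_ml") - v) / v, 0.15)
  }
  # single 26-connected component
  lab <- petrestore:::cpp_label26(array(as.logical(m), dim(m)), dim(m))
  expect_identical(max(lab), 1L)
})

test_that("sub-voxel targets report the minimum representable volume", {
  expect_error(sample_tumour_shape(tumour_spec("uniform", 0.011, 20, seed = 1),
                                   c(4, 4, 4)),
               "minimum representable")
})

test_that("elongation monotonically decreases sphericity", {
  s <- vapply(c(0, 0.4, 0.8), function(e) {
    m <- sample_tumour_shape(tumour_spec("uniform", 6, 20, elongation = e,
                                         noise_amplitude = 0, seed = 3), vs)
    sphericity(array(as.logical(m), dim(m)), vs)
  }, numeric(1))
  expect_true(all(diff(s) < 0))
  expect_gte(s[1], 0.95)
})

test_that("activity patterns partition the mask", {
  # hollow: shell thickness half the equivalent radius; core gets background
  tum <- make_tumour(tumour_spec("hollow", 8, 20, seed = 5), vs)
  expect_true(all((tum$region_masks$core | tum$region_masks$shell) == tum$mask))
  expect_false(any(tum$region_masks$core & tum$region_masks$shell))
  expect_setequal(unique(tum$values[tum$region_masks$shell]), 20)
  expect_setequal(unique(tum$values[tum$region_masks$core]), tum$background)
  # on a sphere of radius r the core is close to a centred r/2 sphere
  spb <- tumour_spec("hollow", 4 / 3 * pi, 20, noise_amplitude = 0, seed = 2)
  tb <- make_tumour(spb, c(1, 1, 1))  # r = 10 with 1 mm voxels
  r_core <- (3 * sum(tb$region_masks$core) / (4 * pi))^(1 / 3)
  expect_lt(abs(r_core - 5) / 5, 0.15)
  # halves: disjoint partition, high side gets the larger activity
  th <- make_tumour(tumour_spec("halves", 6, 24, secondary_activity = 12, seed = 8), vs)
  expect_true(all((th$region_masks$high | th$region_masks$low) == th$mask))
  expect_false(any(th$region_masks$high & th$region_masks$low))
  expect_setequal(unique(th$values[th$region_masks$high]), 24)
  expect_setequal(unique(th$values[th$region_masks$low]), 12)
  # halves with equal activities degenerates to the uniform pattern
  te <- make_tumour(tumour_spec("halves", 6, 24, secondary_activity = 24, seed = 8), vs)
  tu <- make_tumour(tumour_spec("uniform", 6, 24, seed = 8), vs)
  expect_equal(te$values, tu$values)
  # halves on a single voxel cannot split
  expect_error(apply_pattern(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)),
                             tumour_spec("halves", 6, 24, secondary_activity = 12),
                             vs),
               "single-voxel")
})

test_that("assembled ground truth has tumour-to-background ratio exactly 10", {
  torso <- make_torso_phantom(c(64, 64, 32), vs)
  for (pat in c("uniform", "halves", "hollow")) {
    sp <- tumour_spec(pat, 3, 30,
                      secondary_activity = if (pat == "halves") 15 else NULL,
                      seed = 11)
    gt <- assemble_ground_truth(torso, make_tumour(sp, vs), placement_seed = 4)
    expect_equal(max(gt$activity[gt$record$mask]) / gt$record$background, 10)
    # the lung background sits at the background level
    lung_free <- torso$lung_mask & !gt$record$mask
    expect_equal(unique(gt$activity[lung_free]), gt$record$background)
  }
})

test_that("placement is deterministic and translation-invariant in shape", {
  torso <- make_torso_phantom(c(64, 64, 32), vs)
  tum <- make_tumour(tumour_spec("uniform", 2, 20, seed = 5), vs)
  g1 <- assemble_ground_truth(torso, tum, placement_seed = 1)
  g1b <- assemble_ground_truth(torso, tum, placement_seed = 1)
  g2 <- assemble_ground_truth(torso, tum, placement_seed = 2)
  expect_identical(g1$activity, g1b$activity)
  expect_false(all(g1$record$centroid == g2$record$centroid))
  expect_identical(sum(g1$record$mask), sum(g2$record$mask))
})

test_that("oversized tumours cannot be placed in the lung", {
  torso <- make_torso_phantom(c(48, 48, 24), vs)
  tum <- make_tumour(tumour_spec("uniform", 150, 20, seed = 1), vs)
  expect_error(assemble_ground_truth(torso, tum, 1), "larger than the left lung")
})

test_that("crops are clamped, sized exactly, and round-trip", {
  vol <- array(rnorm(64 * 64 * 32), c(64, 64, 32))
  cr <- crop_around_tumour(vol, c(3, 60, 2), c(20, 20, 20))  # corner tumour
  expect_identical(dim(cr), c(20L, 20L, 20L))
  off <- attr(cr, "offset")
  expect_true(all(off >= 1) && all(off + 19 <= c(64, 64, 32)))
  back <- embed_crop(array(0, dim(vol)), cr)
  expect_identical(c(back[off[1] + 0:19, off[2] + 0:19, off[3] + 0:19]), c(cr))
  expect_error(crop_around_tumour(vol, c(5, 5, 5), c(70, 70, 70)), "larger")
})
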