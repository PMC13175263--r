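#' Standardised uptake value
#'
#' `SUV = concentration / (injected activity / body weight)`, assuming unit
#' tissue density (1 g/ml), so the result is dimensionless.
#'
#' @param activity_concentration kBq/ml.
#' @param injected_activity MBq.
#' @param body_weight kg.
#' @export
suv <- function(activity_concentration, injected_activity, body_weight) {
  if (injected_activity <= 0 || body_weight <= 0)
    stop("injected activity and body weight must be positive")
  activity_concentration / (injected_activity / body_weight)
}

#' SSIM configuration
#'
#' Local-window structural similarity with unit exponents for the luminance,
#' contrast and structure terms and the standard stability constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `C3 = C2 / 2`.
#'
#' @param window odd cubic window side in voxels.
#' @param L data range; `NULL` means take the range of the reference image.
#' @param k1,k2 stability constant factors.
#' @export
ssim_config <- function(window = 7L, L = NULL, k1 = 0.01, k2 = 0.03) {
  stopifnot(window %% 2 == 1, window >= 3)
  structure(list(window = as.integer(window), L = L, k1 = k1, k2 = k2),
            class = "ssim_config")
}

#' Mean structural similarity over 3D windows
#'
#' Mean of the windowed SSIM over all fully interior cubic windows (stride
#' 1). With unit exponents and `C3 = C2/2` the per-window SSIM reduces to
#' `(2 mx my + C1)(2 sxy + C2) / ((mx^2 + my^2 + C1)(sx^2 + sy^2 + C2))`.
#' Symmetric in its two images and exactly 1 for identical images.
#'
#' @param x image to assess.
#' @param y reference image (sets the data range when `cfg$L` is `NULL`).
#' @param cfg a [ssim_config()].
#' @return MSSIM value with attribute `n_windows`.
#' @export
mssim <- function(x, y, cfg = ssim_config()) {
  check_volume3d(x, "x"); check_volume3d(y, "y")
  if (!identical(dim(x), dim(y))) stop("image shapes do not match")
  w <- cfg$window
  if (any(dim(x) < w)) stop("image smaller than the SSIM window")
  L <- if (is.null(cfg$L)) diff(range(y)) else cfg$L
  if (L <= 0) stop("reference image has zero data range; supply L explicitly")
  C1 <- (cfg$k1 * L)^2; C2 <- (cfg$k2 * L)^2
  n <- w^3
  dm <- dim(x)
  sx  <- cpp_boxsum3(x, dm, w);       sy  <- cpp_boxsum3(y, dm, w)
  sxx <- cpp_boxsum3(x * x, dm, w);   syy <- cpp_boxsum3(y * y, dm, w)
  sxy <- cpp_boxsum3(x * y, dm, w)
  mx <- sx / n; my <- sy / n
  vx <- sxx / n - mx^2; vy <- syy / n - my^2
  cxy <- sxy / n - mx * my
  ssim_map <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  structure(mean(ssim_map), n_windows = length(ssim_map))
}

#' Peak activity in a 1 ml spherical VOI
#'
#' Maximum over VOI centres inside the tumour mask (whose full sphere fits
#' inside the image) of the mean activity within a spherical volume of
#' interest of `voi_volume_ml` (default 1 ml, radius about 6.2 mm).
#'
#' @param volume 3D activity array.
#' @param mask logical tumour mask (same grid).
#' @param voxel_size voxel edges in mm.
#' @param voi_volume_ml VOI volume in ml.
#' @export
peak_activity <- function(volume, mask, voxel_size, voi_volume_ml = 1) {
  check_volume3d(volume); check_volume3d(mask, "mask")
  if (!any(mask)) stop("mask is empty")
  r <- (3 * voi_volume_ml * 1000 / (4 * pi))^(1 / 3)
  rad <- floor(r / voxel_size)
  off <- expand.grid(x = -rad[1]:rad[1], y = -rad[2]:rad[2], z = -rad[3]:rad[3])
  keep <- (off$x * voxel_size[1])^2 + (off$y * voxel_size[2])^2 +
    (off$z * voxel_size[3])^2 <= r^2
  off <- off[keep, , drop = FALSE]
  dm <- dim(volume)
  ctr <- which(mask, arr.ind = TRUE)
  inb <- ctr[, 1] + min(off$x) >= 1 & ctr[, 1] + max(off$x) <= dm[1] &
         ctr[, 2] + min(off$y) >= 1 & ctr[, 2] + max(off$y) <= dm[2] &
         ctr[, 3] + min(off$z) >= 1 & ctr[, 3] + max(off$z) <= dm[3]
  ctr <- ctr[inb, , drop = FALSE]
  if (nrow(ctr) == 0)
    stop("no valid VOI centre: the VOI does not fit inside the image for any mask voxel")
  lin_ctr <- ctr[, 1] + (ctr[, 2] - 1) * dm[1] + (ctr[, 3] - 1) * dm[1] * dm[2]
  lin_off <- off$x + off$y * dm[1] + off$z * dm[1] * dm[2]
  acc <- numeric(length(lin_ctr))
  for (k in seq_along(lin_off)) acc <- acc + volume[lin_ctr + lin_off[k]]
  max(acc) / nrow(off)
}

#' Recovery coefficients inside the ground-truth tumour mask
#'
#' Ratios of the maximum, median and peak activities of `prediction` to
#' those of `ground_truth`, all evaluated within the ground-truth mask.
#' The median RC is not reported for the halves pattern (its uptake is not
#' uniform), matching the evaluation convention.
#'
#' @param prediction,ground_truth 3D activity arrays on the same grid.
#' @param mask logical ground-truth tumour mask.
#' @param voxel_size voxel edges in mm (needed for the peak VOI); `NULL`
#'   skips the peak RC.
#' @param pattern tumour pattern; `"halves"` suppresses the median RC.
#' @return named list: `rc_max`, `rc_median`, `rc_peak` (NA where not
#'   computed).
#' @export
rc_metrics <- function(prediction, ground_truth, mask, voxel_size = NULL,
                       pattern = "uniform") {
  if (!any(mask)) stop("mask is empty")
  gt_max <- max(ground_truth[mask])
  if (gt_max <= 0) stop("ground-truth maximum in the mask is zero")
  rc_max <- max(prediction[mask]) / gt_max
  rc_median <- NA_real_
  if (!identical(pattern, "halves")) {
    gt_med <- median(ground_truth[mask])
    if (gt_med <= 0) stop("ground-truth median in the mask is zero")
    rc_median <- median(prediction[mask]) / gt_med
  }
  rc_peak <- NA_real_
  if (!is.null(voxel_size)) {
    rc_peak <- tryCatch({
      peak_activity(prediction, mask, voxel_size) /
        peak_activity(ground_truth, mask, voxel_size)
    }, error = function(e) NA_real_)
  }
  list(rc_max = rc_max, rc_median = rc_median, rc_peak = rc_peak)
}

#' Surface area of a binary mask
#'
#' Two estimators. `"grad"` (default) counts exposed voxel faces, each
#' weighted by the matching component of the local surface normal estimated
#' from a Gaussian-smoothed copy of the mask; the weighting makes the count
#' exact for planar interfaces of any orientation, so both curved and flat
#' surfaces converge with resolution. `"mesh"` triangulates the 0.5 level
#' of the smoothed mask with marching tetrahedra and sums triangle areas.
#'
#' @param mask logical 3D array.
#' @param voxel_size voxel edges in mm.
#' @param method `"grad"` or `"mesh"`.
#' @param smooth_sigma smoothing scale (voxels) for the normal / level-set
#'   estimate.
#' @return area in mm^2.
#' @export
surface_area <- function(mask, voxel_size, method = c("grad", "mesh"),
                         smooth_sigma = 1.5) {
  check_volume3d(mask, "mask")
  if (!any(mask)) stop("mask is empty")
  method <- match.arg(method)
  pad <- as.integer(ceiling(4 * smooth_sigma) + 1)
  dm <- dim(mask) + 2L * pad
  m <- array(0, dm)
  m[(pad + 1):(pad + dim(mask)[1]), (pad + 1):(pad + dim(mask)[2]),
    (pad + 1):(pad + dim(mask)[3])] <- as.numeric(mask)
  f <- if (smooth_sigma > 0) cpp_gauss3(m, dm, rep(smooth_sigma, 3)) else m
  if (method == "mesh") return(cpp_surface_area(f, dm, voxel_size, 0.5))
  n <- dm
  gx <- (f[c(2:n[1], n[1]), , ] - f[c(1, 1:(n[1] - 1)), , ]) / (2 * voxel_size[1])
  gy <- (f[, c(2:n[2], n[2]), ] - f[, c(1, 1:(n[2] - 1)), ]) / (2 * voxel_size[2])
  gz <- (f[, , c(2:n[3], n[3])] - f[, , c(1, 1:(n[3] - 1))]) / (2 * voxel_size[3])
  gm <- sqrt(gx^2 + gy^2 + gz^2); gm[gm == 0] <- 1
  mb <- m > 0.5
  A <- 0
  d <- mb[1:(n[1] - 1), , ] != mb[2:n[1], , ]
  w <- abs(gx / gm)
  A <- A + sum(((w[1:(n[1] - 1), , ] + w[2:n[1], , ]) / 2)[d]) * voxel_size[2] * voxel_size[3]
  d <- mb[, 1:(n[2] - 1), ] != mb[, 2:n[2], ]
  w <- abs(gy / gm)
  A <- A + sum(((w[, 1:(n[2] - 1), ] + w[, 2:n[2], ]) / 2)[d]) * voxel_size[1] * voxel_size[3]
  d <- mb[, , 1:(n[3] - 1)] != mb[, , 2:n[3]]
  w <- abs(gz / gm)
  A <- A + sum(((w[, , 1:(n[3] - 1)] + w[, , 2:n[3]]) / 2)[d]) * voxel_size[1] * voxel_size[2]
  A
}

#' Sphericity of a binary mask
#'
#' `(36 pi V^2)^(1/3) / A` with the volume from the voxel count and the
#' surface area from [surface_area()]; 1 for a perfect sphere, smaller for
#' elongated shapes. Clipped to at most 1.
#'
#' @param mask logical 3D array.
#' @param voxel_size voxel edges in mm.
#' @param method surface-area estimator, see [surface_area()].
#' @export
sphericity <- function(mask, voxel_size, method = "grad") {
  check_volume3d(mask, "mask")
  if (!any(mask)) stop("mask is empty")
  V <- sum(mask) * prod(voxel_size)            # mm^3
  A <- surface_area(mask, voxel_size, method = method)
  if (A <= 0) stop("degenerate surface; mask too small for the area estimate")
  min(1, sphericity_from_measurements(V, A))
}

#' Sphericity from volume and surface-area measurements
#'
#' @param volume_mm3 volume in cubic mm.
#' @param area_mm2 surface area in square mm.
#' @export
sphericity_from_measurements <- function(volume_mm3, area_mm2) {
  stopifnot(volume_mm3 > 0, area_mm2 > 0)
  (36 * pi * volume_mm3^2)^(1 / 3) / area_mm2
}

#' Median-activity ratio between the two halves of a split tumour
#'
#' @param prediction,ground_truth 3D activity arrays.
#' @param halves_masks list with logical masks `high` and `low` (ground-truth
#'   ordering by assigned activity).
#' @return list: `predicted_ratio`, `true_ratio`, `underestimated` flag.
#' @export
halves_ratio_analysis <- function(prediction, ground_truth, halves_masks) {
  h <- halves_masks$high; l <- halves_masks$low
  if (is.null(h) || is.null(l) || !any(h) || !any(l))
    stop("both half masks must be non-empty")
  true_ratio <- median(ground_truth[h]) / median(ground_truth[l])
  predicted_ratio <- median(prediction[h]) / median(prediction[l])
  list(predicted_ratio = predicted_ratio, true_ratio = true_ratio,
       underestimated = predicted_ratio < true_ratio)
}

#' Tumour detectability in a restored image
#'
#' A tumour counts as detected when the maximum predicted activity inside
#' its mask exceeds the background level by `factor`.
#'
#' @param prediction 3D array.
#' @param mask logical tumour mask.
#' @param background_level ground-truth background activity.
#' @param factor detection threshold multiplier.
#' @export
detect_tumour <- function(prediction, mask, background_level, factor = 1.5) {
  if (!any(mask)) return(FALSE)
  max(prediction[mask]) > factor * background_level
}

#' Volume-binned recovery-coefficient summary
#'
#' Two cohort summaries: tumours with volume >= 5 ml get a plain mean and SD
#' per RC; tumours with volume in \[1, 2\] ml are split into four 0.25 ml
#' segments whose per-segment means are averaged unweighted (empty segments
#' are dropped with a warning).
#'
#' @param reports data.frame with columns `volume_ml`, `rc_max`, `rc_median`,
#'   `rc_peak` (NAs allowed).
#' @return data.frame with columns `bin`, `metric`, `mean`, `sd`, `n`.
#' @export
binned_rc_summary <- function(reports) {
  stopifnot(is.data.frame(reports), "volume_ml" %in% names(reports))
  metrics <- intersect(c("rc_max", "rc_median", "rc_peak"), names(reports))
  out <- list()
  big <- reports[reports$volume_ml >= 5, , drop = FALSE]
  for (m in metrics) {
    v <- big[[m]][!is.na(big[[m]])]
    out[[length(out) + 1]] <- data.frame(bin = ">=5ml", metric = m,
                                         mean = if (length(v)) mean(v) else NA_real_,
                                         sd = if (length(v) > 1) sd(v) else NA_real_,
                                         n = length(v))
  }
  edges <- seq(1, 2, by = 0.25)
  sml <- reports[reports$volume_ml >= 1 & reports$volume_ml <= 2, , drop = FALSE]
  for (m in metrics) {
    seg_means <- numeric(0); ntot <- 0L
    for (s in 1:4) {
      inseg <- sml$volume_ml >= edges[s] & sml$volume_ml < edges[s + 1] |
        (s == 4 & sml$volume_ml == 2)
      v <- sml[[m]][inseg & !is.na(sml[[m]])]
      if (length(v) == 0) {
        warning(sprintf("empty %.2f-%.2f ml segment for %s; excluded from the mean",
                        edges[s], edges[s + 1], m))
      } else {
        seg_means <- c(seg_means, mean(v)); ntot <- ntot + length(v)
      }
    }
    out[[length(out) + 1]] <- data.frame(bin = "1-2ml", metric = m,
                                         mean = if (length(seg_means)) mean(seg_means) else NA_real_,
                                         sd = if (length(seg_means) > 1) sd(seg_means) else NA_real_,
                                         n = ntot)
  }
  do.call(rbind, out)
}
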