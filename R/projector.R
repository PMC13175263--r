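#' Point-spread-function specification
#'
#' @param fwhm_transaxial FWHM in mm applied in x and y.
#' @param fwhm_axial FWHM in mm applied in z; defaults to
#'   `fwhm_transaxial / 1.125`, the fixed transaxial/axial ratio used
#'   throughout.
#' @return object of class `psf_spec`.
#' @export
psf_spec <- function(fwhm_transaxial = 4.5, fwhm_axial = fwhm_transaxial / 1.125) {
  stopifnot(length(fwhm_transaxial) == 1, length(fwhm_axial) == 1)
  if (fwhm_transaxial < 0 || fwhm_axial < 0)
    stop("PSF FWHM must be non-negative")
  structure(list(fwhm_transaxial = fwhm_transaxial, fwhm_axial = fwhm_axial),
            class = "psf_spec")
}

#' Draw a PSF for the multi-scanner dataset
#'
#' Transaxial FWHM ~ N(mean, sd) mm (redrawn in the vanishingly unlikely
#' non-positive case); axial = transaxial / 1.125. Uses the current RNG
#' stream, so wrap in `set.seed()` for reproducibility.
#'
#' @param mean,sd Gaussian parameters in mm.
#' @return a [psf_spec()].
#' @export
sample_psf_dataset2 <- function(mean = 4.5, sd = 0.2) {
  repeat {
    ft <- rnorm(1, mean, sd)
    if (ft > 0) break
  }
  psf_spec(fwhm_transaxial = ft)
}

#' Acquisition specification
#'
#' @param total_prompts expected total prompt coincidences.
#' @param trues_fraction fraction of prompts that are true coincidences; the
#'   default 0.352 reproduces 12.4 million noise-equivalent counts at 100
#'   million prompts under NEC = T^2 / P.
#' @param psf a [psf_spec()].
#' @param seed noise seed.
#' @export
acquisition_spec <- function(total_prompts = 1e8, trues_fraction = 0.352,
                             psf = psf_spec(), seed = 1L) {
  stopifnot(total_prompts > 0, trues_fraction > 0, trues_fraction <= 1)
  structure(list(total_prompts = total_prompts, trues_fraction = trues_fraction,
                 psf = psf, seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Sinogram geometry for the slice-wise parallel-beam projector
#'
#' Radial bins at the transaxial voxel pitch spanning the grid diagonal;
#' `n_angles` evenly spaced over `[0, pi)`.
#'
#' @param grid_dim volume dimensions (voxels).
#' @param voxel_size voxel edges in mm.
#' @param n_angles number of projection angles (default 168, divisible by
#'   the default 21 reconstruction subsets).
#' @export
sinogram_geometry <- function(grid_dim, voxel_size, n_angles = 168L) {
  stopifnot(length(grid_dim) == 3, n_angles >= 1)
  ds <- voxel_size[1]
  diag_mm <- sqrt((grid_dim[1] * voxel_size[1])^2 + (grid_dim[2] * voxel_size[2])^2)
  n_bins <- 2L * as.integer(ceiling(diag_mm / (2 * ds))) + 1L
  structure(list(n_angles = as.integer(n_angles), n_bins = n_bins, ds = ds,
                 angles = (seq_len(n_angles) - 1) * pi / n_angles,
                 grid_dim = as.integer(grid_dim), voxel_size = voxel_size),
            class = "sinogram_geometry")
}

## raw projector pair (no attenuation); angle_idx selects a subset
project_volume <- function(volume, geom, angle_idx = NULL) {
  check_volume3d(volume)
  ang <- if (is.null(angle_idx)) geom$angles else geom$angles[angle_idx]
  cpp_project(volume, dim(volume), ang, geom$n_bins,
              geom$voxel_size[1], geom$voxel_size[2], geom$ds)
}

backproject_volume <- function(sino, geom, angle_idx = NULL) {
  ang <- if (is.null(angle_idx)) geom$angles else geom$angles[angle_idx]
  cpp_backproject(sino, dim(sino), ang, geom$grid_dim,
                  geom$voxel_size[1], geom$voxel_size[2], geom$ds)
}

#' Attenuation factors per line of response
#'
#' `exp(-integral of mu dl)` for every (radial bin, angle, slice).
#'
#' @param mu 3D attenuation volume (1/mm).
#' @param geom a [sinogram_geometry()].
#' @return sinogram-shaped array of factors in (0, 1].
#' @export
attenuation_factors <- function(mu, geom) {
  exp(-project_volume(mu, geom))
}

#' Forward-project an activity volume into an expected-trues sinogram
#'
#' Slice-wise 2D parallel-beam line integrals weighted by the attenuation
#' factors `exp(-integral mu dl)`. Linear in the activity; unscaled (absolute
#' count scaling is applied by [scale_and_contaminate()]). Any PSF blurring
#' is applied beforehand with [apply_image_psf()].
#'
#' @param activity 3D activity volume (kBq/ml).
#' @param mu 3D attenuation volume (1/mm), same grid; `NULL` for none.
#' @param geom a [sinogram_geometry()].
#' @return sinogram array (`n_bins`, `n_angles`, `nz`).
#' @export
forward_project <- function(activity, mu = NULL, geom) {
  check_volume3d(activity, "activity")
  if (!is.null(mu)) {
    if (!identical(dim(activity), dim(mu)))
      stop("activity and attenuation grids do not match")
    attenuation_factors(mu, geom) * project_volume(activity, geom)
  } else {
    project_volume(activity, geom)
  }
}

#' Blur a volume with the anisotropic image-space PSF
#'
#' Gaussian convolution with sigma = FWHM / (2 sqrt(2 log 2)) per axis
#' (transaxial in x/y, axial in z). A zero FWHM is the identity.
#'
#' @param volume 3D array.
#' @param psf a [psf_spec()].
#' @param voxel_size voxel edges in mm.
#' @export
apply_image_psf <- function(volume, psf, voxel_size) {
  check_volume3d(volume)
  if (psf$fwhm_transaxial < 0 || psf$fwhm_axial < 0)
    stop("PSF FWHM must be non-negative")
  if (psf$fwhm_transaxial == 0 && psf$fwhm_axial == 0) return(volume)
  sig_mm <- c(psf$fwhm_transaxial, psf$fwhm_transaxial, psf$fwhm_axial) * FWHM_TO_SIGMA
  cpp_gauss3(volume, dim(volume), sig_mm / voxel_size)
}

#' Scale trues to the target statistics and add scatter/randoms background
#'
#' The trues sinogram is scaled so its expected total equals
#' `trues_fraction * total_prompts`; a spatially uniform background supplies
#' the remaining `(1 - trues_fraction) * total_prompts` expected scatter and
#' random events, so the expected prompt total is exact.
#'
#' @param trues_sino expected-trues sinogram from [forward_project()].
#' @param acq an [acquisition_spec()].
#' @return list: `expected` (prompt sinogram), `background` (uniform expected
#'   background per bin), `trues_scale` (applied trues scale factor).
#' @export
scale_and_contaminate <- function(trues_sino, acq) {
  tot <- sum(trues_sino)
  if (tot <= 0) stop("trues sinogram is zero; nothing to scale")
  alpha <- acq$trues_fraction * acq$total_prompts / tot
  bg <- (1 - acq$trues_fraction) * acq$total_prompts / length(trues_sino)
  list(expected = alpha * trues_sino + bg, background = bg, trues_scale = alpha)
}

#' Poisson-sample a sinogram of expected counts
#'
#' @param expected sinogram of non-negative expectations.
#' @param seed RNG seed; the draw is reproducible.
#' @return integer-valued sinogram of the same shape.
#' @export
poisson_sample <- function(expected, seed = 1L) {
  if (any(!is.finite(expected)) || any(expected < 0))
    stop("expected counts must be finite and non-negative")
  counts <- with_seed(seed, rpois(length(expected), as.vector(expected)))
  array(as.numeric(counts), dim = dim(expected))
}

#' Noise-equivalent counts
#'
#' NEC = T^2 / P with T true and P total prompt counts (scatter and randoms
#' are not separated here).
#'
#' @param trues_total,prompts_total counts.
#' @export
compute_nec <- function(trues_total, prompts_total) {
  if (prompts_total <= 0) stop("prompts_total must be positive")
  if (trues_total < 0 || trues_total > prompts_total)
    stop("need 0 <= trues_total <= prompts_total")
  trues_total^2 / prompts_total
}
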