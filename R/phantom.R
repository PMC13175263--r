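#' Default organ activity / attenuation table
#'
#' Nominal radiotracer concentrations (kBq/ml, rescaled later so that the
#' lung background sits at 1/10 of the maximum tumour activity) and 511 keV
#' linear attenuation coefficients (1/mm) for the procedural torso phantom.
#'
#' @return data.frame with columns `organ`, `activity`, `attenuation`.
#' @export
default_organ_table <- function() {
  data.frame(
    organ       = c("soft", "lung", "heart", "bone"),
    activity    = c(1.0, 0.4, 3.0, 0.3),
    attenuation = c(0.0096, 0.0026, 0.0096, 0.0150),
    stringsAsFactors = FALSE
  )
}

#' Generate a procedural torso phantom
#'
#' Builds a simple anthropomorphic background on a voxel grid: an elliptical
#' soft-tissue body, two low-attenuation lung ellipsoids, a heart with
#' elevated uptake, a spine and periodic rib bands of bone. The left-lung
#' mask (patient left = +x) is returned for tumour placement.
#'
#' @param grid_dim integer length-3, voxels per axis.
#' @param voxel_size numeric length-3, voxel edges in mm.
#' @param organ_table as [default_organ_table()].
#' @return list with `activity` (kBq/ml), `attenuation` (1/mm), `lung_mask`
#'   (logical 3D, left lung only), `masks` (per-organ logical arrays),
#'   `voxel_size`, `organ_table`.
#' @export
make_torso_phantom <- function(grid_dim, voxel_size = c(2.09, 2.09, 2.03),
                               organ_table = default_organ_table()) {
  stopifnot(length(grid_dim) == 3, all(grid_dim >= 1), all(voxel_size > 0))
  if (any(grid_dim < c(24, 24, 8)))
    stop("grid too small to contain the torso organs (need at least 24 x 24 x 8 voxels)")
  need <- c("soft", "lung", "heart", "bone")
  if (!all(need %in% organ_table$organ))
    stop("organ table must contain rows: ", paste(need, collapse = ", "))
  org <- function(o, what) organ_table[[what]][match(o, organ_table$organ)]

  nx <- grid_dim[1]; ny <- grid_dim[2]; nz <- grid_dim[3]
  ext <- grid_dim * voxel_size
  ## voxel-centre world coordinates, origin at volume corner
  x <- ((seq_len(nx) - 0.5) * voxel_size[1] - ext[1] / 2) / ext[1]  # normalised [-0.5, 0.5]
  y <- ((seq_len(ny) - 0.5) * voxel_size[2] - ext[2] / 2) / ext[2]
  z <- ((seq_len(nz) - 0.5) * voxel_size[3] - ext[3] / 2) / ext[3]
  X <- array(rep(x, times = ny * nz), dim = grid_dim)
  Y <- array(rep(rep(y, each = nx), times = nz), dim = grid_dim)
  Z <- array(rep(z, each = nx * ny), dim = grid_dim)

  ellip <- function(cx, cy, cz, ax, ay, az)
    ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 + ((Z - cz) / az)^2 <= 1

  body_r2 <- (X / 0.45)^2 + (Y / 0.38)^2
  body <- body_r2 <= 1
  lung_l <- ellip( 0.20, -0.03, 0, 0.155, 0.22, 0.42)
  lung_r <- ellip(-0.20, -0.03, 0, 0.155, 0.22, 0.42)
  heart  <- ellip(-0.04,  0.02, 0, 0.11, 0.12, 0.30)
  spine  <- (X / 0.055)^2 + ((Y - 0.26) / 0.055)^2 <= 1
  ## rib shell: thin band of the body ellipse, periodic along z (in mm)
  zmm <- (Z + 0.5) * ext[3]
  shell <- body_r2 <= 1 & body_r2 >= 0.85 & (zmm %% 26) < 9
  ribs <- shell & !lung_l & !lung_r

  lungs <- (lung_l | lung_r) & body & !heart & !spine & !ribs
  heart <- heart & body
  spine <- spine & body
  act <- array(0, dim = grid_dim)
  att <- array(0, dim = grid_dim)
  assign_organ <- function(mask, organ) {
    act[mask] <<- org(organ, "activity")
    att[mask] <<- org(organ, "attenuation")
  }
  assign_organ(body, "soft")
  assign_organ(lungs, "lung")
  assign_organ(heart, "heart")
  assign_organ(spine, "bone")
  assign_organ(ribs, "bone")

  left_mask <- lung_l & lungs
  if (!any(left_mask) || !any(lungs) || !any(heart) || !any(ribs | spine))
    stop("grid too small to contain the torso organs")
  list(activity = act, attenuation = att,
       lung_mask = left_mask,
       masks = list(body = body, lungs = lungs, left_lung = left_mask,
                    heart = heart, spine = spine, ribs = ribs),
       voxel_size = voxel_size, organ_table = organ_table)
}

#' Tumour specification
#'
#' @param pattern one of `"uniform"`, `"halves"`, `"hollow"`.
#' @param target_volume_ml target volume in ml (0.01 to 200).
#' @param primary_activity main activity in kBq/ml.
#' @param secondary_activity second-half activity (halves pattern only).
#' @param elongation >= 0; larger values give more elongated, less spherical
#'   shapes (0 = near-spherical).
#' @param noise_amplitude relative amplitude of the smoothed random radial
#'   perturbation of the surface.
#' @param seed RNG seed making the shape reproducible.
#' @export
tumour_spec <- function(pattern = c("uniform", "halves", "hollow"),
                        target_volume_ml, primary_activity,
                        secondary_activity = NULL, elongation = 0,
                        noise_amplitude = 0.12, seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(target_volume_ml > 0, primary_activity > 0, elongation >= 0,
            noise_amplitude >= 0)
  if (target_volume_ml < 0.01 || target_volume_ml > 200)
    stop("target volume must lie within [0.01, 200] ml")
  if (pattern == "halves") {
    if (is.null(secondary_activity) || secondary_activity <= 0)
      stop("halves pattern requires a positive secondary_activity")
  }
  structure(list(pattern = pattern, target_volume_ml = target_volume_ml,
                 primary_activity = primary_activity,
                 secondary_activity = secondary_activity,
                 elongation = elongation, noise_amplitude = noise_amplitude,
                 seed = as.integer(seed)),
            class = "tumour_spec")
}

## random rotation matrix from the current RNG stream
random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; xq <- q[2]; yq <- q[3]; zq <- q[4]
  matrix(c(1 - 2 * (yq^2 + zq^2), 2 * (xq * yq - w * zq), 2 * (xq * zq + w * yq),
           2 * (xq * yq + w * zq), 1 - 2 * (xq^2 + zq^2), 2 * (yq * zq - w * xq),
           2 * (xq * zq - w * yq), 2 * (yq * zq + w * xq), 1 - 2 * (xq^2 + yq^2)),
         3, 3, byrow = TRUE)
}

#' Sample a tumour-like binary shape
#'
#' The shape is an ellipsoid (axis ratio set by `elongation`, random
#' orientation) whose radius is modulated by a smoothed random radial field,
#' voxelised on a local grid; the implicit-surface scale is found by binary
#' search so the voxelised volume matches the target. The result is a single
#' 26-connected component. Deterministic given (spec, seed).
#'
#' @param spec a [tumour_spec()].
#' @param voxel_size voxel edges in mm.
#' @return logical 3D array (local bounding grid, odd dimensions) with
#'   attributes `volume_ml` (achieved) and `n_voxels`.
#' @export
sample_tumour_shape <- function(spec, voxel_size) {
  stopifnot(inherits(spec, "tumour_spec"), length(voxel_size) == 3)
  vv <- voxel_volume_ml(voxel_size)
  n_target <- round(spec$target_volume_ml / vv)
  if (n_target < 1)
    stop(sprintf(paste0("target volume %.4f ml is below the minimum representable ",
                        "volume of %.4f ml (one voxel) at this grid"),
                 spec$target_volume_ml, vv))
  r_mm <- (3 * spec$target_volume_ml * 1000 / (4 * pi))^(1 / 3)
  e <- spec$elongation
  ax <- r_mm / sqrt(1 + e); az <- r_mm * (1 + e)
  half <- 1.25 * r_mm * (1 + e) * (1 + spec$noise_amplitude) + 2 * max(voxel_size)
  n_loc <- pmax(2L * as.integer(ceiling(half / voxel_size)) + 1L, 3L)

  with_seed(spec$seed, {
    R <- random_rotation()
    cx <- (n_loc + 1) / 2
    px <- (seq_len(n_loc[1]) - cx[1]) * voxel_size[1]
    py <- (seq_len(n_loc[2]) - cx[2]) * voxel_size[2]
    pz <- (seq_len(n_loc[3]) - cx[3]) * voxel_size[3]
    P <- cbind(rep(px, times = n_loc[2] * n_loc[3]),
               rep(rep(py, each = n_loc[1]), times = n_loc[3]),
               rep(pz, each = n_loc[1] * n_loc[2]))
    Q <- P %*% R                               # rotate into ellipsoid frame
    rho <- sqrt((Q[, 1] / ax)^2 + (Q[, 2] / ax)^2 + (Q[, 3] / az)^2)
    if (spec$noise_amplitude > 0) {
      noise <- array(rnorm(prod(n_loc)), dim = n_loc)
      sig <- pmax(1.0, (r_mm / 4) / voxel_size)
      delta <- cpp_gauss3(noise, n_loc, sig)
      delta <- as.vector(delta)
      delta <- delta / max(sd(delta), 1e-12) * spec$noise_amplitude
      delta <- pmin(pmax(delta, -0.5), 0.5)
    } else delta <- 0
    mod <- 1 + delta
    lo <- 0.2; hi <- 3.0
    for (i in 1:48) {
      mid <- (lo + hi) / 2
      cnt <- sum(rho <= mid * mod)
      if (cnt < n_target) lo <- mid else hi <- mid
    }
    cl <- sum(rho <= lo * mod); ch <- sum(rho <= hi * mod)
    s <- if (abs(cl - n_target) < abs(ch - n_target)) lo else hi
    mask <- array(rho <= s * mod, dim = n_loc)
    if (!any(mask)) {                          # tiny targets: one voxel
      mask[ceiling(n_loc[1] / 2), ceiling(n_loc[2] / 2), ceiling(n_loc[3] / 2)] <- TRUE
    }
    lab <- cpp_label26(mask, n_loc)
    if (max(lab) > 1) {                        # keep largest component
      keep <- which.max(tabulate(lab[lab > 0]))
      mask <- array(lab == keep, dim = n_loc)
    }
  })
  structure(mask, volume_ml = sum(mask) * vv, n_voxels = sum(mask))
}

#' Paint an activity pattern onto a tumour mask
#'
#' * `uniform`: every mask voxel gets `primary_activity`.
#' * `halves`: the mask is split by a plane through its centroid with random
#'   (seeded) orientation; one side gets the primary, the other the secondary
#'   activity.
#' * `hollow`: voxels deeper than half the equivalent-sphere radius from the
#'   surface (Euclidean distance transform) form a necrotic core assigned
#'   `background_activity`; the outer shell gets `primary_activity`.
#'
#' @param mask logical 3D tumour mask (local grid).
#' @param spec a [tumour_spec()].
#' @param voxel_size voxel edges in mm.
#' @param background_activity kBq/ml used for the hollow core.
#' @return list: `values` (activity array, 0 outside mask) and `region_masks`
#'   (`halves`: `high`/`low`; `hollow`: `shell`/`core`).
#' @export
apply_pattern <- function(mask, spec, voxel_size, background_activity = NULL) {
  check_volume3d(mask, "mask")
  if (!any(mask)) stop("mask is empty")
  dm <- dim(mask)
  vals <- array(0, dim = dm)
  regions <- list()
  if (spec$pattern == "uniform") {
    vals[mask] <- spec$primary_activity
  } else if (spec$pattern == "halves") {
    if (sum(mask) < 2) stop("cannot split a single-voxel tumour into halves")
    idx <- which(mask, arr.ind = TRUE)
    ctr <- colMeans(idx)
    pos <- sweep(idx, 2, ctr) * rep(voxel_size, each = nrow(idx))
    side <- NULL
    with_seed(spec$seed + 101L, {
      for (try in 1:20) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        s <- as.vector(pos %*% u) >= 0
        if (any(s) && any(!s)) { side <- s; break }
      }
    })
    if (is.null(side)) stop("cannot split a single-voxel tumour into halves")
    acts <- c(spec$primary_activity, spec$secondary_activity)
    hi <- which.max(acts); lo <- 3 - hi
    high_mask <- low_mask <- array(FALSE, dm)
    high_mask[idx[side, , drop = FALSE]] <- TRUE
    low_mask[idx[!side, , drop = FALSE]] <- TRUE
    vals[high_mask] <- acts[hi]
    vals[low_mask] <- acts[lo]
    regions <- list(high = high_mask, low = low_mask)
  } else {  # hollow
    if (is.null(background_activity) || background_activity < 0)
      stop("hollow pattern requires a non-negative background_activity")
    vml <- sum(mask) * voxel_volume_ml(voxel_size)
    r_eq <- (3 * vml * 1000 / (4 * pi))^(1 / 3)
    depth <- cpp_edt(mask, dim(mask), voxel_size)
    core <- mask & depth > r_eq / 2
    shell <- mask & !core
    vals[shell] <- spec$primary_activity
    vals[core] <- background_activity
    regions <- list(shell = shell, core = core)
  }
  list(values = vals, region_masks = regions)
}

#' Build a complete tumour record (shape + pattern + metadata)
#'
#' @inheritParams apply_pattern
#' @param spec a [tumour_spec()].
#' @param tbr tumour-to-background activity ratio (background = max tumour
#'   activity / `tbr`).
#' @return list of class `tumour_record`: local `mask`, `values`,
#'   `region_masks`, `pattern`, `volume_ml`, `sphericity`, `activities`,
#'   `background`, `spec`.
#' @export
make_tumour <- function(spec, voxel_size, tbr = 10) {
  mask <- sample_tumour_shape(spec, voxel_size)
  acts <- c(primary = spec$primary_activity)
  if (spec$pattern == "halves") acts <- c(acts, secondary = spec$secondary_activity)
  background <- max(acts) / tbr
  pat <- apply_pattern(mask, spec, voxel_size, background_activity = background)
  structure(list(mask = array(as.logical(mask), dim(mask)), values = pat$values,
                 region_masks = pat$region_masks, pattern = spec$pattern,
                 volume_ml = attr(mask, "volume_ml"),
                 sphericity = sphericity(array(as.logical(mask), dim(mask)), voxel_size),
                 activities = acts, background = background, tbr = tbr,
                 voxel_size = voxel_size, spec = spec),
            class = "tumour_record")
}

#' Place a tumour into the torso and set the global background level
#'
#' The whole torso activity is rescaled so the lung background equals
#' `max(tumour activity) / tbr` (ratio exactly `tbr`, default 10), then the
#' tumour activity pattern overwrites the background at a uniformly random
#' position fully inside the left lung.
#'
#' @param torso from [make_torso_phantom()].
#' @param tumour a `tumour_record` from [make_tumour()].
#' @param placement_seed RNG seed for the placement draw.
#' @return list: `activity` (ground-truth volume), `attenuation`, `record`
#'   (tumour record augmented with global `mask`, `region_masks`, `centroid`
#'   and `background`).
#' @export
assemble_ground_truth <- function(torso, tumour, placement_seed = 1L) {
  stopifnot(inherits(tumour, "tumour_record"))
  gdim <- dim(torso$activity)
  lung_act <- torso$organ_table$activity[match("lung", torso$organ_table$organ)]
  if (lung_act <= 0) stop("torso lung activity must be positive to set the background level")
  scale <- tumour$background / lung_act
  act <- torso$activity * scale

  ldim <- dim(tumour$mask)
  loc <- which(tumour$mask, arr.ind = TRUE)
  ctr <- ceiling(ldim / 2)
  offs <- sweep(loc, 2, ctr)                 # voxel offsets about local centre
  lung_idx <- which(torso$lung_mask, arr.ind = TRUE)
  if (nrow(lung_idx) == 0) stop("left lung mask is empty")
  try_centre <- function(cand) {
    vox <- sweep(offs, 2, cand, FUN = "+")
    if (any(vox < 1) || any(vox[, 1] > gdim[1]) || any(vox[, 2] > gdim[2]) ||
        any(vox[, 3] > gdim[3])) return(NULL)
    if (all(torso$lung_mask[vox])) list(centre = cand, vox = vox) else NULL
  }
  placed <- NULL
  with_seed(placement_seed, {
    ord <- sample.int(nrow(lung_idx))
    for (i in ord[seq_len(min(2000, length(ord)))]) {
      placed <- try_centre(lung_idx[i, ])
      if (!is.null(placed)) break
    }
  })
  if (is.null(placed)) {
    ## random search failed: fall back to the deepest lung positions, which
    ## maximise clearance; succeeds whenever any placement exists nearby
    depth <- cpp_edt(torso$lung_mask, gdim, torso$voxel_size)
    deep <- lung_idx[order(depth[torso$lung_mask], decreasing = TRUE), , drop = FALSE]
    for (i in seq_len(min(200, nrow(deep)))) {
      placed <- try_centre(deep[i, ])
      if (!is.null(placed)) break
    }
  }
  if (is.null(placed))
    stop("tumour larger than the left lung region: no valid placement found")

  vox <- placed$vox
  act[vox] <- tumour$values[loc]
  gmask <- array(FALSE, gdim)
  gmask[vox] <- TRUE
  gregions <- lapply(tumour$region_masks, function(rm) {
    g <- array(FALSE, gdim)
    g[sweep(which(rm, arr.ind = TRUE), 2, ctr - placed$centre, FUN = "-")] <- TRUE
    g
  })
  rec <- tumour
  rec$mask <- gmask
  rec$region_masks <- gregions
  rec$centroid <- colMeans(which(gmask, arr.ind = TRUE))
  rec$placement_seed <- placement_seed
  list(activity = act, attenuation = torso$attenuation, record = rec)
}

#' Crop a cubic patch centred on the tumour
#'
#' The crop is centred on the tumour centroid and clamped so it stays inside
#' the volume; the returned patch carries an `offset` attribute (1-based
#' start voxel) so it can be re-embedded with [embed_crop()].
#'
#' @param volume 3D array.
#' @param record a tumour record with a `centroid` (or a length-3 centre).
#' @param crop_shape integer length-3 (or scalar) crop dimensions.
#' @return array of dim `crop_shape` with attribute `offset`.
#' @export
crop_around_tumour <- function(volume, record, crop_shape) {
  check_volume3d(volume)
  if (length(crop_shape) == 1) crop_shape <- rep(crop_shape, 3)
  dm <- dim(volume)
  if (any(crop_shape > dm)) stop("crop_shape larger than the volume")
  ctr <- if (is.list(record)) record$centroid else record
  start <- round(ctr) - floor(crop_shape / 2)
  start <- pmin(pmax(start, 1), dm - crop_shape + 1)
  out <- volume[start[1]:(start[1] + crop_shape[1] - 1),
                start[2]:(start[2] + crop_shape[2] - 1),
                start[3]:(start[3] + crop_shape[3] - 1), drop = FALSE]
  attr(out, "offset") <- as.integer(start)
  out
}

#' Re-embed a crop produced by [crop_around_tumour()]
#' @param volume 3D array to write into.
#' @param patch crop with an `offset` attribute.
#' @return the modified volume.
#' @export
embed_crop <- function(volume, patch) {
  off <- attr(patch, "offset")
  if (is.null(off)) stop("patch has no offset attribute")
  cs <- dim(patch)
  volume[off[1]:(off[1] + cs[1] - 1), off[2]:(off[2] + cs[2] - 1),
         off[3]:(off[3] + cs[3] - 1)] <- patch
  volume
}
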