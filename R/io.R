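#' Write a volume to NIfTI
#'
#' @param values 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size voxel edges in mm, stored in the header.
#' @return the path, invisibly.
#' @export
write_volume <- function(values, path, voxel_size) {
  check_volume3d(values)
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path file path.
#' @return list: `values` (plain 3D array), `voxel_size` (mm).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  list(values = array(as.numeric(img), dim(img)), voxel_size = vs)
}

#' Write a sinogram with its geometry sidecar
#'
#' The count array is stored as NIfTI (bins x angles x slices) and the
#' geometry as a JSON sidecar next to it.
#'
#' @param sino sinogram array.
#' @param path `.nii` path; the sidecar replaces the extension with `.json`.
#' @param geom a [sinogram_geometry()].
#' @export
write_sinogram <- function(sino, path, geom) {
  img <- RNifti::asNifti(sino)
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(n_angles = geom$n_angles, n_bins = geom$n_bins,
                            ds = geom$ds, grid_dim = geom$grid_dim,
                            voxel_size = geom$voxel_size),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sinogram written by [write_sinogram()]
#' @param path `.nii` path.
#' @return list: `sino` array and `geom` ([sinogram_geometry()]).
#' @export
read_sinogram <- function(path) {
  img <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  geom <- sinogram_geometry(meta$grid_dim, meta$voxel_size, meta$n_angles)
  if (geom$n_bins != meta$n_bins)
    stop("sinogram geometry sidecar is inconsistent with its array")
  sino <- array(as.numeric(img), dim(img))
  if (!identical(dim(sino), c(geom$n_bins, geom$n_angles, as.integer(meta$grid_dim[3]))))
    stop("sinogram dimensions do not match the geometry sidecar")
  list(sino = sino, geom = geom)
}

#' Write a tumour record sidecar (metadata only, no voxel masks)
#' @param record a `tumour_record`.
#' @param path JSON output path.
#' @export
write_tumour_record <- function(record, path) {
  meta <- list(pattern = record$pattern, volume_ml = record$volume_ml,
               sphericity = record$sphericity,
               activities = as.list(record$activities),
               background = record$background, tbr = record$tbr,
               centroid = record$centroid,
               placement_seed = record$placement_seed,
               shape_seed = record$spec$seed)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a dataset manifest (one row per case)
#' @param manifest data.frame.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) read.csv(path, stringsAsFactors = FALSE)
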