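#' Write a sinogram container
#'
#' Binary little-endian float64 payload (`<path>`) plus a JSON sidecar
#' (`<path>.json`) carrying the kind and the full geometry, so the
#' round trip through [read_sinogram()] is bit-exact.
#'
#' @param sino A `sinogram`.
#' @param path Payload file path; the sidecar gets a `.json` suffix.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  g <- sino$geometry
  meta <- list(
    format = "acfmargin-sinogram-v1", kind = sino$kind,
    dim = dim(sino$values), endian = "little",
    geometry = list(n_rings = g$n_rings, ring_pitch_mm = g$ring_pitch_mm,
                    n_angles = g$n_angles, n_radial = g$n_radial,
                    radial_pitch_mm = g$radial_pitch_mm,
                    max_ring_difference = g$max_ring_difference,
                    fov_radius_mm = g$fov_radius_mm))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(sino$values), con, size = 8, endian = "little")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sinogram container written by [write_sinogram()]
#' @param path Payload file path.
#' @export
read_sinogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "acfmargin-sinogram-v1"))
    stop("not an acfmargin sinogram container")
  gm <- meta$geometry
  g <- build_geometry(n_rings = gm$n_rings, ring_pitch_mm = gm$ring_pitch_mm,
                      n_angles = gm$n_angles, n_radial = gm$n_radial,
                      radial_pitch_mm = gm$radial_pitch_mm,
                      max_ring_difference = gm$max_ring_difference,
                      fov_radius_mm = gm$fov_radius_mm)
  n <- prod(meta$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8, endian = "little")
  sinogram(array(v, meta$dim), meta$kind, g)
}

#' Write a volume as NIfTI-1
#'
#' Voxel pitch is carried in the NIfTI pixdim. Use a `.nii.gz` path.
#' @param vol A `volume_image`.
#' @param path Output path.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- c(vol$voxel_pitch_mm, vol$voxel_pitch_mm,
                           vol$slice_pitch_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_volume()]
#' @param path NIfTI path.
#' @param quantity Quantity tag to attach (not stored in NIfTI).
#' @export
read_volume <- function(path, quantity = "activity_kBq_per_ml") {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  volume_image(array(as.vector(img), dim(img)[1:3]),
               voxel_pitch_mm = pd[1], slice_pitch_mm = pd[3],
               quantity = quantity)
}
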