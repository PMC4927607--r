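#' Forward project a volume into a sinogram
#'
#' Each bin receives the line integral of the volume along its LOR
#' (input units times mm). The operator is linear, and [back_project()]
#' is its exact adjoint (same ray sampling and trilinear weights).
#'
#' @param volume A `volume_image` of activity or attenuation.
#' @param geometry A `scanner_geometry` whose FOV the volume covers.
#' @param angle_idx Optional integer subset of angles (used by OSEM).
#' @param step_mm Ray sampling step; defaults to half the voxel pitch.
#' @return A `sinogram` of kind `"trues"` (or a plain array for a subset).
#' @export
forward_project <- function(volume, geometry, angle_idx = NULL,
                            step_mm = NULL) {
  stopifnot(inherits(volume, "volume_image"),
            inherits(geometry, "scanner_geometry"))
  if (volume$quantity == "label")
    stop("cannot forward project a label volume")
  check_vol_covers(volume, geometry)
  full <- is.null(angle_idx)
  angles <- if (full) geometry$angles else geometry$angles[angle_idx]
  v <- cpp_project(as.double(volume$values), dim(volume$values),
                   volume$voxel_pitch_mm, volume$slice_pitch_mm,
                   angles, geometry$radials,
                   geometry$plane_table$z_a, geometry$plane_table$z_b,
                   geometry$det_radius_mm,
                   if (is.null(step_mm)) volume$voxel_pitch_mm / 2 else step_mm,
                   TRUE, numeric(0))
  arr <- array(v, c(geometry$n_radial, length(angles), geometry$n_planes))
  if (full) sinogram(pmax(arr, 0), "trues", geometry) else arr
}

#' Back project a sinogram into a volume
#'
#' Exact adjoint of [forward_project()]: for any volume `x` and sinogram
#' `y`, `<Px, y> == <x, P'y>` to floating-point accuracy.
#'
#' @param sino A `sinogram`, or a plain array when `angle_idx` is given.
#' @param geometry A `scanner_geometry`.
#' @param nx Transverse output matrix size.
#' @param angle_idx Optional integer subset of angles.
#' @param step_mm Ray sampling step (must match the forward call).
#' @export
back_project <- function(sino, geometry, nx = 64, angle_idx = NULL,
                         step_mm = NULL) {
  vals <- if (inherits(sino, "sinogram")) sino$values else sino
  tmpl <- blank_volume(geometry, nx)
  full <- is.null(angle_idx)
  angles <- if (full) geometry$angles else geometry$angles[angle_idx]
  stopifnot(identical(dim(vals)[2], length(angles)))
  v <- cpp_project(as.double(tmpl$values), dim(tmpl$values),
                   tmpl$voxel_pitch_mm, tmpl$slice_pitch_mm,
                   angles, geometry$radials,
                   geometry$plane_table$z_a, geometry$plane_table$z_b,
                   geometry$det_radius_mm,
                   if (is.null(step_mm)) tmpl$voxel_pitch_mm / 2 else step_mm,
                   FALSE, as.double(vals))
  tmpl$values <- array(v, dim(tmpl$values))
  tmpl
}

check_vol_covers <- function(volume, geometry) {
  d <- dim(volume$values)
  if (d[1] != d[2])
    stop("transverse volume grid must be square")
  half <- d[1] * volume$voxel_pitch_mm / 2
  if (half < geometry$fov_radius_mm - volume$voxel_pitch_mm)
    stop("volume grid does not cover the transverse FOV")
  invisible(TRUE)
}

#' Attenuation correction factor sinogram
#'
#' ACF bin = exp(line integral of mu along the LOR); bins whose LOR misses
#' the object are exactly 1.
#'
#' @param mu_map A `volume_image` with quantity `"mu_per_mm"`.
#' @param geometry A `scanner_geometry`.
#' @export
compute_acf <- function(mu_map, geometry) {
  stopifnot(inherits(mu_map, "volume_image"))
  if (mu_map$quantity != "mu_per_mm")
    stop("mu_map must have quantity 'mu_per_mm'")
  if (any(mu_map$values < 0)) stop("mu values must be non-negative")
  p <- forward_project(mu_map, geometry)
  sinogram(exp(p$values), "acf", geometry)
}

#' Add Poisson counting noise to a sinogram
#'
#' The input is rescaled so its expected total equals `total_counts`, then
#' each bin is replaced by an independent Poisson draw. The same seed gives
#' a bitwise-identical result.
#'
#' @param sino An emission-like `sinogram` (kinds `"emission"`/`"trues"`).
#' @param total_counts Expected total counts (> 0).
#' @param seed Integer seed.
#' @export
add_poisson_noise <- function(sino, total_counts, seed) {
  stopifnot(inherits(sino, "sinogram"), total_counts > 0)
  if (!sino$kind %in% c("emission", "trues"))
    stop("Poisson noise applies to emission-like sinograms")
  if (any(sino$values < 0)) stop("input values must be non-negative")
  tot <- sum(sino$values)
  v <- sino$values
  if (tot > 0) {
    lam <- sino$values * (total_counts / tot)
    v <- array(as.double(withr::with_seed(as.integer(seed),
                                          rpois(length(lam),
                                                as.vector(lam)))),
               dim(sino$values))
  }
  sinogram(v, "emission", sino$geometry)
}
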