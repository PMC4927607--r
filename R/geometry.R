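#' Build a cylindrical scanner geometry
#'
#' Defines a miniature cylindrical PET scanner in a parallel-beam sinogram
#' parameterisation: per axial plane, bins are indexed by projection angle
#' and signed radial offset; axially, line-of-response (LOR) groups with a
#' fixed ring difference form segments, and within a segment each plane is
#' one ordered ring pair. Segment 0 holds the direct (non-oblique) planes.
#'
#' @param n_rings Number of detector rings.
#' @param ring_pitch_mm Axial spacing between ring centres (mm).
#' @param n_angles Number of projection angles over \eqn{[0, \pi)}.
#' @param n_radial Number of radial bins.
#' @param radial_pitch_mm Radial bin spacing (mm).
#' @param max_ring_difference Largest |ring difference| kept; must be
#'   smaller than `n_rings`.
#' @param fov_radius_mm Transverse field-of-view radius (mm). Defaults to
#'   half the radial extent, `n_radial * radial_pitch_mm / 2`.
#' @return An object of class `scanner_geometry` with derived angle/radial
#'   coordinate vectors and the (segment, plane) to ring-pair table.
#' @export
build_geometry <- function(n_rings = 8, ring_pitch_mm = 4.88,
                           n_angles = 96, n_radial = 128,
                           radial_pitch_mm = 2.44,
                           max_ring_difference = n_rings - 1L,
                           fov_radius_mm = NULL) {
  stopifnot(n_rings >= 1, n_angles >= 1, n_radial >= 1,
            ring_pitch_mm > 0, radial_pitch_mm > 0,
            max_ring_difference >= 0)
  if (max_ring_difference >= n_rings)
    stop("max_ring_difference must be smaller than n_rings")
  if (is.null(fov_radius_mm))
    fov_radius_mm <- n_radial * radial_pitch_mm / 2
  if (n_radial * radial_pitch_mm < 2 * fov_radius_mm)
    stop("radial extent (n_radial * radial_pitch_mm) does not cover the FOV")

  # segment order 0, +1, -1, +2, -2, ...; planes ordered by first ring
  segs <- 0L
  if (max_ring_difference > 0)
    segs <- c(0L, as.integer(rbind(seq_len(max_ring_difference),
                                   -seq_len(max_ring_difference))))
  ring_z <- (seq_len(n_rings) - (n_rings + 1) / 2) * ring_pitch_mm
  pt <- do.call(rbind, lapply(segs, function(d) {
    n <- n_rings - abs(d)
    r1 <- seq_len(n)
    if (d >= 0) data.frame(segment = d, ring_a = r1, ring_b = r1 + d)
    else        data.frame(segment = d, ring_a = r1 + abs(d), ring_b = r1)
  }))
  pt$z_a <- ring_z[pt$ring_a]
  pt$z_b <- ring_z[pt$ring_b]

  g <- structure(list(
    n_rings = as.integer(n_rings), ring_pitch_mm = ring_pitch_mm,
    n_angles = as.integer(n_angles), n_radial = as.integer(n_radial),
    radial_pitch_mm = radial_pitch_mm,
    max_ring_difference = as.integer(max_ring_difference),
    fov_radius_mm = fov_radius_mm,
    det_radius_mm = 1.5 * fov_radius_mm,
    angles = (seq_len(n_angles) - 1) * pi / n_angles,
    radials = (seq_len(n_radial) - 1 - (n_radial - 1) / 2) * radial_pitch_mm,
    ring_z = ring_z,
    plane_table = pt,
    n_planes = nrow(pt)
  ), class = "scanner_geometry")
  g
}

#' Desk-scale default geometry
#'
#' Eight rings, 96 angles and 128 radial bins at a 2.44-mm radial pitch
#' (twice the HRRT's 1.22-mm voxel pitch) so that a 180-mm head fits the
#' field of view with ample scatter-tail room on either side.
#' @export
desk_geometry <- function() {
  build_geometry(n_rings = 8, ring_pitch_mm = 4.88, n_angles = 96,
                 n_radial = 128, radial_pitch_mm = 2.44,
                 max_ring_difference = 7L)
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat(sprintf(
    "<scanner_geometry> %d rings (pitch %.2f mm), %d angles x %d radial (pitch %.2f mm)\n",
    x$n_rings, x$ring_pitch_mm, x$n_angles, x$n_radial, x$radial_pitch_mm))
  cat(sprintf("  FOV radius %.1f mm; %d segments (|ring diff| <= %d), %d planes\n",
              x$fov_radius_mm, length(unique(x$plane_table$segment)),
              x$max_ring_difference, x$n_planes))
  invisible(x)
}

#' Construct a sinogram
#'
#' Values live on the (radial, angle, plane) grid of a geometry. `kind`
#' records what the values mean: emission counts, attenuation correction
#' factors (all >= 1), a scatter model, or noiseless trues.
#'
#' @param values Numeric array `c(n_radial, n_angles, n_planes)`.
#' @param kind One of `"emission"`, `"acf"`, `"scatter"`, `"trues"`.
#' @param geometry A `scanner_geometry`.
#' @export
sinogram <- function(values, kind, geometry) {
  kind <- match.arg(kind, c("emission", "acf", "scatter", "trues"))
  stopifnot(inherits(geometry, "scanner_geometry"))
  dims <- c(geometry$n_radial, geometry$n_angles, geometry$n_planes)
  if (!identical(dim(values), as.integer(dims)))
    stop("sinogram values have shape inconsistent with geometry")
  if (any(!is.finite(values))) stop("sinogram values must be finite")
  if (kind == "acf") {
    if (any(values < 1 - 1e-9)) stop("ACF sinogram must have all values >= 1")
  } else if (any(values < 0)) {
    stop(sprintf("%s sinogram must be non-negative", kind))
  }
  structure(list(values = values, kind = kind, geometry = geometry),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram:%s> %d x %d x %d, total %.4g\n", x$kind,
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              sum(x$values)))
  invisible(x)
}

#' Construct a voxel image
#'
#' A scalar field on a voxel grid with the physical origin at the grid
#' centre. Transverse pitch is isotropic in x/y; the axial pitch may differ.
#'
#' @param values Numeric 3D array (nx, ny, nz).
#' @param voxel_pitch_mm Transverse voxel pitch (mm).
#' @param slice_pitch_mm Axial slice pitch (mm); defaults to the transverse.
#' @param quantity One of `"activity_kBq_per_ml"`, `"mu_per_mm"`, `"label"`.
#' @export
volume_image <- function(values, voxel_pitch_mm,
                         slice_pitch_mm = voxel_pitch_mm,
                         quantity = c("activity_kBq_per_ml", "mu_per_mm",
                                      "label")) {
  quantity <- match.arg(quantity)
  stopifnot(length(dim(values)) == 3, voxel_pitch_mm > 0, slice_pitch_mm > 0)
  if (quantity == "mu_per_mm" && (any(values < 0) || any(values > 0.02)))
    stop("mu values must lie in [0, 0.02] per mm")
  if (quantity == "activity_kBq_per_ml" && any(values < 0))
    stop("activity values must be non-negative")
  if (quantity == "label" && any(values != round(values)))
    stop("label values must be integers")
  structure(list(values = values, voxel_pitch_mm = voxel_pitch_mm,
                 slice_pitch_mm = slice_pitch_mm, quantity = quantity),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_image:%s> %d x %d x %d @ %.2f/%.2f mm\n", x$quantity,
              d[1], d[2], d[3], x$voxel_pitch_mm, x$slice_pitch_mm))
  invisible(x)
}

#' Blank volume matched to a geometry
#'
#' Transverse grid of `nx` x `nx` voxels spanning the FOV diameter; axial
#' grid of `2 * n_rings - 1` slices at half the ring pitch, exactly covering
#' the axial span of the rings.
#' @param geometry A `scanner_geometry`.
#' @param nx Transverse matrix size.
#' @param quantity Passed to [volume_image()].
#' @export
blank_volume <- function(geometry, nx = 64,
                         quantity = "activity_kBq_per_ml") {
  nz <- 2L * geometry$n_rings - 1L
  volume_image(array(0, c(nx, nx, nz)),
               voxel_pitch_mm = 2 * geometry$fov_radius_mm / nx,
               slice_pitch_mm = geometry$ring_pitch_mm / 2,
               quantity = quantity)
}

# physical voxel-centre coordinates along each axis
vol_coords <- function(vol) {
  d <- dim(vol$values)
  list(x = (seq_len(d[1]) - (d[1] + 1) / 2) * vol$voxel_pitch_mm,
       y = (seq_len(d[2]) - (d[2] + 1) / 2) * vol$voxel_pitch_mm,
       z = (seq_len(d[3]) - (d[3] + 1) / 2) * vol$slice_pitch_mm)
}

#' Rigid translation descriptor
#'
#' @param dx,dy,dz Displacements in mm.
#' @export
rigid_shift <- function(dx = 0, dy = 0, dz = 0) {
  stopifnot(is.finite(dx), is.finite(dy), is.finite(dz))
  structure(list(dx = dx, dy = dy, dz = dz), class = "rigid_shift")
}

#' Apply a rigid translation to a volume
#'
#' Content moves by `+shift` (trilinear interpolation, zero outside).
#' @param vol A `volume_image`.
#' @param shift A [rigid_shift()].
#' @export
shift_volume <- function(vol, shift) {
  stopifnot(inherits(vol, "volume_image"), inherits(shift, "rigid_shift"))
  v <- cpp_shift_volume(as.double(vol$values), dim(vol$values),
                        vol$voxel_pitch_mm, vol$slice_pitch_mm,
                        shift$dx, shift$dy, shift$dz)
  out <- vol
  if (vol$quantity == "mu_per_mm") v <- pmin(pmax(v, 0), 0.02)
  out$values <- array(v, dim(vol$values))
  out
}
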