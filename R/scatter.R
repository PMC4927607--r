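#' Klein-Nishina differential cross-section at 511 keV
#'
#' For an incident annihilation photon, the differential Compton
#' cross-section in units of the classical electron radius squared:
#' `0.5 * P^2 * (P + 1/P - sin^2 theta)` with `P = E'/E = 1/(2 - cos
#' theta)`. Equals 1 at forward scatter and 5/27 at backscatter.
#'
#' @param theta Scattering angle(s) in radians, in `[0, pi]`.
#' @export
klein_nishina <- function(theta) {
  if (any(theta < 0 | theta > pi)) stop("theta must lie in [0, pi]")
  P <- 1 / (2 - cos(theta))
  0.5 * P^2 * (P + 1 / P - sin(theta)^2)
}

#' Energy of a Compton-scattered annihilation photon
#'
#' `E' = 511 / (2 - cos theta)` keV.
#' @param theta Scattering angle(s) in radians, in `[0, pi]`.
#' @export
scattered_energy <- function(theta) {
  if (any(theta < 0 | theta > pi)) stop("theta must lie in [0, pi]")
  511 / (2 - cos(theta))
}

#' Total Klein-Nishina cross-section
#'
#' Per-electron total Compton cross-section (units of r_e^2) at photon
#' energy `E_keV`; its ratio to the 511-keV value supplies the energy
#' scaling of the attenuation coefficient on the scattered photon's leg.
#' @param E_keV Photon energy in keV.
#' @export
kn_total_cross_section <- function(E_keV) {
  stopifnot(all(E_keV > 0))
  vapply(E_keV / 511, cpp_kn_total, numeric(1))
}

#' Single scatter simulation (2D or 3D)
#'
#' Estimates the unscaled single-scatter sinogram for an activity estimate
#' and an attenuation map. For every LOR (A, B) the estimator sums, over
#' scatter points S on a coarse grid restricted to attenuating tissue, the
#' standard single-scatter term: emission line integral on one leg,
#' attenuation at 511 keV on the unscattered leg and at the scattered
#' energy on the other, the Klein-Nishina weight at the scattering angle,
#' inverse-square distances to both detectors, and a Gaussian-smoothed
#' energy-window acceptance (lower level discriminator `lld_keV`, Gaussian
#' energy resolution `energy_fwhm` fractional FWHM). The scatter sinogram
#' is evaluated on a coarse (angle, radial) grid and bilinearly
#' interpolated to full resolution; it is smooth by construction.
#'
#' Mode `"sss3d"` evaluates every segment's true oblique geometry with
#' volumetric scatter points. Mode `"sss2d"` takes only scatter
#' coincidences in non-oblique imaging planes into account: each direct
#' (segment 0) plane is evaluated with scatter points and detector
#' endpoints confined to that plane, and oblique planes are filled by
#' axial-midpoint interpolation between direct planes. Because the 2D
#' restriction changes the absolute amount of modelled scatter, 2D and 3D
#' models are comparable (and are used) only up to the scale set downstream
#' by tail fitting.
#'
#' @param activity_estimate Activity `volume_image` (any positive scale;
#'   tail fitting absorbs the global factor).
#' @param mu_map Congruent `mu_per_mm` volume.
#' @param geometry A `scanner_geometry`.
#' @param mode `"sss3d"` (default) or `"sss2d"`.
#' @param scatter_grid_mm Scatter-point grid spacing (mm).
#' @param lld_keV Lower level discriminator (keV).
#' @param energy_fwhm Fractional energy resolution FWHM at 511 keV.
#' @param mu_cutoff Minimum mu for a grid point to scatter (1/mm).
#' @param coarse_angles,coarse_radial Size of the coarse evaluation grid.
#' @param step_mm Ray sampling step for the scatter-leg integrals.
#' @return A `scatter_model`: list with `sino` (kind `"scatter"`), `mode`,
#'   `scatter_grid_mm` and the number of scatter points used.
#' @export
sss_estimate <- function(activity_estimate, mu_map, geometry,
                         mode = c("sss3d", "sss2d"), scatter_grid_mm = 8,
                         lld_keV = 400, energy_fwhm = 0.17,
                         mu_cutoff = 0.002, coarse_angles = 24,
                         coarse_radial = 32, step_mm = 4) {
  mode <- match.arg(mode)
  stopifnot(inherits(activity_estimate, "volume_image"),
            inherits(mu_map, "volume_image"),
            identical(dim(activity_estimate$values), dim(mu_map$values)))

  sp <- scatter_points(mu_map, scatter_grid_mm, mu_cutoff)
  if (nrow(sp$xyz) == 0)
    stop("degenerate input: no scatter points (mu below cutoff everywhere)")

  # coarse transverse LOR grid (indices into the full angle/radial grids)
  na <- geometry$n_angles; nr <- geometry$n_radial
  ia <- unique(round(seq(1, na, length.out = min(coarse_angles, na))))
  ir <- unique(round(seq(1, nr, length.out = min(coarse_radial, nr))))
  nca <- length(ia); ncr <- length(ir)

  # transverse endpoints: 2 per coarse LOR (sides A/B), on the detector circle
  Rdet <- geometry$det_radius_mm
  ang <- geometry$angles[ia]; rad <- geometry$radials[ir]
  grid <- expand.grid(r = seq_len(ncr), a = seq_len(nca))
  s <- rad[grid$r]; phi <- ang[grid$a]
  tmax <- sqrt(pmax(Rdet^2 - s^2, 0))
  axy <- cbind(-sin(phi) * s - tmax * cos(phi),
               cos(phi) * s - tmax * sin(phi))
  bxy <- cbind(-sin(phi) * s + tmax * cos(phi),
               cos(phi) * s + tmax * sin(phi))
  n_t <- nrow(grid)                       # coarse transverse LORs
  # endpoint table: (side, transverse LOR) x ring
  ring_z <- geometry$ring_z
  n_rings <- geometry$n_rings
  exy <- rbind(axy, bxy)                  # 2 * n_t rows
  ep <- cbind(exy[rep(seq_len(2 * n_t), n_rings), ],
              rep(ring_z, each = 2 * n_t))
  e_idx <- function(side, tl, ring)       # 1-based row in ep
    (ring - 1L) * 2L * n_t + (side - 1L) * n_t + tl

  pt <- geometry$plane_table
  tl <- seq_len(n_t)
  n_pts <- 0L
  if (mode == "sss3d") {
    ints <- cpp_ray_integrals(as.double(activity_estimate$values),
                              as.double(mu_map$values),
                              dim(mu_map$values),
                              mu_map$voxel_pitch_mm, mu_map$slice_pitch_mm,
                              ep, sp$xyz, step_mm)
    ia_idx <- unlist(lapply(seq_len(nrow(pt)), function(p)
      e_idx(1L, tl, pt$ring_a[p])))
    ib_idx <- unlist(lapply(seq_len(nrow(pt)), function(p)
      e_idx(2L, tl, pt$ring_b[p])))
    vals <- cpp_sss_assemble(ep, sp$xyz, sp$mu, ints$act, ints$mu,
                             as.integer(ia_idx), as.integer(ib_idx),
                             lld_keV, energy_fwhm, sp$vol_elem,
                             2 * scatter_grid_mm)
    coarse <- array(vals, c(ncr, nca, nrow(pt)))
    n_pts <- nrow(sp$xyz)
  } else {
    # per direct plane: scatter points and endpoints confined to the plane
    direct <- array(0, c(ncr, nca, n_rings))
    for (r in seq_len(n_rings)) {
      spp <- plane_scatter_points(mu_map, scatter_grid_mm, mu_cutoff,
                                  ring_z[r], geometry$ring_pitch_mm)
      if (nrow(spp$xyz) == 0) next
      epp <- cbind(exy, ring_z[r])
      ints <- cpp_ray_integrals(as.double(activity_estimate$values),
                                as.double(mu_map$values),
                                dim(mu_map$values),
                                mu_map$voxel_pitch_mm,
                                mu_map$slice_pitch_mm,
                                epp, spp$xyz, step_mm)
      vals <- cpp_sss_assemble(epp, spp$xyz, spp$mu, ints$act, ints$mu,
                               as.integer(tl), as.integer(n_t + tl),
                               lld_keV, energy_fwhm, spp$vol_elem,
                               2 * scatter_grid_mm)
      direct[, , r] <- vals
      n_pts <- n_pts + nrow(spp$xyz)
    }
    if (all(direct == 0))
      stop("degenerate input: no scatter points on any direct plane")
    # oblique planes looked up at their axial midpoint
    zs <- ring_z
    coarse <- array(0, c(ncr, nca, nrow(pt)))
    for (p in seq_len(nrow(pt))) {
      zm <- (pt$z_a[p] + pt$z_b[p]) / 2
      if (n_rings == 1) { coarse[, , p] <- direct[, , 1]; next }
      j <- findInterval(zm, zs, all.inside = TRUE)
      w <- min(max((zm - zs[j]) / (zs[j + 1] - zs[j]), 0), 1)
      coarse[, , p] <- (1 - w) * direct[, , j] + w * direct[, , j + 1]
    }
  }

  full <- interp_sino_coarse(coarse, ir, ia, nr, na)
  sm <- structure(list(sino = sinogram(pmax(full, 0), "scatter", geometry),
                       mode = mode, scatter_grid_mm = scatter_grid_mm,
                       n_scatter_points = n_pts),
                  class = "scatter_model")
  sm
}

# in-plane scatter points for the 2D mode: transverse grid at the plane's
# axial position, slab thickness = ring pitch
plane_scatter_points <- function(mu_map, grid_mm, mu_cutoff, z_mm,
                                 slab_mm) {
  co <- vol_coords(mu_map)
  gx <- seq(min(co$x), max(co$x), by = grid_mm)
  gy <- seq(min(co$y), max(co$y), by = grid_mm)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = z_mm))
  mu <- interp_volume(mu_map, pts)
  keep <- mu > mu_cutoff
  list(xyz = pts[keep, , drop = FALSE], mu = mu[keep],
       vol_elem = grid_mm * grid_mm * slab_mm)
}

# coarse grid of scatter points inside attenuating tissue
scatter_points <- function(mu_map, grid_mm, mu_cutoff) {
  co <- vol_coords(mu_map)
  gx <- seq(min(co$x), max(co$x), by = grid_mm)
  gy <- seq(min(co$y), max(co$y), by = grid_mm)
  gz <- if (diff(range(co$z)) >= grid_mm)
    seq(min(co$z), max(co$z), by = grid_mm) else mean(range(co$z))
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  mu <- interp_volume(mu_map, pts)
  keep <- mu > mu_cutoff
  zel <- if (length(gz) > 1) grid_mm else diff(range(co$z)) + mu_map$slice_pitch_mm
  list(xyz = pts[keep, , drop = FALSE], mu = mu[keep],
       vol_elem = grid_mm * grid_mm * zel)
}

# trilinear interpolation of a volume at physical points (n x 3, mm)
interp_volume <- function(vol, pts) {
  d <- dim(vol$values)
  fx <- pts[, 1] / vol$voxel_pitch_mm + (d[1] + 1) / 2
  fy <- pts[, 2] / vol$voxel_pitch_mm + (d[2] + 1) / 2
  fz <- pts[, 3] / vol$slice_pitch_mm + (d[3] + 1) / 2
  i0 <- pmin(pmax(floor(fx), 1), d[1] - 1); wx <- pmin(pmax(fx - i0, 0), 1)
  j0 <- pmin(pmax(floor(fy), 1), d[2] - 1); wy <- pmin(pmax(fy - j0, 0), 1)
  k0 <- pmin(pmax(floor(fz), 1), max(d[3] - 1, 1)); wz <-
    if (d[3] > 1) pmin(pmax(fz - k0, 0), 1) else 0
  k1 <- pmin(k0 + 1, d[3])
  v <- vol$values
  out <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy) *
      (if (dz) wz else 1 - wz)
    out <- out + w * v[cbind(i0 + dx, j0 + dy, if (dz) k1 else k0)]
  }
  out
}

# bilinear upsampling of a coarse (radial, angle, plane) stack to the full
# grid; the angular direction wraps with the pi-periodic radial flip
interp_sino_coarse <- function(coarse, ir, ia, nr, na) {
  ncr <- length(ir); nca <- length(ia); np <- dim(coarse)[3]
  out <- array(0, c(nr, na, np))
  ia_ext <- c(ia, na + ia[1])
  for (p in seq_len(np)) {
    sl <- coarse[, , p]
    # radial first
    rfull <- apply(sl, 2, function(col)
      approx(ir, col, xout = seq_len(nr), rule = 2)$y)
    # angular wrap column: first coarse angle + pi == radial flip
    wrap <- rev(rfull[, 1])
    rext <- cbind(rfull, wrap)
    out[, , p] <- t(apply(rext, 1, function(row)
      approx(ia_ext, row, xout = seq_len(na), rule = 2)$y))
  }
  out
}

# separable Gaussian smoothing along the radial and angular axes; used for
# the ground-truth scatter broadening in the simulator
smooth_sinogram <- function(arr, sigma_radial = 1.5, sigma_angle = 1.5) {
  sm1 <- function(m, sigma, along) {
    if (sigma <= 0) return(m)
    half <- max(1L, ceiling(3 * sigma))
    k <- exp(-0.5 * ((-half):half / sigma)^2)
    k <- k / sum(k)
    conv1 <- function(v) {
      vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
      as.numeric(stats::filter(vp, k, sides = 2))[(half + 1):(half + length(v))]
    }
    if (along == 1) apply(m, 2, conv1) else t(apply(m, 1, conv1))
  }
  out <- arr
  for (p in seq_len(dim(arr)[3])) {
    sl <- arr[, , p]
    sl <- sm1(sl, sigma_radial, 1)
    sl <- sm1(sl, sigma_angle, 2)
    out[, , p] <- sl
  }
  out
}

#' Tail mask from an ACF sinogram
#'
#' Bins outside the attenuating object, identified by thresholding the ACF
#' sinogram (`ACF <= threshold`), optionally after widening the object band
#' by `margin_voxels` bins along the radial axis only (the ACF-margin). The
#' margin moves emission-contaminated object-edge bins out of the scatter
#' tail when transmission and emission data are misaligned; it affects only
#' scatter scaling, never attenuation correction.
#'
#' @param acf An `"acf"` sinogram.
#' @param threshold ACF object threshold (default 1.03).
#' @param margin_voxels Radial dilation of the object band, in bins.
#' @return A `tail_mask`: logical array + parameters.
#' @export
tail_mask <- function(acf, threshold = 1.03, margin_voxels = 0L) {
  stopifnot(inherits(acf, "sinogram"))
  if (acf$kind != "acf") stop("tail_mask needs an ACF sinogram")
  margin_voxels <- as.integer(margin_voxels)
  if (margin_voxels < 0) stop("margin must be non-negative")
  nr <- dim(acf$values)[1]
  if (margin_voxels >= nr / 2)
    stop("margin must be smaller than half the radial extent")
  obj <- acf$values > threshold
  dil <- obj
  if (margin_voxels > 0) {
    for (k in seq_len(margin_voxels)) {
      up <- dil; up[-1, , ] <- dil[-nr, , ]; up[1, , ] <- FALSE
      dn <- dil; dn[-nr, , ] <- dil[-1, , ]; dn[nr, , ] <- FALSE
      dil <- dil | up | dn
    }
  }
  structure(list(mask = !dil, acf_threshold = threshold,
                 margin_voxels = margin_voxels),
            class = "tail_mask")
}

#' Least-squares tail fit of scatter scale factors
#'
#' Per plane p, the scale is the non-negative least-squares solution
#' `s_p = sum_tail(y m) / sum_tail(m^2)` (clamped at 0). Planes with fewer
#' than `min_tail_bins` usable tail bins, or with an identically zero model
#' on their tail, are flagged and filled from the nearest fitted plane.
#' `per_plane = FALSE` pools all tail bins into a single global scale.
#'
#' @param measured Measured emission `sinogram`.
#' @param model A `scatter_model` (or scatter `sinogram`).
#' @param mask A [tail_mask()] congruent with the data.
#' @param per_plane Fit per plane (default) or one global scale.
#' @param min_tail_bins Minimum tail bins for a plane to be fitted.
#' @return A `tail_fit`: per-plane scales `s`, `global_scale`, per-plane
#'   tail-bin counts, flags, and the tail residual norm.
#' @export
fit_tail_scale <- function(measured, model, mask, per_plane = TRUE,
                           min_tail_bins = 20L) {
  m <- if (inherits(model, "scatter_model")) model$sino$values else
    model$values
  y <- measured$values
  stopifnot(identical(dim(y), dim(m)),
            identical(dim(y), dim(mask$mask)))
  np <- dim(y)[3]
  msk <- mask$mask
  if (sum(m[msk]^2) == 0)
    stop("fit degenerate: scatter model is zero on all tail bins")
  global <- max(0, sum(y[msk] * m[msk]) / sum(m[msk]^2))
  n_tail <- integer(np)
  s <- rep(NA_real_, np)
  for (p in seq_len(np)) {
    mb <- msk[, , p]
    n_tail[p] <- sum(mb)
    if (n_tail[p] < min_tail_bins) next
    mm <- m[, , p][mb]
    den <- sum(mm^2)
    if (den == 0) next
    s[p] <- max(0, sum(y[, , p][mb] * mm) / den)
  }
  flagged <- is.na(s)
  if (all(flagged)) {
    s[] <- global
  } else if (any(flagged)) {
    ok <- which(!flagged)
    for (p in which(flagged)) s[p] <- s[ok[which.min(abs(ok - p))]]
  }
  if (!per_plane) s <- rep(global, np)
  sv <- array(rep(s, each = prod(dim(y)[1:2])), dim(y))
  resid <- sqrt(sum((y[msk] - sv[msk] * m[msk])^2))
  structure(list(s = s, global_scale = global, n_tail = n_tail,
                 flagged = flagged, per_plane = per_plane,
                 residual_norm = resid,
                 margin_voxels = mask$margin_voxels),
            class = "tail_fit")
}

#' Scaled scatter estimate for reconstruction
#'
#' Applies the fitted per-plane scale factors to the scatter model,
#' producing the additive scatter term used by OSEM. The ACF-margin enters
#' only through the fit; attenuation correction is untouched.
#'
#' @param measured Measured emission `sinogram` (congruence check).
#' @param model The `scatter_model` the fit was made with.
#' @param fit A [fit_tail_scale()] result.
#' @export
scatter_correct <- function(measured, model, fit) {
  m <- if (inherits(model, "scatter_model")) model$sino else model
  stopifnot(identical(dim(measured$values), dim(m$values)),
            length(fit$s) == dim(m$values)[3])
  sv <- array(rep(fit$s, each = prod(dim(m$values)[1:2])), dim(m$values))
  sinogram(sv * m$values, "scatter", m$geometry)
}
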