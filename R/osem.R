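#' Reconstruction settings
#'
#' @param iterations OSEM iterations (default 12).
#' @param subsets Ordered subsets (default 16); must divide the number of
#'   angles of the geometry used.
#' @param psf_fwhm_mm Optional isotropic Gaussian PSF applied radially in
#'   projection space (resolution modelling); `NULL` disables.
#' @param stop_epsilon Early-stop threshold on the relative image change
#'   per iteration; 0 disables.
#' @param nx Transverse reconstruction matrix size.
#' @param step_mm Ray sampling step of the system model; `NULL` uses one
#'   sample per voxel pitch (forward and back projection always share the
#'   step, so the pair stays exactly adjoint).
#' @export
recon_settings <- function(iterations = 12L, subsets = 16L,
                           psf_fwhm_mm = NULL, stop_epsilon = 0,
                           nx = 64L, step_mm = NULL) {
  stopifnot(iterations >= 1, subsets >= 1, stop_epsilon >= 0)
  structure(list(iterations = as.integer(iterations),
                 subsets = as.integer(subsets),
                 psf_fwhm_mm = psf_fwhm_mm, stop_epsilon = stop_epsilon,
                 nx = as.integer(nx), step_mm = step_mm),
            class = "recon_settings")
}

recon_step <- function(geometry, settings) {
  if (is.null(settings$step_mm)) 2 * geometry$fov_radius_mm / settings$nx
  else settings$step_mm
}

# subset processing order: bit-reversed when the count is a power of two
# (maximally separated angular coverage), natural otherwise; fixed for
# determinism
subset_order <- function(n) {
  if (n == 1) return(1L)
  if (bitwAnd(n, n - 1L) == 0L) {
    bits <- log2(n)
    vapply(0:(n - 1), function(i) {
      r <- 0L
      for (b in seq_len(bits)) {
        r <- bitwOr(bitwShiftL(r, 1L), bitwAnd(i, 1L))
        i <- bitwShiftR(i, 1L)
      }
      r + 1L
    }, integer(1))
  } else seq_len(n)
}

subset_angles <- function(geometry, subsets) {
  lapply(seq_len(subsets), function(s)
    seq(s, geometry$n_angles, by = subsets))
}

# radial Gaussian PSF in projection space; symmetric kernel with zero
# padding, hence self-adjoint
psf_blur <- function(arr, fwhm_mm, radial_pitch_mm) {
  sigma <- fwhm_mm / 2.354820045 / radial_pitch_mm
  if (sigma <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half):half / sigma)^2)
  k <- k / sum(k)
  nr <- dim(arr)[1]
  out <- arr
  flat <- matrix(arr, nrow = nr)
  padded <- rbind(matrix(0, half, ncol(flat)), flat,
                  matrix(0, half, ncol(flat)))
  conv <- apply(padded, 2, function(v)
    as.numeric(stats::filter(v, k, sides = 2)))
  array(conv[(half + 1):(half + nr), ], dim(arr))
}

#' Subset sensitivity image
#'
#' Back projection of `1/ACF` over a subset's angles; the voxelwise
#' normaliser of the OSEM update. Strictly positive inside the FOV support.
#'
#' @param geometry A `scanner_geometry`.
#' @param acf The ACF `sinogram`.
#' @param subset Integer angle indices; `NULL` means all angles.
#' @param nx Transverse matrix size.
#' @param step_mm Ray sampling step (must match the reconstruction's).
#' @export
sensitivity_image <- function(geometry, acf, subset = NULL, nx = 64,
                              step_mm = NULL) {
  stopifnot(inherits(acf, "sinogram"), acf$kind == "acf")
  inv <- 1 / acf$values
  if (is.null(subset))
    back_project(sinogram(inv, "trues", geometry), geometry, nx = nx,
                 step_mm = step_mm)
  else
    back_project(inv[, subset, , drop = FALSE], geometry, nx = nx,
                 angle_idx = subset, step_mm = step_mm)
}

#' Ordinary-Poisson OSEM reconstruction
#'
#' Multiplicative EM update per ordered subset for the forward model
#' `y = P(x)/ACF + scatter`, i.e. attenuation acts on the trues and the
#' scatter estimate is the already-scaled additive term in the measured
#' count domain (never attenuation-corrected). The update is
#' `x <- x / sens * P'[ (1/ACF) y / (P(x)/ACF + s) ]` over the subset's
#' angles; non-negativity is preserved at every step and the result is
#' deterministic given its inputs. Voxels with zero sensitivity are masked
#' from the update.
#'
#' @param emission Measured emission `sinogram` (counts).
#' @param acf ACF `sinogram` used for attenuation correction.
#' @param scatter Scaled additive scatter `sinogram`, or `NULL` for none.
#' @param geometry A `scanner_geometry`.
#' @param settings A [recon_settings()].
#' @param sensitivities Optional precomputed list of per-subset
#'   sensitivity `volume_image`s (reused across dynamic frames).
#' @param init Optional initial `volume_image`; default is ones inside the
#'   FOV cylinder.
#' @return The reconstructed activity `volume_image` (count-proportional
#'   units; divide by the acquisition count scale for kBq/ml).
#' @export
osem_reconstruct <- function(emission, acf, scatter, geometry,
                             settings = recon_settings(),
                             sensitivities = NULL, init = NULL) {
  stopifnot(inherits(emission, "sinogram"), inherits(acf, "sinogram"))
  if (geometry$n_angles %% settings$subsets != 0)
    stop("subsets must divide the number of angles")
  y <- emission$values
  if (sum(y) == 0) {
    warning("zero-count frame: returning a zero image")
    return(blank_volume(geometry, settings$nx))
  }
  svals <- if (is.null(scatter)) array(0, dim(y)) else scatter$values
  stopifnot(all(svals >= 0))
  inv_acf <- 1 / acf$values
  step <- recon_step(geometry, settings)
  subs <- subset_angles(geometry, settings$subsets)
  ord <- subset_order(settings$subsets)
  if (is.null(sensitivities))
    sensitivities <- lapply(subs, function(sb)
      sensitivity_image(geometry, acf, sb, nx = settings$nx,
                        step_mm = step))

  x <- blank_volume(geometry, settings$nx)
  if (is.null(init)) {
    co <- vol_coords(x)
    fovmask <- outer(co$x^2, co$y^2, "+") <= geometry$fov_radius_mm^2
    x$values <- array(as.double(rep(fovmask, dim(x$values)[3])),
                      dim(x$values))
  } else {
    stopifnot(identical(dim(init$values), dim(x$values)))
    x$values <- init$values
  }
  use_psf <- !is.null(settings$psf_fwhm_mm)

  for (it in seq_len(settings$iterations)) {
    x_prev <- x$values
    for (si in ord) {
      sb <- subs[[si]]
      fp <- forward_project(x, geometry, angle_idx = sb, step_mm = step)
      if (use_psf) fp <- psf_blur(fp, settings$psf_fwhm_mm,
                                  geometry$radial_pitch_mm)
      fp <- fp * inv_acf[, sb, , drop = FALSE] + svals[, sb, , drop = FALSE]
      ratio <- array(0, dim(fp))
      pos <- fp > 0
      ratio[pos] <- y[, sb, , drop = FALSE][pos] / fp[pos]
      ratio <- ratio * inv_acf[, sb, , drop = FALSE]
      if (use_psf) ratio <- psf_blur(ratio, settings$psf_fwhm_mm,
                                     geometry$radial_pitch_mm)
      bp <- back_project(ratio, geometry, nx = settings$nx, angle_idx = sb,
                         step_mm = step)
      sens <- sensitivities[[si]]$values
      upd <- array(0, dim(sens))
      ok <- sens > 1e-9 * max(sens)
      upd[ok] <- bp$values[ok] / sens[ok]
      x$values <- x$values * upd
    }
    if (settings$stop_epsilon > 0) {
      rel <- sum(abs(x$values - x_prev)) / max(sum(x_prev), 1e-12)
      if (rel < settings$stop_epsilon) break
    }
  }
  x$values <- pmax(x$values, 0)
  x
}

#' Reconstruct a dynamic acquisition with tail-fitted scatter
#'
#' The scatter pipeline used throughout the margin experiments:
#' \enumerate{
#'   \item a preliminary no-scatter OSEM reconstruction of the summed
#'     (all-frame) emission sinogram;
#'   \item a single scatter simulation (mode per `scatter_strategy`) from
#'     that preliminary image and the delivered (possibly misaligned)
#'     attenuation map — the scatter \emph{shape};
#'   \item per frame, a tail fit of the scale with the strategy's
#'     ACF-margin, then a final OSEM pass with the scaled scatter term.
#' }
#' One scatter-update outer loop is used; `n_outer = 2` repeats the shape
#' estimate from the summed corrected frames.
#'
#' @param acquisition A [simulate_acquisition()] result.
#' @param scatter_strategy List with `mode` (`"sss3d"`/`"sss2d"`),
#'   `margin` (radial bins) and `per_plane` (logical).
#' @param settings A [recon_settings()].
#' @param shared Optional precomputed [prepare_recon_shared()] result
#'   (lets several margins reuse the preliminary image, scatter shape and
#'   sensitivities).
#' @param sss_args Extra arguments passed to [sss_estimate()].
#' @param n_outer Scatter-update outer loops (default 1).
#' @return List with `frames` (activity `volume_image`s in kBq/ml),
#'   `tail_fits`, `scatter_model`, `prelim` and the strategy.
#' @export
reconstruct_dynamic <- function(acquisition,
                                scatter_strategy = list(mode = "sss3d",
                                                        margin = 0L,
                                                        per_plane = TRUE),
                                settings = recon_settings(),
                                shared = NULL, sss_args = list(),
                                n_outer = 1L) {
  acq <- acquisition
  if (is.null(shared))
    shared <- prepare_recon_shared(acq, settings,
                                   mode = scatter_strategy$mode, sss_args)
  stopifnot(identical(shared$mode, scatter_strategy$mode))
  g <- acq$geometry
  msk <- tail_mask(acq$acf, threshold = 1.03,
                   margin_voxels = scatter_strategy$margin)
  per_plane <- isTRUE(scatter_strategy$per_plane)
  out_frames <- vector("list", length(acq$frames))
  fits <- vector("list", length(acq$frames))
  model <- shared$scatter_model
  for (o in seq_len(max(1L, n_outer))) {
    for (f in seq_along(acq$frames)) {
      em <- acq$frames[[f]]$emission
      fit <- fit_tail_scale(em, model, msk, per_plane = per_plane)
      sc <- scatter_correct(em, model, fit)
      rec <- osem_reconstruct(em, acq$acf, sc, g, settings,
                              sensitivities = shared$sensitivities)
      rec$values <- rec$values / acq$frames[[f]]$count_scale
      out_frames[[f]] <- rec
      fits[[f]] <- fit
    }
    if (o < n_outer) {
      summed <- Reduce(`+`, lapply(out_frames, function(v) v$values))
      est <- out_frames[[1]]
      est$values <- pmax(summed, 0)
      model <- do.call(sss_estimate,
                       c(list(est, acq$mu_delivered, g,
                              mode = scatter_strategy$mode), sss_args))
    }
  }
  list(frames = out_frames, tail_fits = fits, scatter_model = model,
       prelim = shared$prelim, strategy = scatter_strategy)
}

#' Shared inputs for margin sweeps
#'
#' Preliminary no-scatter reconstruction of the summed emission data, the
#' SSS shape estimated from it, and the per-subset sensitivity images.
#' These do not depend on the ACF-margin, so a sweep over margins computes
#' them once.
#'
#' @param acquisition A [simulate_acquisition()] result.
#' @param settings A [recon_settings()].
#' @param mode SSS mode for the shape estimate.
#' @param sss_args Extra arguments for [sss_estimate()].
#' @export
prepare_recon_shared <- function(acquisition, settings = recon_settings(),
                                 mode = "sss3d", sss_args = list()) {
  acq <- acquisition
  g <- acq$geometry
  summed <- Reduce(`+`, lapply(acq$frames, function(fr) fr$emission$values))
  summed_sino <- sinogram(summed, "emission", g)
  subs <- subset_angles(g, settings$subsets)
  sens <- lapply(subs, function(sb)
    sensitivity_image(g, acq$acf, sb, nx = settings$nx,
                      step_mm = recon_step(g, settings)))
  prelim <- osem_reconstruct(summed_sino, acq$acf, NULL, g, settings,
                             sensitivities = sens)
  model <- do.call(sss_estimate,
                   c(list(prelim, acq$mu_delivered, g, mode = mode),
                     sss_args))
  list(prelim = prelim, scatter_model = model, sensitivities = sens,
       mode = mode)
}
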