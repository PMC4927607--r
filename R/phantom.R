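#' Head phantom specification
#'
#' A cylindrical head (constant transverse silhouette across the thin axial
#' FOV) with an outermost skin shell and optional spherical interior
#' regions. Region centres/radii are in mm relative to the FOV centre.
#'
#' @param head_radius_mm Outer head radius (mm).
#' @param skin_thickness_mm Thickness of the outermost skin shell (mm);
#'   0 disables the skin label.
#' @param regions Data frame with columns `name`, `cx`, `cy`, `cz`,
#'   `radius` (mm); may be `NULL`.
#' @param mu_tissue_per_mm Soft-tissue linear attenuation at 511 keV.
#' @param mu_bone_per_mm Bone attenuation (stored; the default phantom is
#'   soft tissue only).
#' @export
phantom_spec <- function(head_radius_mm = 88, skin_thickness_mm = 5,
                         regions = default_regions(head_radius_mm),
                         mu_tissue_per_mm = 0.0096,
                         mu_bone_per_mm = 0.0096) {
  stopifnot(head_radius_mm > 0, skin_thickness_mm >= 0,
            skin_thickness_mm < head_radius_mm)
  if (!is.null(regions) && nrow(regions) > 0) {
    inner <- head_radius_mm - skin_thickness_mm
    d <- sqrt(regions$cx^2 + regions$cy^2)
    if (any(d + regions$radius > inner))
      stop("phantom regions must lie inside the head (within the skin shell)")
  }
  structure(list(head_radius_mm = head_radius_mm,
                 skin_thickness_mm = skin_thickness_mm,
                 regions = regions,
                 mu_tissue_per_mm = mu_tissue_per_mm,
                 mu_bone_per_mm = mu_bone_per_mm),
            class = "phantom_spec")
}

#' Default interior regions
#'
#' A "lower brain" sphere placed low and posterior (mimicking the
#' cerebellum / parahippocampal placement next to the skin rim, where the
#' scatter-scaling artefact lives) and a central "deep nuclei" sphere
#' (striatum-like) in the middle of the head.
#' @param head_radius_mm Head radius the regions are scaled to.
#' @export
default_regions <- function(head_radius_mm = 88) {
  r <- head_radius_mm
  data.frame(
    name = c("lower_brain", "deep_nuclei"),
    cx = c(0, 0), cy = c(-0.52 * r, 0.1 * r), cz = c(-0.15 * r, 0),
    radius = c(0.24 * r, 0.22 * r))
}

#' Rasterise a head phantom
#'
#' Labels: 0 background, 1 brain bulk, 2 skin shell (if present), 3+
#' interior regions in `spec$regions` order. The attenuation map is uniform
#' soft tissue inside the head (skin included) and 0 outside. The activity
#' template is 1 inside the head, 0 outside. An optional axial activity
#' profile — a smooth off-centre step `w(z) = 1 + g tanh((z0 - z)/h)`,
#' hot towards the lowest slices — is returned as a congruent weight array
#' for the simulator. Its curvature matters: 2D single scatter simulation
#' fills oblique planes by axial-midpoint lookup, which is exact for
#' axially uniform (and, to first order, linearly varying) objects, so only
#' a nonlinear axial profile separates the 2D and 3D estimates.
#'
#' @param spec A [phantom_spec()].
#' @param geometry A `scanner_geometry` (sets the voxel grid).
#' @param nx Transverse matrix size.
#' @param axial_gradient Gradient strength `g` in `[0, 1)`; 0 disables.
#' @return List with `template`, `mu`, `labels` (`volume_image`s),
#'   `region_names` (label value -> name), `gradient` (array or `NULL`)
#'   and the `spec`.
#' @export
make_head_phantom <- function(spec, geometry, nx = 64, axial_gradient = 0) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(geometry, "scanner_geometry"),
            axial_gradient >= 0, axial_gradient < 1)
  if (spec$head_radius_mm >= geometry$fov_radius_mm)
    stop("head does not fit inside the FOV")
  tmpl <- blank_volume(geometry, nx, quantity = "label")
  co <- vol_coords(tmpl)
  d <- dim(tmpl$values)
  r2 <- outer(co$x^2, co$y^2, "+")
  head2d <- r2 <= spec$head_radius_mm^2
  inner2d <- r2 <= (spec$head_radius_mm - spec$skin_thickness_mm)^2

  lab <- array(0L, d)
  lab[rep(head2d, d[3])] <- 1L
  region_names <- c("1" = "brain")
  if (spec$skin_thickness_mm > 0) {
    skin2d <- head2d & !inner2d
    lab[rep(skin2d, d[3])] <- 2L
    region_names <- c(region_names, "2" = "skin")
  }
  if (!is.null(spec$regions) && nrow(spec$regions) > 0) {
    for (i in seq_len(nrow(spec$regions))) {
      rg <- spec$regions[i, ]
      dist2 <- outer(outer((co$x - rg$cx)^2, (co$y - rg$cy)^2, "+"),
                     (co$z - rg$cz)^2, "+")
      lval <- 2L + i
      lab[dist2 <= rg$radius^2] <- lval
      region_names <- c(region_names, stats::setNames(rg$name, lval))
    }
  }

  labels <- volume_image(lab, tmpl$voxel_pitch_mm, tmpl$slice_pitch_mm,
                         "label")
  mu <- volume_image(array(ifelse(lab > 0, spec$mu_tissue_per_mm, 0), d),
                     tmpl$voxel_pitch_mm, tmpl$slice_pitch_mm, "mu_per_mm")
  template <- volume_image(array(as.double(lab > 0), d),
                           tmpl$voxel_pitch_mm, tmpl$slice_pitch_mm,
                           "activity_kBq_per_ml")
  gradient <- NULL
  if (axial_gradient > 0) {
    z0 <- min(co$z) + 0.35 * diff(range(co$z))
    h <- 2 * tmpl$slice_pitch_mm
    zw <- 1 + axial_gradient * tanh((z0 - co$z) / h)
    gradient <- aperm(array(zw, c(d[3], d[1], d[2])), c(2, 3, 1))
  }
  list(template = template, mu = mu, labels = labels,
       region_names = region_names, gradient = gradient, spec = spec)
}

#' Tracer kinetic profiles
#'
#' Per-region compartmental parameters for three synthetic tracers spanning
#' the kinetic range of interest: a verapamil-like P-gp substrate (1T model,
#' low brain uptake, prominent skin-rim uptake), a raclopride-like D2
#' antagonist (reversible 2T model with elevated striatal k3/k4) and a
#' flumazenil-like GABA-A antagonist (1T, high K1). Units: K1 in
#' ml cm^-3 min^-1, k2..k4 in min^-1, Vb unitless.
#'
#' @param name One of `"verapamil_like"`, `"raclopride_like"`,
#'   `"flumazenil_like"`.
#' @export
tracer_profile <- function(name = c("verapamil_like", "raclopride_like",
                                    "flumazenil_like")) {
  name <- match.arg(name)
  p1 <- function(K1, k2, Vb = 0.05) list(K1 = K1, k2 = k2, Vb = Vb)
  p2 <- function(K1, k2, k3, k4, Vb = 0.05)
    list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, Vb = Vb)
  prof <- switch(name,
    verapamil_like = list(
      model = "1t", skin_activity_ratio = 3,
      regions = list(brain = p1(0.05, 0.05),
                     lower_brain = p1(0.055, 0.055),
                     deep_nuclei = p1(0.05, 0.05),
                     skin = p1(0.15, 0.05))),
    raclopride_like = list(
      model = "2t", skin_activity_ratio = 1,
      regions = list(brain = p2(0.10, 0.20, 0.02, 0.05),
                     lower_brain = p2(0.10, 0.20, 0.02, 0.05),
                     deep_nuclei = p2(0.10, 0.20, 0.15, 0.05),
                     skin = p2(0.05, 0.10, 0.01, 0.05))),
    flumazenil_like = list(
      model = "1t", skin_activity_ratio = 1,
      regions = list(brain = p1(0.35, 0.07),
                     lower_brain = p1(0.35, 0.07),
                     deep_nuclei = p1(0.30, 0.075),
                     skin = p1(0.06, 0.06))))
  for (rg in prof$regions) {
    stopifnot(all(unlist(rg[c("K1", "k2", "k3", "k4")], use.names = FALSE) > 0),
              rg$Vb >= 0, rg$Vb <= 0.2)
  }
  if (name != "verapamil_like" && prof$skin_activity_ratio > 1)
    stop("skin_activity_ratio > 1 is reserved for the verapamil-like profile")
  structure(c(list(name = name), prof), class = "tracer_profile")
}

#' Dynamic framing protocols
#'
#' The two printed 60-min framing schemes: 20 frames
#' (1x15, 3x5, 3x10, 2x30, 3x60, 2x150, 2x300, 4x600 s) for the
#' verapamil/raclopride protocol and 16 frames
#' (4x15, 4x60, 2x150, 2x300, 4x600 s) for the flumazenil protocol.
#'
#' @param protocol `"verapamil_raclopride"` or `"flumazenil"`.
#' @return A `frame_schedule` data frame with `start_s` and `duration_s`.
#' @export
make_frame_schedule <- function(protocol = c("verapamil_raclopride",
                                             "flumazenil")) {
  protocol <- match.arg(protocol)
  dur <- switch(protocol,
    verapamil_raclopride = rep(c(15, 5, 10, 30, 60, 150, 300, 600),
                               c(1, 3, 3, 2, 3, 2, 2, 4)),
    flumazenil = rep(c(15, 60, 150, 300, 600), c(4, 4, 2, 2, 4)))
  frame_schedule(dur)
}

#' Build a frame schedule from contiguous durations
#' @param durations_s Frame durations in seconds.
#' @export
frame_schedule <- function(durations_s) {
  stopifnot(all(durations_s > 0))
  out <- data.frame(start_s = cumsum(c(0, head(durations_s, -1))),
                    duration_s = durations_s)
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Synthetic plasma input function
#'
#' Feng-type curve: linear rise from 0 to the peak, then a weighted sum of
#' decaying exponentials, sampled on a 1-s grid. The whole-blood curve is
#' the plasma curve scaled by a constant blood-to-plasma ratio (no
#' metabolite modelling). Deterministic given its parameters; optional
#' multiplicative sampling noise is controlled by `noise_sd` + `seed`.
#'
#' @param peak_time_s Time of the peak (s).
#' @param peak_value Peak plasma activity (kBq/ml).
#' @param decay_constants Exponential decay rates (1/s), slowest last.
#' @param weights Mixture weights (normalised internally).
#' @param duration_s Curve length (s).
#' @param blood_ratio Whole-blood to plasma scale.
#' @param noise_sd Relative Gaussian sampling noise (0 = none).
#' @param seed Seed used only when `noise_sd > 0`.
#' @export
make_input_function <- function(peak_time_s = 30, peak_value = 40,
                                decay_constants = c(8e-3, 1.5e-3, 2.5e-4),
                                weights = c(0.6, 0.3, 0.1),
                                duration_s = 3600, blood_ratio = 0.8,
                                noise_sd = 0, seed = 1L) {
  stopifnot(peak_time_s > 0, peak_value >= 0, all(decay_constants > 0),
            all(weights > 0), duration_s > peak_time_s)
  t <- seq(0, duration_s, by = 1)
  w <- weights / sum(weights)
  cp <- ifelse(t <= peak_time_s, peak_value * t / peak_time_s,
               peak_value * colSums(w * exp(-outer(decay_constants,
                                                   t - peak_time_s))))
  if (noise_sd > 0)
    cp <- pmax(0, cp * (1 + withr::with_seed(as.integer(seed),
                                             rnorm(length(cp), 0, noise_sd))))
  structure(list(t_s = t, Cp = cp, Cb = blood_ratio * cp,
                 blood_ratio = blood_ratio),
            class = "input_function")
}
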