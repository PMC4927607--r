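# Shared study fixtures, built once per test run and cached. Three scales:
#  - mini:  generic unit-test geometry (fast projector checks)
#  - bench: 3-ring dynamic-reconstruction scale (margin sweeps)
#  - axial: 6-ring variant with real oblique tilts (2D-vs-3D)
#  - desk:  the full scatter-margin study scale (scale-recovery criteria)

.fx <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

mini_geometry <- function()
  build_geometry(n_rings = 4, ring_pitch_mm = 6, n_angles = 48,
                 n_radial = 80, radial_pitch_mm = 3.2,
                 max_ring_difference = 3)

bench_geometry <- function()
  build_geometry(n_rings = 3, ring_pitch_mm = 6, n_angles = 32,
                 n_radial = 112, radial_pitch_mm = 2.44,
                 max_ring_difference = 2)

axial_geometry <- function()
  build_geometry(n_rings = 6, ring_pitch_mm = 6, n_angles = 32,
                 n_radial = 112, radial_pitch_mm = 2.44,
                 max_ring_difference = 5)

sargs_bench <- list(scatter_grid_mm = 8, coarse_angles = 16,
                    coarse_radial = 28)
sargs_desk <- list(scatter_grid_mm = 10, coarse_angles = 20,
                   coarse_radial = 28)

bench_phantom <- function(gradient = 0, geometry = bench_geometry()) {
  spec <- phantom_spec(head_radius_mm = 70, skin_thickness_mm = 7,
                       regions = default_regions(70))
  make_head_phantom(spec, geometry, nx = 40, axial_gradient = gradient)
}

# static skin-rim activity on the bench phantom (verapamil-like late frame)
bench_static_activity <- function(ph = bench_phantom()) {
  av <- c("0" = 0, "1" = 1, "2" = 3, "3" = 1.1, "4" = 1)
  volume_image(array(av[as.character(ph$labels$values)],
                     dim(ph$labels$values)),
               ph$labels$voxel_pitch_mm, ph$labels$slice_pitch_mm,
               "activity_kBq_per_ml")
}

# single-frame skin-rim acquisition at the desk scale plus the tail-fit
# scale ladder over the full margin range (used by the scale-recovery and
# artefact criteria)
desk_scale_ladder <- function(shift_mm) {
  g <- desk_geometry()
  ph <- fx("desk_phantom", {
    make_head_phantom(phantom_spec(head_radius_mm = 88,
                                   skin_thickness_mm = 5),
                      g, nx = 64)
  })
  acq <- simulate_acquisition(ph, tracer_profile("verapamil_like"),
                              frame_schedule(3600), make_input_function(),
                              g, mismatch = rigid_shift(shift_mm, 0, 0),
                              scatter_fraction = 0.35, counts_total = 2e6,
                              seed = 11, sss_args = sargs_desk)
  fr <- acq$frames[[1]]
  model <- do.call(sss_estimate,
                   c(list(fr$truth, acq$mu_delivered, g, mode = "sss3d"),
                     sargs_desk))
  margins <- seq(0, 14, by = 2)
  ratios <- vapply(margins, function(m) {
    ft <- fit_tail_scale(fr$emission, model,
                         tail_mask(acq$acf, 1.03, m))
    ft$global_scale / fr$s_star
  }, numeric(1))
  list(acq = acq, model = model,
       ratios = stats::setNames(ratios, margins))
}

fx_desk_aligned <- function() fx("desk_aligned", desk_scale_ladder(0))
fx_desk_shifted <- function() fx("desk_shifted", desk_scale_ladder(5))

# 2D vs 3D scatter models on the 6-ring geometry, axially uniform and
# step-profiled phantoms
fx_mode_models <- function() fx("mode_models", {
  g <- axial_geometry()
  out <- lapply(c(uniform = 0, gradient = 0.6), function(gr) {
    ph <- bench_phantom(gradient = gr, geometry = g)
    act <- ph$template
    if (!is.null(ph$gradient)) act$values <- act$values * ph$gradient
    list(m3 = do.call(sss_estimate, c(list(act, ph$mu, g, mode = "sss3d"),
                                      sargs_bench)),
         m2 = do.call(sss_estimate, c(list(act, ph$mu, g, mode = "sss2d"),
                                      sargs_bench)))
  })
  out
})

bench_sweep_config <- function(mismatch_mm, margins, n_outer, seed = 1L) {
  experiment_config(tracer = "verapamil_like", n_subjects = 1,
                    mismatch_mm = mismatch_mm, margins = margins,
                    counts_total = 2e7, scatter_fraction = 0.35,
                    seed = seed, geometry = bench_geometry(), nx = 40L,
                    settings = recon_settings(nx = 40L),
                    phantom_args = list(head_radius_mm = 70,
                                        skin_thickness_mm = 7,
                                        regions = default_regions(70)),
                    sss_args = sargs_bench, n_outer = n_outer)
}

fx_sweep_flat <- function() fx("sweep_flat", {
  run_margin_sweep(bench_sweep_config(0, c(0, 4, 8), n_outer = 1L))
})

fx_sweep_mismatch <- function() fx("sweep_mismatch", {
  run_margin_sweep(bench_sweep_config(5, c(0, 2, 8, 12), n_outer = 2L))
})

fx_mode_comparison <- function() fx("mode_comparison", {
  cfg <- experiment_config(tracer = "verapamil_like", n_subjects = 1,
                           mismatch_mm = 0, counts_total = 2e7,
                           scatter_fraction = 0.35, seed = 9L,
                           geometry = axial_geometry(), nx = 40L,
                           settings = recon_settings(nx = 40L),
                           phantom_args = list(head_radius_mm = 70,
                                               skin_thickness_mm = 7,
                                               regions = default_regions(70)),
                           sss_args = sargs_bench, n_outer = 1L)
  run_sss_mode_comparison(cfg, margin = 8L, axial_gradient = 0.6)
})

# relative RMS between two arrays over their mutually significant bins
rel_rms <- function(a, b, floor_frac = 0.05) {
  m <- (a + b) / 2
  ok <- m > floor_frac * max(m)
  sqrt(mean(((a[ok] - b[ok]) / m[ok])^2))
}
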