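test_that("head phantom rasterisation matches its specification", {
  # 3-mm voxels: single-ring geometry just to set the grid
  g <- build_geometry(n_rings = 2, ring_pitch_mm = 6, n_angles = 8,
                      n_radial = 64, radial_pitch_mm = 3,
                      max_ring_difference = 1)
  # no regions, no skin: two labels only
  ph0 <- make_head_phantom(phantom_spec(head_radius_mm = 60,
                                        skin_thickness_mm = 0,
                                        regions = NULL), g, nx = 64)
  expect_setequal(unique(as.vector(ph0$labels$values)), c(0L, 1L))

  # head mask area within 3% of pi r^2 per slice
  area <- sum(ph0$labels$values[, , 1] > 0) * ph0$labels$voxel_pitch_mm^2
  expect_lt(abs(area - pi * 60^2) / (pi * 60^2), 0.03)

  # 4-mm skin at 3-mm pitch forms a closed ring 1-2 voxels wide
  ph1 <- make_head_phantom(phantom_spec(head_radius_mm = 60,
                                        skin_thickness_mm = 4,
                                        regions = NULL), g, nx = 64)
  sl <- ph1$labels$values[, , 1]
  skin <- which(sl == 2L, arr.ind = TRUE)
  ctr <- (dim(sl)[1] + 1) / 2
  ang <- atan2(skin[, 2] - ctr, skin[, 1] - ctr)
  # closed: every 10-degree sector contains skin voxels
  expect_true(all(table(cut(ang, seq(-pi, pi, by = pi / 18))) > 0))
  # width 1-2 voxels: area between 1x and 2.5x the ideal 4-mm annulus
  ann <- pi * (60^2 - 56^2)
  expect_gt(nrow(skin) * 9, ann * 0.7)
  expect_lt(nrow(skin) * 9, ann * 2.5)

  # mu: uniform soft tissue inside, zero outside
  expect_setequal(unique(as.vector(ph1$mu$values)), c(0, 0.0096))
  expect_true(all((ph1$mu$values > 0) == (ph1$labels$values > 0)))

  # region outside the head is rejected
  bad <- data.frame(name = "x", cx = 55, cy = 0, cz = 0, radius = 20)
  expect_error(phantom_spec(head_radius_mm = 60, regions = bad), "inside")
})

test_that("framing protocols match the printed schedules", {
  s20 <- make_frame_schedule("verapamil_raclopride")
  s16 <- make_frame_schedule("flumazenil")
  expect_equal(nrow(s20), 20L)
  expect_equal(nrow(s16), 16L)
  expect_equal(sum(s20$duration_s), 3600)
  expect_equal(sum(s16$duration_s), 3600)
  # contiguous and non-overlapping
  expect_equal(s20$start_s,
               cumsum(c(0, utils::head(s20$duration_s, -1))))
  expect_error(make_frame_schedule("pib"))
})

test_that("input function peaks on time and decays monotonically", {
  expect_equal(max(make_input_function(peak_value = 0)$Cp), 0)
  inp <- make_input_function(peak_time_s = 30, peak_value = 40)
  expect_equal(inp$Cp[1], 0)
  expect_lt(abs(inp$t_s[which.max(inp$Cp)] - 30), 1.5)
  # single early peak; tail strictly non-increasing
  expect_true(all(diff(inp$Cp[inp$t_s > 30]) <= 1e-12))
  expect_true(all(inp$Cp >= 0))
  expect_equal(inp$Cb, 0.8 * inp$Cp)
})

test_that("tracer profiles respect the skin-uptake and Vb constraints", {
  for (nm in c("verapamil_like", "raclopride_like", "flumazenil_like")) {
    tp <- tracer_profile(nm)
    for (rg in tp$regions) {
      expect_true(rg$Vb >= 0 && rg$Vb <= 0.2)
      expect_true(all(unlist(rg[c("K1", "k2")]) > 0))
    }
    if (nm != "verapamil_like")
      expect_lte(tp$skin_activity_ratio, 1)
  }
  expect_gt(tracer_profile("verapamil_like")$skin_activity_ratio, 1)
})

test_that("simulated acquisitions hold their scatter fraction and seeds", {
  g <- bench_geometry()
  ph <- bench_phantom()
  sched <- frame_schedule(c(600, 3000))
  inp <- make_input_function()
  acq <- simulate_acquisition(ph, tracer_profile("verapamil_like"), sched,
                              inp, g, scatter_fraction = 0.5,
                              counts_total = 1e6, seed = 3,
                              sss_args = sargs_bench)
  for (fr in acq$frames) {
    expect_equal(fr$expected_scatter / fr$expected_total, 0.5,
                 tolerance = 1e-9)
    # realised counts near expectation
    expect_lt(abs(sum(fr$emission$values) - fr$expected_total) /
                fr$expected_total, 0.02)
  }
  acq2 <- simulate_acquisition(ph, tracer_profile("verapamil_like"), sched,
                               inp, g, scatter_fraction = 0.5,
                               counts_total = 1e6, seed = 3,
                               sss_args = sargs_bench)
  expect_identical(acq$frames[[2]]$emission$values,
                   acq2$frames[[2]]$emission$values)

  # zero scatter, zero mismatch: emission is Poisson of the trues only
  acq0 <- simulate_acquisition(ph, tracer_profile("verapamil_like"), sched,
                               inp, g, scatter_fraction = 0,
                               counts_total = 1e6, seed = 3)
  expect_equal(acq0$frames[[1]]$expected_scatter, 0)
  expect_equal(acq0$acf$values, acq0$acf_true$values)
})

test_that("ground-truth TACs are the kinetic model's curves", {
  g <- bench_geometry()
  ph <- bench_phantom()
  sched <- make_frame_schedule("verapamil_raclopride")
  inp <- make_input_function()
  tr <- tracer_profile("verapamil_like")
  acq <- simulate_acquisition(ph, tr, sched, inp, g, scatter_fraction = 0,
                              counts_total = 1e6, seed = 1)
  ref <- model_tac(tr$regions$skin, tr$model, inp, sched)
  expect_equal(acq$region_tacs[["2"]]$value, ref$value)

  # frame averages agree with independent trapezoid integration within 1%
  curve <- acfmargin:::model_curve(tr$regions$brain, "1t", inp)
  for (f in c(3, 10, 20)) {
    a <- sched$start_s[f]; b <- a + sched$duration_s[f]
    idx <- which(inp$t_s >= a & inp$t_s <= b)
    trap <- sum(diff(inp$t_s[idx]) *
                  (utils::head(curve[idx], -1) + utils::tail(curve[idx], -1)) / 2) /
      (b - a)
    expect_equal(acq$region_tacs[["1"]]$value[f], trap, tolerance = 0.01)
  }
})

test_that("only the verapamil-like profile builds a hot skin rim", {
  sched <- make_frame_schedule("verapamil_raclopride")
  inp <- make_input_function()
  late <- 17:20
  for (nm in c("verapamil_like", "raclopride_like", "flumazenil_like")) {
    tr <- tracer_profile(nm)
    skin <- model_tac(tr$regions$skin, tr$model, inp, sched)$value
    brain <- model_tac(tr$regions$brain, tr$model, inp, sched)$value
    ratio <- mean(skin[late]) / mean(brain[late])
    if (nm == "verapamil_like") expect_gt(ratio, 2) else expect_lt(ratio, 2)
  }
})

test_that("acquisitions round-trip to disk with a complete manifest", {
  g <- bench_geometry()
  ph <- bench_phantom()
  acq <- simulate_acquisition(ph, tracer_profile("verapamil_like"),
                              frame_schedule(c(1800, 1800)),
                              make_input_function(), g,
                              scatter_fraction = 0, counts_total = 1e5,
                              seed = 2)
  dir <- file.path(tempdir(), "acq_test")
  save_acquisition(acq, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$n_frames, 2L)
  expect_equal(man$seed, 2L)
  em <- read_sinogram(file.path(dir, man$emission_files[1]))
  expect_identical(em$values, acq$frames[[1]]$emission$values)
})
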