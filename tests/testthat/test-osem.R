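# shared noiseless bench problem: skin-rim phantom, aligned ACF
bench_recon_problem <- function() fx("recon_problem", {
  g <- bench_geometry()
  ph <- bench_phantom()
  x <- bench_static_activity(ph)
  acf <- fx("bench_acf", compute_acf(ph$mu, g))
  y <- sinogram(forward_project(x, g)$values / acf$values, "emission", g)
  list(g = g, ph = ph, x = x, acf = acf, y = y)
})

test_that("sensitivity images behave like back projections of 1/ACF", {
  pr <- bench_recon_problem()
  g <- pr$g
  ones_acf <- sinogram(array(1, dim(pr$acf$values)), "acf", g)
  s1 <- sensitivity_image(g, ones_acf, nx = 40)
  b1 <- back_project(sinogram(array(1, dim(pr$acf$values)), "trues", g),
                     g, nx = 40)
  expect_equal(s1$values, b1$values, tolerance = 1e-12)

  # attenuation reduces sensitivity everywhere it matters
  s_att <- sensitivity_image(g, pr$acf, nx = 40)
  inside <- pr$ph$labels$values > 0
  expect_true(all(s_att$values[inside] < s1$values[inside]))

  # subset sensitivities sum to the full one
  subs <- acfmargin:::subset_angles(g, 16L)
  parts <- lapply(subs, function(sb) sensitivity_image(g, pr$acf, sb,
                                                       nx = 40))
  total <- Reduce(`+`, lapply(parts, `[[`, "values"))
  expect_equal(total, s_att$values, tolerance = 1e-10)
})

test_that("MLEM conserves modelled counts at every iteration", {
  pr <- bench_recon_problem()
  total_y <- sum(pr$y$values)
  for (it in 1:3) {
    st <- recon_settings(iterations = it, subsets = 1L, nx = 40)
    rec <- osem_reconstruct(pr$y, pr$acf, NULL, pr$g, st)
    fp <- forward_project(rec, pr$g,
                          step_mm = acfmargin:::recon_step(pr$g, st))$values /
      pr$acf$values
    expect_lt(abs(sum(fp) - total_y) / total_y, 1e-6)
  }
})

test_that("a data-consistent image is an MLEM fixed point", {
  pr <- bench_recon_problem()
  g <- pr$g
  st <- recon_settings(iterations = 1L, subsets = 1L, nx = 40)
  # smooth positive image supported in the FOV cylinder
  x0 <- blank_volume(g, 40)
  co <- acfmargin:::vol_coords(x0)
  r2 <- outer(co$x^2, co$y^2, "+")
  x0$values <- array(rep(exp(-r2 / 80^2), dim(x0$values)[3]),
                     dim(x0$values))
  y0 <- forward_project(x0, g,
                        step_mm = acfmargin:::recon_step(g, st))$values /
    pr$acf$values
  rec <- osem_reconstruct(sinogram(y0, "emission", g), pr$acf, NULL, g, st,
                          init = x0)
  supp <- x0$values > 1e-3 * max(x0$values)
  expect_lt(max(abs(rec$values[supp] - x0$values[supp]) / x0$values[supp]),
            1e-6)
})

test_that("12 iterations x 16 subsets reconstruct the phantom within 5%", {
  pr <- bench_recon_problem()
  rec <- fx("recon_12x16", {
    osem_reconstruct(pr$y, pr$acf, NULL, pr$g,
                     recon_settings(iterations = 12, subsets = 16, nx = 40))
  })
  expect_true(all(rec$values >= 0))
  mask <- pr$ph$labels$values > 0
  nrmse <- sqrt(mean((rec$values[mask] - pr$x$values[mask])^2)) /
    mean(pr$x$values[mask])
  expect_lt(nrmse, 0.05)
})

test_that("an overestimated scatter term biases low-uptake regions low", {
  pr <- bench_recon_problem()
  g <- pr$g
  # true additive scatter: smooth, 35% of counts
  model <- fx("bench_model_uniform", {
    do.call(sss_estimate, c(list(bench_static_activity(pr$ph), pr$ph$mu, g),
                            sargs_bench))
  })
  sc_true <- model$sino$values *
    (0.35 / 0.65 * sum(pr$y$values) / sum(model$sino$values))
  y <- sinogram(pr$y$values + sc_true, "emission", g)
  st <- recon_settings(iterations = 12, subsets = 16, nx = 40)
  rec_ok <- osem_reconstruct(y, pr$acf, sinogram(sc_true, "scatter", g),
                             g, st)
  rec_over <- osem_reconstruct(y, pr$acf,
                               sinogram(1.5 * sc_true, "scatter", g), g, st)
  central <- pr$ph$labels$values == 4L   # deep, low-uptake VOI
  expect_lt(mean(rec_over$values[central]), mean(rec_ok$values[central]))
  expect_lt(mean(rec_over$values[central]), mean(pr$x$values[central]))
})

test_that("degenerate reconstruction inputs are handled", {
  pr <- bench_recon_problem()
  zero <- sinogram(array(0, dim(pr$y$values)), "emission", pr$g)
  expect_warning(rec <- osem_reconstruct(zero, pr$acf, NULL, pr$g,
                                         recon_settings(nx = 40)),
                 "zero-count")
  expect_equal(sum(rec$values), 0)
  expect_error(osem_reconstruct(pr$y, pr$acf, NULL, pr$g,
                                recon_settings(subsets = 7L, nx = 40)),
               "divide")
})

test_that("projection-space PSF modelling sharpens recovery when enabled", {
  pr <- bench_recon_problem()
  # data blurred radially (4 mm FWHM), reconstruct with and without PSF
  blurred <- acfmargin:::psf_blur(pr$y$values, 4, pr$g$radial_pitch_mm)
  yb <- sinogram(blurred, "emission", pr$g)
  st0 <- recon_settings(iterations = 6, subsets = 16, nx = 40)
  stp <- recon_settings(iterations = 6, subsets = 16, nx = 40,
                        psf_fwhm_mm = 4)
  r0 <- osem_reconstruct(yb, pr$acf, NULL, pr$g, st0)
  rp <- osem_reconstruct(yb, pr$acf, NULL, pr$g, stp)
  mask <- pr$ph$labels$values > 0
  err0 <- sqrt(mean((r0$values[mask] - pr$x$values[mask])^2))
  errp <- sqrt(mean((rp$values[mask] - pr$x$values[mask])^2))
  expect_lt(errp, err0)
})
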