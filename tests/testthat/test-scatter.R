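test_that("Klein-Nishina endpoints and monotonicity", {
  expect_equal(klein_nishina(0), 1)
  expect_equal(klein_nishina(pi), 5 / 27, tolerance = 1e-12)
  th <- seq(0, pi / 2, length.out = 200)
  expect_true(all(diff(klein_nishina(th)) < 0))
  expect_true(all(klein_nishina(seq(0, pi, length.out = 100)) > 0))
  expect_error(klein_nishina(-0.1))
  expect_error(klein_nishina(3.2))
})

test_that("scattered photon energy follows 511/(2 - cos theta)", {
  expect_equal(scattered_energy(0), 511)
  expect_equal(scattered_energy(pi / 2), 255.5)
  expect_equal(scattered_energy(pi), 511 / 3, tolerance = 1e-12)
  expect_error(scattered_energy(4))
  # total cross-section grows as energy drops (mu scaling > 1 below 511)
  expect_equal(kn_total_cross_section(511) / kn_total_cross_section(511), 1)
  e <- c(170, 255, 350, 511)
  expect_true(all(diff(kn_total_cross_section(e)) < 0))
})

test_that("SSS handles degenerate inputs and stays smooth", {
  g <- bench_geometry()
  ph <- bench_phantom()
  zero_act <- ph$template
  zero_act$values[] <- 0
  m <- do.call(sss_estimate, c(list(zero_act, ph$mu, g), sargs_bench))
  expect_equal(sum(m$sino$values), 0)

  empty_mu <- ph$mu
  empty_mu$values[] <- 0
  expect_error(do.call(sss_estimate,
                       c(list(ph$template, empty_mu, g), sargs_bench)),
               "degenerate")

  m1 <- fx("bench_model_uniform", {
    do.call(sss_estimate, c(list(bench_static_activity(ph), ph$mu, g),
                            sargs_bench))
  })
  # smoothness: no bin above 4x the mean of its 8 in-plane neighbours
  v <- m1$sino$values
  worst <- 0
  for (p in seq_len(dim(v)[3])) {
    sl <- v[, , p]
    if (max(sl) == 0) next
    n <- nrow(sl); a <- ncol(sl)
    nb <- (rbind(0, sl[-n, ]) + rbind(sl[-1, ], 0) +
             cbind(0, sl[, -a]) + cbind(sl[, -1], 0) +
             rbind(0, cbind(0, sl[-n, -a])) + rbind(0, cbind(sl[-n, -1], 0)) +
             rbind(cbind(0, sl[-1, -a]), 0) + rbind(cbind(sl[-1, -1], 0), 0)) / 8
    sig <- sl > 0.01 * max(sl)
    inner <- sig; inner[c(1, n), ] <- FALSE; inner[, c(1, a)] <- FALSE
    if (any(inner)) worst <- max(worst, max(sl[inner] / nb[inner]))
  }
  expect_lt(worst, 4)
})

test_that("halving the scatter-point grid changes the estimate by < 3% RMS", {
  g <- bench_geometry()
  ph <- bench_phantom()
  act <- bench_static_activity(ph)
  m8 <- fx("bench_model_grid8", {
    sss_estimate(act, ph$mu, g, scatter_grid_mm = 8, coarse_angles = 16,
                 coarse_radial = 28)
  })
  m4 <- sss_estimate(act, ph$mu, g, scatter_grid_mm = 4, coarse_angles = 16,
                     coarse_radial = 28)
  expect_lt(rel_rms(m8$sino$values, m4$sino$values), 0.03)
})

test_that("tail mask thresholds and dilates exactly as specified", {
  g1 <- build_geometry(n_rings = 1, ring_pitch_mm = 2, n_angles = 1,
                       n_radial = 7, radial_pitch_mm = 2,
                       max_ring_difference = 0)
  acf <- sinogram(array(c(1, 1, 1.5, 2, 1.5, 1, 1), c(7, 1, 1)), "acf", g1)
  expect_equal(which(tail_mask(acf, 1.03, 0)$mask), c(1L, 2L, 6L, 7L))
  expect_equal(which(tail_mask(acf, 1.03, 1)$mask), c(1L, 7L))
  expect_error(tail_mask(acf, 1.03, 4), "margin")

  ones <- sinogram(array(1, c(7, 1, 1)), "acf", g1)
  expect_true(all(tail_mask(ones, 1.03, 2)$mask))
})

test_that("tail fit recovers exact and noisy scales, clamps at zero", {
  g <- bench_geometry()
  ph <- bench_phantom()
  model <- fx("bench_model_uniform", {
    do.call(sss_estimate, c(list(bench_static_activity(ph), ph$mu, g),
                            sargs_bench))
  })
  acf <- fx("bench_acf", compute_acf(ph$mu, g))
  msk <- tail_mask(acf, 1.03, 0)

  twice <- sinogram(2 * model$sino$values, "emission", g)
  ft <- fit_tail_scale(twice, model, msk)
  expect_equal(ft$s, rep(2, g$n_planes), tolerance = 1e-12)
  expect_equal(ft$global_scale, 2, tolerance = 1e-12)

  # brute-force scan oracle on one plane: the closed form minimises the
  # tail residual over a dense grid of candidate scales
  p <- which(g$plane_table$segment == 0)[2]
  mb <- msk$mask[, , p]; mm <- model$sino$values[, , p][mb]
  set.seed(5)
  yy <- 1.7 * mm + rnorm(length(mm), 0, 0.1 * max(mm))
  scan <- seq(0, 4, by = 1e-3)
  sse <- vapply(scan, function(s) sum((yy - s * mm)^2), numeric(1))
  closed <- max(0, sum(yy * mm) / sum(mm^2))
  expect_lt(abs(scan[which.min(sse)] - closed), 1e-3)

  # Poisson-noisy recovery within 2%
  lam <- 5e6 * model$sino$values / sum(model$sino$values)
  noisy <- sinogram(array(withr::with_seed(7, rpois(length(lam), lam)),
                          dim(lam)), "emission", g)
  ftn <- fit_tail_scale(noisy, sinogram(lam, "scatter", g), msk)
  expect_lt(abs(ftn$global_scale - 1), 0.02)

  # anti-correlated data clamp at zero
  neg <- sinogram(pmax(max(model$sino$values) - model$sino$values, 0),
                  "emission", g)
  expect_true(all(fit_tail_scale(neg, model, msk, per_plane = FALSE)$s >= 0))

  # degenerate: model identically zero on the tails
  zero_model <- sinogram(0 * model$sino$values, "scatter", g)
  expect_error(fit_tail_scale(twice, zero_model, msk), "degenerate")
})

test_that("planes with thin tails are flagged and filled from neighbours", {
  g <- bench_geometry()
  ph <- bench_phantom()
  model <- fx("bench_model_uniform", {
    do.call(sss_estimate, c(list(bench_static_activity(ph), ph$mu, g),
                            sargs_bench))
  })
  acf <- fx("bench_acf", compute_acf(ph$mu, g))
  msk <- tail_mask(acf, 1.03, 0)
  # starve one plane of tail bins
  msk$mask[, , 3] <- FALSE
  y <- sinogram(1.5 * model$sino$values, "emission", g)
  ft <- fit_tail_scale(y, model, msk)
  expect_true(ft$flagged[3])
  expect_false(any(ft$flagged[-3]))
  expect_equal(ft$s[3], ft$s[which(!ft$flagged)[
    which.min(abs(which(!ft$flagged) - 3))]])
})

test_that("scatter_correct scales the model and nothing else", {
  g <- bench_geometry()
  ph <- bench_phantom()
  model <- fx("bench_model_uniform", {
    do.call(sss_estimate, c(list(bench_static_activity(ph), ph$mu, g),
                            sargs_bench))
  })
  acf <- fx("bench_acf", compute_acf(ph$mu, g))
  msk <- tail_mask(acf, 1.03, 0)
  y <- sinogram(2 * model$sino$values, "emission", g)
  ft <- fit_tail_scale(y, model, msk)

  zero_fit <- ft; zero_fit$s[] <- 0
  expect_equal(sum(scatter_correct(y, model, zero_fit)$values), 0)

  # doubling the model and halving the scales leaves the product unchanged
  m2 <- model; m2$sino$values <- 2 * model$sino$values
  half <- ft; half$s <- ft$s / 2
  expect_equal(scatter_correct(y, m2, half)$values,
               scatter_correct(y, model, ft)$values, tolerance = 1e-12)

  # valid fits do not out-count the measurement
  expect_lte(sum(scatter_correct(y, model, ft)$values),
             sum(y$values) * (1 + 1e-9))
})

test_that("2D and 3D SSS collapse for axially uniform objects and split on a step", {
  mm <- fx_mode_models()
  norm <- function(a) a / sum(a)
  g <- axial_geometry()
  obl <- which(abs(g$plane_table$segment) > 0)
  r_unif <- rel_rms(norm(mm$uniform$m2$sino$values),
                    norm(mm$uniform$m3$sino$values))
  r_grad_obl <- rel_rms(norm(mm$gradient$m2$sino$values)[, , obl],
                        norm(mm$gradient$m3$sino$values)[, , obl])
  r_unif_obl <- rel_rms(norm(mm$uniform$m2$sino$values)[, , obl],
                        norm(mm$uniform$m3$sino$values)[, , obl])
  expect_lt(r_unif, 0.05)
  expect_gt(r_grad_obl, r_unif_obl)
})
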