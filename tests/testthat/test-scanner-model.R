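test_that("geometry construction enumerates segments and rejects bad configs", {
  g1 <- build_geometry(n_rings = 1, ring_pitch_mm = 2, n_angles = 4,
                       n_radial = 5, radial_pitch_mm = 2,
                       max_ring_difference = 0)
  expect_equal(g1$n_planes, 1L)
  expect_equal(unique(g1$plane_table$segment), 0L)
  expect_equal(dim(sinogram(array(0, c(5, 4, 1)), "emission", g1)$values),
               c(5L, 4L, 1L))

  # ring pairs for 4 rings, |diff| <= 3: 4 + 3 + 3 + 2 + 2 + 1 + 1 = 16
  g2 <- build_geometry(n_rings = 4, ring_pitch_mm = 2, n_angles = 8,
                       n_radial = 16, radial_pitch_mm = 2,
                       max_ring_difference = 3)
  expect_equal(length(unique(g2$plane_table$segment)), 7L)
  expect_equal(g2$n_planes, 16L)
  # every (segment, plane) is one ordered ring pair, no duplicates
  expect_equal(anyDuplicated(g2$plane_table[, c("ring_a", "ring_b")]), 0L)

  expect_error(build_geometry(n_rings = 4, max_ring_difference = 4),
               "max_ring_difference")
  expect_error(build_geometry(n_rings = 2, n_radial = 8,
                              radial_pitch_mm = 1, fov_radius_mm = 100),
               "FOV")
})

test_that("forward projection matches analytic chord lengths on a disc", {
  g <- mini_geometry()
  vol <- blank_volume(g, nx = 48)
  co <- acfmargin:::vol_coords(vol)
  r <- 50
  disc <- array(as.double(rep(outer(co$x^2, co$y^2, "+") <= r^2,
                              dim(vol$values)[3])), dim(vol$values))
  v <- volume_image(disc, vol$voxel_pitch_mm, vol$slice_pitch_mm)

  expect_equal(forward_project(volume_image(0 * disc, vol$voxel_pitch_mm,
                                            vol$slice_pitch_mm), g)$values,
               array(0, c(g$n_radial, g$n_angles, g$n_planes)))

  fp <- forward_project(v, g)
  p0 <- which(g$plane_table$segment == 0)[2]
  chord <- ifelse(abs(g$radials) < r,
                  2 * sqrt(pmax(r^2 - g$radials^2, 0)), 0)
  for (a in c(1, 13, 30)) {
    prof <- fp$values[, a, p0]
    # rasterisation blurs the edge by about one voxel
    expect_lt(max(abs(prof - chord)),
              2 * (vol$voxel_pitch_mm + g$radial_pitch_mm))
  }
  # central bin equals the diameter within a voxel
  ctr <- which.min(abs(g$radials))
  expect_lt(abs(fp$values[ctr, 1, p0] - 2 * r), 2 * vol$voxel_pitch_mm)
})

test_that("a hot voxel projects only onto LORs passing near it", {
  g <- mini_geometry()
  vol <- blank_volume(g, nx = 48)
  d <- dim(vol$values)
  ix <- c(30, 20, 3)   # off-centre voxel on a ring plane (z = -3 mm)
  vol$values[ix[1], ix[2], ix[3]] <- 1
  co <- acfmargin:::vol_coords(vol)
  pos <- c(co$x[ix[1]], co$y[ix[2]], co$z[ix[3]])
  fp <- forward_project(vol, g)
  p0 <- which(g$plane_table$segment == 0 &
                abs(g$plane_table$z_a - pos[3]) < 1e-9)[1]
  expect_gt(sum(fp$values[, , p0]), 0)
  nz <- which(fp$values[, , p0] > 0, arr.ind = TRUE)
  # distance from each hit LOR to the voxel, in the transverse plane
  s <- g$radials[nz[, 1]]
  phi <- g$angles[nz[, 2]]
  dist <- abs(pos[1] * (-sin(phi)) + pos[2] * cos(phi) - s)
  expect_lt(max(dist), 2 * vol$voxel_pitch_mm)
})

test_that("projector is linear and back projection is its exact adjoint", {
  g <- mini_geometry()
  vol <- blank_volume(g, nx = 32)
  d <- dim(vol$values)
  set.seed(4)
  x1 <- vol; x1$values <- array(runif(prod(d)), d)
  x2 <- vol; x2$values <- array(runif(prod(d)), d)
  lin <- vol; lin$values <- 2 * x1$values + 3 * x2$values
  expect_equal(forward_project(lin, g)$values,
               2 * forward_project(x1, g)$values +
                 3 * forward_project(x2, g)$values, tolerance = 1e-12)

  y <- array(runif(g$n_radial * g$n_angles * g$n_planes),
             c(g$n_radial, g$n_angles, g$n_planes))
  lhs <- sum(forward_project(x1, g)$values * y)
  rhs <- sum(x1$values *
               back_project(sinogram(y, "trues", g), g, nx = 32)$values)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("ACF sinogram follows exp(mu * path) and its identities", {
  g <- mini_geometry()
  vol <- blank_volume(g, nx = 48, quantity = "mu_per_mm")
  co <- acfmargin:::vol_coords(vol)
  r <- 50; mu <- 0.0096
  disc2d <- outer(co$x^2, co$y^2, "+") <= r^2
  mu1 <- vol
  mu1$values <- array(mu * rep(disc2d, dim(vol$values)[3]),
                      dim(vol$values))

  zero_mu <- vol
  expect_equal(compute_acf(zero_mu, g)$values,
               array(1, c(g$n_radial, g$n_angles, g$n_planes)))

  acf <- compute_acf(mu1, g)
  expect_true(all(acf$values >= 1))
  # bins missing the object are exactly 1
  expect_equal(acf$values[1, 1, 1], 1)
  # closed form exp(mu * chord) within one voxel of chord blur
  p0 <- which(g$plane_table$segment == 0)[2]
  ctr <- which.min(abs(g$radials))
  expect_lt(abs(log(acf$values[ctr, 1, p0]) / mu - 2 * r),
            2 * vol$voxel_pitch_mm)

  # doubling mu squares every bin; ACF(mu1 + mu2) = ACF(mu1) * ACF(mu2)
  mu2 <- mu1; mu2$values <- 2 * mu1$values
  expect_equal(compute_acf(mu2, g)$values, acf$values^2, tolerance = 1e-10)

  mu_neg <- vol
  mu_neg$values[1] <- -0.001
  expect_error(compute_acf(mu_neg, g))
})

test_that("Poisson noise is mean-preserving, deterministic per seed", {
  g <- mini_geometry()
  flat <- sinogram(array(1, c(g$n_radial, g$n_angles, g$n_planes)),
                   "trues", g)
  zero <- sinogram(array(0, c(g$n_radial, g$n_angles, g$n_planes)),
                   "trues", g)
  expect_equal(sum(add_poisson_noise(zero, 1e6, 1)$values), 0)

  n1 <- add_poisson_noise(flat, 1e6, 42)
  expect_lt(abs(sum(n1$values) - 1e6), 4 * sqrt(1e6))
  expect_identical(n1$values, add_poisson_noise(flat, 1e6, 42)$values)
  expect_false(identical(n1$values, add_poisson_noise(flat, 1e6, 43)$values))
  expect_error(sinogram(array(-1, c(g$n_radial, g$n_angles, g$n_planes)),
                        "emission", g), "non-negative")
})

test_that("sinogram container and NIfTI volumes round-trip", {
  g <- mini_geometry()
  set.seed(9)
  s <- sinogram(array(rexp(g$n_radial * g$n_angles * g$n_planes),
                      c(g$n_radial, g$n_angles, g$n_planes)),
                "scatter", g)
  tf <- tempfile(fileext = ".sino")
  write_sinogram(s, tf)
  s2 <- read_sinogram(tf)
  expect_identical(s2$values, s$values)   # bit-exact
  expect_identical(s2$kind, s$kind)
  expect_equal(s2$geometry$n_planes, g$n_planes)

  v <- volume_image(array(runif(6 * 6 * 3), c(6, 6, 3)), 2.44, 3)
  tn <- tempfile(fileext = ".nii.gz")
  write_volume(v, tn)
  v2 <- read_volume(tn)
  expect_equal(v2$values, v$values)
  # pixdim is stored as float32 in the NIfTI header
  expect_equal(v2$voxel_pitch_mm, 2.44, tolerance = 1e-6)
  expect_equal(v2$slice_pitch_mm, 3, tolerance = 1e-6)
})

test_that("volume invariants are enforced", {
  expect_error(volume_image(array(-0.001, c(2, 2, 2)), 1,
                            quantity = "mu_per_mm"), "mu")
  expect_error(volume_image(array(0.05, c(2, 2, 2)), 1,
                            quantity = "mu_per_mm"), "mu")
  expect_error(volume_image(array(-1, c(2, 2, 2)), 1,
                            quantity = "activity_kBq_per_ml"))
  expect_error(volume_image(array(0.5, c(2, 2, 2)), 1,
                            quantity = "label"), "integer")
  g <- mini_geometry()
  lab <- blank_volume(g, nx = 16, quantity = "label")
  expect_error(forward_project(lab, g), "label")
})
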