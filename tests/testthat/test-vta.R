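test_that("activation radius matches the point-source closed form", {
  # independent evaluation of r = sqrt(I / (4 pi sigma E_t)) in A, S/mm, V/mm
  oracle <- sqrt(0.00258 / (4 * pi * 1e-4 * 0.19))
  expect_lt(abs(vta_radius(2.58) - oracle), 1e-9)
  expect_lt(abs(vta_radius(2.58) - 3.29), 0.01)
  # quadrupling the current doubles the radius; r -> 0 as I -> 0+
  expect_equal(vta_radius(4 * 1.7) / vta_radius(1.7), 2, tolerance = 1e-12)
  expect_lt(vta_radius(1e-9), 1e-3)
})

test_that("radius is monotone in current, threshold and conductivity", {
  cur <- c(0.5, 1.5, 2.6, 4, 5)
  expect_true(all(diff(vta_radius(cur)) > 0))
  for (et in c(0.1, 0.19, 0.3))
    for (sg in c(0.05, 0.1, 0.2)) {
      r1 <- vta_radius(2.6, field_settings(et, sg))
      expect_gt(r1, vta_radius(2.6, field_settings(et * 1.5, sg)))
      expect_gt(r1, vta_radius(2.6, field_settings(et, sg * 1.5)))
    }
})

test_that("radius input validation and capping behave as documented", {
  expect_error(vta_radius(0), "positive")
  expect_error(vta_radius(-2), "positive")
  expect_warning(r <- vta_radius(2.6, field_settings(max_radius_mm = 2)),
                 "capped")
  expect_equal(r, 2)
  expect_error(field_settings(efield_threshold_V_per_mm = 0), "positive")
})

test_that("rasterized spheres match a brute-force voxel-center count", {
  g <- default_grid()
  # sub-half-voxel radius centered on a voxel center: exactly one voxel
  ctr <- voxel_to_mm(g, c(30, 20, 20))
  expect_equal(sum(rasterize_vta(ctr, 0.4, g)$voxels), 1)
  # 3 mm sphere centered on a voxel: count within 15% of (4/3) pi 27
  # (off-center alignment can add up to ~20% discretization excess)
  ctr3 <- voxel_to_mm(g, c(36, 26, 20))
  m <- rasterize_vta(ctr3, 3, g, "right")
  vol <- 4 / 3 * pi * 27
  expect_lt(abs(sum(m$voxels) - vol) / vol, 0.15)
  # any alignment: count equals a direct distance count over voxel centers
  m2 <- rasterize_vta(c(12, -14, -7), 3, g, "right")
  mm <- as.matrix(expand.grid(grid_axis(g, 1), grid_axis(g, 2),
                              grid_axis(g, 3)))
  brute <- sum(sqrt(colSums((t(mm) - c(12, -14, -7))^2)) <= 3)
  expect_equal(sum(m2$voxels), brute)
})

test_that("rasterized volume converges to the sphere volume as voxels shrink", {
  vol <- 4 / 3 * pi * 27
  g1 <- default_grid()
  g05 <- common_grid(c(96, 96, 80), 0.5, center_mm = c(0, -14, -7))
  err1 <- abs(sum(rasterize_vta(c(10, -14, -7), 3, g1)$voxels) - vol) / vol
  err05 <- abs(sum(rasterize_vta(c(10, -14, -7), 3, g05)$voxels) * 0.5^3 -
                 vol) / vol
  expect_lt(err05, err1)
  expect_lt(err05, 0.05)
})

test_that("midline-crossing spheres are clipped to the stated hemisphere", {
  g <- default_grid()
  expect_warning(m <- rasterize_vta(c(1, -14, -7), 3, g, "right"),
                 "crosses the midline")
  x <- grid_axis(g, 1)[arrayInd(which(m$voxels), g$shape)[, 1]]
  expect_true(all(x > 0))
  expect_error(rasterize_vta(c(200, 0, 0), 3, g), "does not cover")
  expect_error(suppressWarnings(rasterize_vta(c(-8, -14, -7), 2, g, "right")),
               "outside the stated hemisphere")
})

test_that("left-right flip mirrors coordinates and is an involution", {
  g <- int_grid()
  vox <- array(FALSE, g$shape)
  vox[mm_to_voxel(g, c(14, -10, -3))[1],
      mm_to_voxel(g, c(14, -10, -3))[2],
      mm_to_voxel(g, c(14, -10, -3))[3]] <- TRUE
  m <- vta_mask(g, vox, "p", "right")
  fl <- flip_lr(m)
  expect_equal(vta_center(fl), c(-14, -10, -3))
  expect_equal(fl$hemisphere, "left")
  for (s in 1:20) {
    rm <- random_mask(g, 25, seed = s)
    ff <- flip_lr(flip_lr(rm))
    expect_identical(ff$voxels, rm$voxels)
    expect_equal(sum(flip_lr(rm)$voxels), sum(rm$voxels))
  }
})

test_that("flipping on an x-asymmetric grid reports the lost voxels", {
  g <- common_grid(c(20, 10, 10), 1, origin_mm = c(-9.3, -5, -5))
  vox <- array(FALSE, g$shape)
  vox[3, 5, 5] <- TRUE
  expect_error(flip_lr(vta_mask(g, vox)), "not x-symmetric")
})

test_that("modelled bilateral VTAs respect hemisphere and current", {
  pats <- rbind(patient_row("P01"), patient_row("P02", cr = 4.5))
  vt <- build_vtas(pats, default_grid())
  expect_length(vt, 2)
  # stronger right current -> more right-hemisphere voxels
  xs <- lapply(vt, function(m)
    grid_axis(m$grid, 1)[arrayInd(which(m$voxels), m$grid$shape)[, 1]])
  expect_gt(sum(xs[[2]] > 0), sum(xs[[1]] > 0))
  expect_gt(sum(xs[[1]] < 0), 0)
})
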