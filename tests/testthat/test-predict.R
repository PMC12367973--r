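test_that("VTA centers are the mean of member voxel coordinates", {
  g <- int_grid()
  vox <- array(FALSE, g$shape)
  i1 <- mm_to_voxel(g, c(0, 0, 0)); i2 <- mm_to_voxel(g, c(2, 0, 0))
  vox[i1[1], i1[2], i1[3]] <- TRUE
  m1 <- vta_mask(g, vox)
  expect_equal(vta_center(m1), c(0, 0, 0))
  vox[i2[1], i2[2], i2[3]] <- TRUE
  expect_equal(vta_center(vta_mask(g, vox)), c(1, 0, 0))
  # symmetric sphere: center of mass within half a voxel of the true center
  sph <- rasterize_vta(c(8.2, -10.3, -5.1), 3, default_grid())
  expect_true(all(abs(vta_center(sph) - c(8.2, -10.3, -5.1)) <= 0.5))
  expect_error(vta_center(vta_mask(g, array(FALSE, g$shape))), "empty")
  # hemisphere restriction picks out one side of a bilateral mask
  bil <- vta_mask(g, rasterize_vta(c(10, 0, 0), 2, g)$voxels |
                    rasterize_vta(c(-10, 0, 0), 2, g)$voxels)
  expect_gt(vta_center(bil, "right")[1], 9)
  expect_lt(vta_center(bil, "left")[1], -9)
  expect_equal(vta_center(bil)[1], 0, tolerance = 1e-9)
})

test_that("median split puts ties in the closer group", {
  res <- assign_groups(c(1, 2, 3, 4, 5, 6))
  expect_equal(res$cutoff_mm, 3.5)
  expect_equal(as.character(res$group),
               c(rep("closer", 3), rep("farther", 3)))
  # tie at the median joins the closer group
  res2 <- assign_groups(c(1, 2, 2, 9))
  expect_equal(sum(res2$group == "closer"), 3)
  expect_warning(res3 <- assign_groups(rep(4, 5)), "everyone")
  expect_true(all(res3$group == "closer"))
  expect_error(assign_groups(3), "at least 2")
})

test_that("distances are translation-invariant and non-negative", {
  g <- common_grid(c(40, 40, 40), 1, center_mm = c(0, 0, 0))
  set.seed(51)
  ctrs <- cbind(runif(5, 5, 12), runif(5, -6, 6), runif(5, -6, 6))
  shift <- c(2, -3, 4)
  d0 <- d1 <- numeric(5)
  for (i in 1:5) {
    m0 <- rasterize_vta(ctrs[i, ], 2.5, g)
    m1 <- rasterize_vta(ctrs[i, ] + shift, 2.5, g)
    d0[i] <- sqrt(sum((vta_center(m0) - c(8, 0, 0))^2))
    d1[i] <- sqrt(sum((vta_center(m1) - (c(8, 0, 0) + shift))^2))
  }
  expect_true(all(d0 >= 0))
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("exactly equal group means are non-concordant (strict rule)", {
  res <- vtamap:::.concordance_one(
    center_mm = c(0, 0, 0), hemisphere = "bilateral",
    direction = "improvement",
    vtas = lapply(c(1, 2, 6, 7), function(x)
      rasterize_vta(c(x, 0, 0), 1.2,
                    common_grid(c(30, 30, 30), 1, center_mm = c(0, 0, 0)))),
    baseline = c(10, 10, 10, 10), followup = c(12, 14, 12, 14),
    higher_is_better = TRUE)
  expect_equal(res$closer_mean_pct, res$farther_mean_pct)
  expect_false(res$concordant)
})

test_that("prediction recovers planted structure through the model object", {
  sim <- simulate_cohort(simulation_spec(
    planted_effects = list(planted_effect(beta = 3, coupling = "binary")),
    noise_sd = 0.3, seed = 61))
  dz <- zscore_change(sim$patients$memory_baseline,
                      sim$patients$memory_followup)
  fit <- suppressMessages(
    vlsm(dz ~ age + duration_years, cbind(sim$patients, dz = dz),
         sim$vtas, n_permutations = 300, seed = 8, scale = "memory"))
  expect_gt(sum(fit$clusters$significant), 0)
  pred <- predict(fit, sim$validation_vtas,
                  baseline = sim$validation_patients$memory_baseline,
                  followup = sim$validation_patients$memory_followup,
                  higher_is_better = TRUE)
  summ <- attr(pred, "summary")
  expect_true(all(c("closer_mean_pct", "farther_mean_pct", "concordant")
                  %in% names(summ)))
  expect_equal(sum(pred$cluster == summ$cluster[1]), 6)
  expect_true(all(pred$distance_mm >= 0))
  expect_equal(sum(pred$group[pred$cluster == summ$cluster[1]] == "closer"),
               3)
})

test_that("multi-scale concordance evaluation is well-formed", {
  sim <- simulate_cohort(simulation_spec(seed = 62))
  clusters <- data.frame(scale = c("memory", "motor"), cluster = 1:2,
                         direction = c("improvement", "worsening"),
                         hemisphere = c("right", "left"),
                         x = c(13.5, -12), y = c(-12.5, -14),
                         z = c(-8.5, -7), stringsAsFactors = FALSE)
  res <- evaluate_concordance(clusters, sim$validation_patients,
                              sim$validation_vtas, default_scales())
  expect_equal(nrow(res$summary), 2)
  expect_equal(nrow(res$detail), 12)
  expect_true(all(res$summary$n_closer == 3))
  expect_true(is.numeric(attr(res$summary, "concordant_fraction")))
})
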