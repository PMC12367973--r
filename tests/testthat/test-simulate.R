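test_that("cohort generation is deterministic and spec-shaped", {
  s1 <- simulate_cohort(simulation_spec(seed = 71))
  s2 <- simulate_cohort(simulation_spec(seed = 71))
  expect_identical(s1$patients, s2$patients)
  expect_identical(lapply(s1$vtas, `[[`, "voxels"),
                   lapply(s2$vtas, `[[`, "voxels"))
  expect_identical(s1$validation_patients, s2$validation_patients)
  expect_false(identical(
    s1$patients, simulate_cohort(simulation_spec(seed = 72))$patients))
  p <- s1$patients
  expect_equal(nrow(p), 25)
  expect_equal(nrow(s1$validation_patients), 6)
  expect_true(all(p$current_mA_left >= 0.5 & p$current_mA_right >= 0.5))
  expect_true(all(p$contact_x_left < 0 & p$contact_x_right > 0))
  expect_true(all(p$most_affected_side %in% c("left", "right")))
  expect_setequal(attr(p, "scales"), c("motor", "memory", "apathy"))
  expect_true(all(c("ledd_change", "updrs3_change") %in% names(p)))
  expect_equal(p$updrs3_change, p$motor_followup - p$motor_baseline)
})

test_that("invalid simulation specs fail before any sampling", {
  expect_error(simulation_spec(n_patients = 6), "at least 8")
  expect_error(simulation_spec(planted_effects = list(
    planted_effect(radius_mm = -1))), "radius")
  expect_error(simulation_spec(planted_effects = list(
    planted_effect(scale = "nonexistent"))), "unknown scale")
  expect_error(simulation_spec(noise_sd = 0), "noise_sd")
  expect_error(planted_effect(beta = Inf), "finite")
})

test_that("generated cohorts resemble the declared population", {
  sim <- simulate_cohort(simulation_spec(n_patients = 200, seed = 73))
  p <- sim$patients
  expect_equal(mean(p$age), 62.3, tolerance = 2.5)
  expect_equal(mean(p$duration_years), 11.7, tolerance = 1.5)
  expect_equal(mean(p$current_mA_right), 2.6, tolerance = 0.2)
  expect_gt(mean(p$sex == "M"), 0.7)
  # the motor scale improves strongly (raw scores fall), apathy worsens
  expect_lt(mean(p$motor_followup - p$motor_baseline), 0)
  expect_gt(mean(p$apathy_followup - p$apathy_baseline), 0)
})

test_that("planted dose never decreases when the VTA grows", {
  g <- default_grid()
  sphere <- rasterize_vta(c(13.5, -12.5, -8.5), 3, g, "right")
  ctr <- c(12, -14, -7)
  doses_f <- doses_b <- numeric(0)
  for (r in seq(1, 6, 0.5)) {
    m <- rasterize_vta(ctr, r, g, "bilateral")
    doses_f <- c(doses_f, sum(m$voxels & sphere$voxels) / sum(sphere$voxels))
    ci <- mm_to_voxel(g, c(13.5, -12.5, -8.5))
    doses_b <- c(doses_b, as.numeric(m$voxels[ci[1], ci[2], ci[3]]))
  }
  expect_true(all(diff(doses_f) >= 0))
  expect_true(all(diff(doses_b) >= 0))
  expect_gt(doses_f[length(doses_f)], 0.9)
})

test_that("null-cohort voxel t statistics follow the Student-t law", {
  sim <- simulate_cohort(simulation_spec(planted_effects = NULL, seed = 74))
  n <- 25
  X <- matrix(1, n, 1)
  prep <- vtamap:::.vlsm_prepare(sim$vtas, X, 4L, sim$grid)
  # a well-covered voxel: stimulated group near half the cohort
  j <- which.min(abs(prep$n_stim[match(prep$lin_elig, prep$lin_cov)] - 12))
  set.seed(75)
  B <- 600
  Y <- matrix(rnorm(n * B), n, B)
  RY <- qr.resid(qr(X), Y)
  tv <- as.vector(vtamap:::.t_stats(crossprod(prep$Gr[, j, drop = FALSE],
                                              RY),
                                    prep$d[j], colSums(RY^2), n - 2L))
  ks <- suppressWarnings(stats::ks.test(tv, stats::pt, df = n - 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("fixture suites regenerate identically and reload cleanly", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  unlink(c(d1, d2), recursive = TRUE)
  make_fixture_suite(d1, seed = 5)
  make_fixture_suite(d2, seed = 5)
  for (coh in c("null", "single_effect", "bilateral", "validation")) {
    f1 <- readLines(file.path(d1, coh, "patients.csv"))
    expect_identical(f1, readLines(file.path(d2, coh, "patients.csv")))
  }
  pats <- load_patient_table(file.path(d1, "single_effect", "patients.csv"))
  expect_equal(nrow(pats), 25)
  val <- load_patient_table(file.path(d1, "validation", "patients.csv"))
  expect_equal(nrow(val), 6)
  g <- default_grid()
  m1 <- read_mask(file.path(d1, "single_effect", "masks", "P01.nii.gz"),
                  grid = g)
  m2 <- read_mask(file.path(d2, "single_effect", "masks", "P01.nii.gz"),
                  grid = g)
  expect_identical(m1$voxels, m2$voxels)
  expect_gt(sum(m1$voxels), 0)
  cfg <- read_vlsm_config(file.path(d1, "config.yaml"))
  expect_equal(cfg$statistics$n_permutations, 1000)
  unlink(c(d1, d2), recursive = TRUE)
})
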