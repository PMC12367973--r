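test_that("voxel t equals the closed-form two-sample t with no covariates", {
  vt_list <- toy_vtas(12, seed = 31)
  set.seed(32)
  dz <- rnorm(12)
  res <- voxelwise_t(dz ~ 1, data.frame(dz = dz), vt_list)
  idx <- which(res$eligible)
  expect_gt(length(idx), 50)
  for (v in idx[seq(1, length(idx), length.out = 60)]) {
    grp <- vapply(vt_list, function(m) m$voxels[v], logical(1))
    expect_equal(res$tmap[v], pooled_t_oracle(dz, grp), tolerance = 1e-10)
  }
})

test_that("voxel t equals a direct least-squares fit with covariates", {
  vt_list <- toy_vtas(14, seed = 33)
  set.seed(34)
  dat <- data.frame(dz = rnorm(14), age = rnorm(14, 62, 8),
                    sex = sample(c("M", "F"), 14, TRUE),
                    dur = rnorm(14, 11, 4))
  res <- voxelwise_t(dz ~ age + sex + dur, dat, vt_list)
  idx <- which(res$eligible)
  expect_gt(length(idx), 20)
  for (v in idx[seq(1, length(idx), length.out = 40)]) {
    grp <- vapply(vt_list, function(m) as.numeric(m$voxels[v]), numeric(1))
    fit <- lm(dz ~ grp + age + sex + dur, dat)
    ct <- summary(fit)$coefficients
    expect_equal(res$tmap[v], ct["grp", "t value"], tolerance = 1e-10)
    expect_equal(res$beta[v], ct["grp", "Estimate"], tolerance = 1e-10)
    expect_equal(res$df, fit$df.residual)
  }
})

test_that("the minimum-group rule discards voxels with sparse groups", {
  g <- default_grid()
  # 25 patients; a marked voxel covered by exactly k of them
  probe_mm <- c(10, -14, -7)
  far <- lapply(1:22, function(i)
    rasterize_vta(c(-12 + (i %% 3), -14, -7), 3, g, "bilateral",
                  patient_id = paste0("F", i)))
  near3 <- lapply(1:3, function(i)
    rasterize_vta(probe_mm + c(0.3 * i, 0, 0), 2.5, g, "bilateral",
                  patient_id = paste0("N", i)))
  extra <- rasterize_vta(probe_mm, 2.5, g, "bilateral", patient_id = "N4")
  pv <- mm_to_voxel(g, probe_mm)
  dz <- rnorm(25, 0, 1)
  # 25 patients, probe voxel covered by exactly 3 -> discarded
  res3 <- voxelwise_t(dz ~ 1, data.frame(dz = dz), c(far, near3))
  expect_equal(res3$n_stim[pv[1], pv[2], pv[3]], 3L)
  expect_false(res3$eligible[pv[1], pv[2], pv[3]])
  expect_equal(res3$ineligible_reason[pv[1], pv[2], pv[3]], 1L)
  # 25 patients, probe voxel covered by exactly 4 -> eligible
  res4 <- voxelwise_t(dz ~ 1, data.frame(dz = dz),
                      c(far[1:21], near3, list(extra)))
  expect_equal(res4$n_stim[pv[1], pv[2], pv[3]], 4L)
  expect_true(res4$eligible[pv[1], pv[2], pv[3]])
})

test_that("raising the minimum group size never adds eligible voxels", {
  vt_list <- toy_vtas(16, seed = 35)
  dz <- rnorm(16)
  prev <- NULL
  for (k in c(2, 4, 6, 8)) {
    el <- voxelwise_t(dz ~ 1, data.frame(dz = dz), vt_list,
                      min_group_n = k)$eligible
    if (!is.null(prev)) expect_true(all(prev | !el))
    prev <- el
  }
})

test_that("a constant outcome yields zero t at every eligible voxel", {
  vt_list <- toy_vtas(10, seed = 36)
  res <- voxelwise_t(dz ~ 1, data.frame(dz = rep(2.5, 10)), vt_list)
  expect_true(all(res$tmap[res$eligible] == 0))
})

test_that("fits are deterministic and reproduce the observed statistic in the
           identity permutation", {
  vt_list <- toy_vtas(20, seed = 37)
  set.seed(38)
  dz <- rnorm(20)
  dat <- data.frame(dz = dz)
  f1 <- vlsm(dz ~ 1, dat, vt_list, n_permutations = 200, seed = 5)
  f2 <- vlsm(dz ~ 1, dat, vt_list, n_permutations = 200, seed = 5)
  expect_identical(f1$clusters, f2$clusters)
  expect_identical(f1$null_max, f2$null_max)
  expect_identical(f1$tmap, f2$tmap)
  # the identity permutation reproduces the observed maximum cluster size
  sup <- which(f1$eligible & f1$tmap > f1$t_threshold)
  obs_max <- vtamap:::.max_cluster_stat(sup, dim(f1$tmap), 26L, "size")
  expect_equal(max(0, f1$clusters$size[f1$clusters$direction ==
                                         "improvement"]), obs_max)
})

test_that("observed clusters are invariant to patient relabelling", {
  vt_list <- toy_vtas(18, seed = 39)
  set.seed(40)
  dz <- rnorm(18)
  f1 <- vlsm(dz ~ 1, data.frame(dz = dz), vt_list,
             n_permutations = 400, seed = 6)
  perm <- sample(18)
  f2 <- vlsm(dz ~ 1, data.frame(dz = dz[perm]), vt_list[perm],
             n_permutations = 400, seed = 6)
  expect_equal(f1$tmap, f2$tmap, tolerance = 1e-12)
  cols <- c("direction", "size", "x", "y", "z")
  expect_equal(f1$clusters[, cols], f2$clusters[, cols],
               tolerance = 1e-12)
  # permutation p agrees up to Monte-Carlo error
  if (nrow(f1$clusters)) expect_lt(max(abs(f1$clusters$p - f2$clusters$p)),
                                   0.1)
})

test_that("an adjusted confound restores nominal cluster error rates", {
  g <- default_grid()
  sph <- rasterize_vta(c(12, -13, -7), 3.5, g, "bilateral")
  reps <- 40
  hit_raw <- hit_adj <- logical(reps)
  for (r in seq_len(reps)) {
    vt_list <- toy_vtas(20, seed = 600 + r)
    conf <- vapply(vt_list, function(m)
      sum(m$voxels & sph$voxels) / sum(sph$voxels), numeric(1))
    conf <- as.numeric(scale(conf))
    set.seed(700 + r)
    dz <- 1.5 * conf + 0.5 * rnorm(20)
    dat <- data.frame(dz = dz, conf = conf)
    raw <- vlsm(dz ~ 1, dat, vt_list, n_permutations = 250, seed = r,
                perm_block = 250)
    adj <- vlsm(dz ~ conf, dat, vt_list, n_permutations = 250, seed = r,
                perm_block = 250)
    hit_raw[r] <- any(raw$clusters$significant)
    hit_adj[r] <- any(adj$clusters$significant)
  }
  # confounded analysis finds spurious structure; adjusted one is nominal
  expect_gt(mean(hit_raw), mean(hit_adj) + 0.2)
  expect_lte(mean(hit_adj), 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("degenerate designs are refused or flagged", {
  vt_list <- toy_vtas(10, seed = 41)
  dat <- data.frame(dz = rnorm(10), x1 = 1:10)
  dat$x2 <- dat$x1 * 2  # collinear pair
  expect_error(vlsm(dz ~ x1 + x2, dat, vt_list, n_permutations = 100,
                    seed = 1), "rank deficient")
  expect_error(vlsm(dz ~ 1, dat[1:3, , drop = FALSE], vt_list[1:3],
                    n_permutations = 100, seed = 1), "refusing")
  # non-overlapping tiny cohort: every voxel fails the minimum-group rule
  g <- default_grid()
  spread <- lapply(1:8, function(i)
    rasterize_vta(c(-15 + 3.6 * i, -14, -7), 1.2, g, "bilateral",
                  patient_id = paste0("S", i)))
  expect_warning(fit <- vlsm(dz ~ 1, data.frame(dz = rnorm(8)), spread,
                             n_permutations = 100, seed = 1),
                 "no voxel passed")
  expect_equal(nrow(fit$clusters), 0)
})

test_that("freedman-lane permutation is available and deterministic", {
  vt_list <- toy_vtas(15, seed = 42)
  set.seed(43)
  dat <- data.frame(dz = rnorm(15), age = rnorm(15, 60, 9))
  f1 <- vlsm(dz ~ age, dat, vt_list, n_permutations = 150, seed = 2,
             permutation = "freedman_lane")
  f2 <- vlsm(dz ~ age, dat, vt_list, n_permutations = 150, seed = 2,
             permutation = "freedman_lane")
  expect_identical(f1$null_max, f2$null_max)
  expect_false(identical(
    f1$null_max,
    vlsm(dz ~ age, dat, vt_list, n_permutations = 150, seed = 2)$null_max))
})

test_that("model methods expose coefficients, residuals and simulations", {
  vt_list <- toy_vtas(12, seed = 44)
  set.seed(45)
  dat <- data.frame(dz = rnorm(12), age = rnorm(12, 60, 8))
  fit <- vlsm(dz ~ age, dat, vt_list, n_permutations = 100, seed = 3)
  expect_identical(dim(coef(fit)), dim(fit$tmap))
  expect_equal(residuals(fit), qr.resid(qr(fit$X), fit$y))
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(12L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 9))
  expect_output(print(fit), "VLSM")
  expect_silent(grDevices::pdf(NULL))
  plot(fit)
  grDevices::dev.off()
})
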