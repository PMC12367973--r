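# Shared fixtures and independent oracles, built in code at test time.

# small grid spanning the midline, voxel centers at half-integer x
toy_grid <- function(nx = 20, ny = 20, nz = 16, center = c(0, 0, 0)) {
  common_grid(c(nx, ny, nz), 1, center_mm = center)
}

# grid with integer-mm voxel centers (odd extents, x = 0 representable)
int_grid <- function() common_grid(c(49, 49, 41), 1, center_mm = c(0, -14, -7))

random_mask <- function(grid, n_voxels = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vox <- array(FALSE, grid$shape)
  vox[sample(prod(grid$shape), n_voxels)] <- TRUE
  vta_mask(grid, vox, patient_id = "rnd")
}

# cohort of bilateral spherical VTAs jittered around the subthalamic region
toy_vtas <- function(n, grid = default_grid(), seed = 1, radius = 3.2,
                     jitter = 1.5) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    vox <- array(FALSE, grid$shape)
    for (s in c(-1, 1)) {
      ctr <- c(s * 12, -14, -7) + stats::rnorm(3, 0, jitter)
      m <- rasterize_vta(ctr, radius, grid, "bilateral",
                        patient_id = sprintf("T%02d", i))
      vox <- vox | m$voxels
    }
    vta_mask(grid, vox, sprintf("T%02d", i))
  })
}

# textbook pooled-variance two-sample t (group = TRUE vs FALSE)
pooled_t_oracle <- function(y, g) {
  a <- y[g]; b <- y[!g]
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# one valid interchange-format patient row
patient_row <- function(id = "P01", cxl = -12, cxr = 12,
                        cl = 2.62, cr = 2.58, side = "left",
                        motor_b = 45, motor_f = 31) {
  data.frame(id = id, age = 62, sex = "M", duration_years = 11.7,
             most_affected_side = side,
             current_mA_left = cl, current_mA_right = cr,
             contact_x_left = cxl, contact_y_left = -14, contact_z_left = -7,
             contact_x_right = cxr, contact_y_right = -14,
             contact_z_right = -7,
             motor_baseline = motor_b, motor_followup = motor_f,
             stringsAsFactors = FALSE)
}
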