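#' Specify a planted voxel-cluster effect
#'
#' A spherical "sweet spot": each patient's outcome change on `scale`
#' gains `beta` baseline-SD units multiplied by the fraction of the sphere
#' overlapped by the patient's VTA. Fractional (rather than binary)
#' coupling gives a smooth dose-response, a harder and more realistic
#' test of the binary-membership voxel model. Positive `beta` plants an
#' improvement effect, negative a worsening effect.
#'
#' @param scale scale name the effect acts on.
#' @param hemisphere `"left"` or `"right"`.
#' @param center_mm sphere center in mm.
#' @param radius_mm sphere radius in mm (> 0).
#' @param beta effect size in baseline-SD units of the scale.
#' @param coupling `"fraction"` (the default dose-response described
#'   above) or `"binary"` (each patient gains the full `beta` iff their
#'   VTA covers the voxel at the sphere center, an all-or-nothing sweet
#'   spot matching the binary group model of the voxel-wise test).
#' @return A list describing the effect.
#' @export
planted_effect <- function(scale = "memory", hemisphere = "right",
                           center_mm = c(13.5, -12.5, -8.5), radius_mm = 3,
                           beta = 1.5, coupling = c("fraction", "binary")) {
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("planted effect radius must be > 0", call. = FALSE)
  if (!is.finite(beta)) stop("planted effect beta must be finite",
                             call. = FALSE)
  list(scale = scale, hemisphere = match.arg(hemisphere, c("left", "right")),
       center_mm = center_mm, radius_mm = radius_mm, beta = beta,
       coupling = match.arg(coupling))
}

#' Default synthetic scale set
#'
#' Three scales covering the analysis domains, with baseline
#' distributions and cohort-level mean changes (`shift_sd`, in baseline-SD
#' units, improvement-positive) patterned on typical 1-year subthalamic
#' stimulation outcomes: a strongly improving motor score (lower raw =
#' better), a mildly changing memory score (higher raw = better) and a
#' worsening apathy score (lower raw = better).
#'
#' @return A data frame with columns `scale`, `domain`,
#'   `higher_is_better`, `baseline_mean`, `baseline_sd`, `shift_sd`.
#' @export
default_scales <- function() {
  data.frame(
    scale = c("motor", "memory", "apathy"),
    domain = c("motor", "cognitive", "behavioral"),
    higher_is_better = c(FALSE, TRUE, FALSE),
    baseline_mean = c(45, 43, 9.5),
    baseline_sd = c(12, 8.6, 5.3),
    shift_sd = c(1.2, 0.1, -0.5),
    stringsAsFactors = FALSE)
}

#' Specify a synthetic cohort
#'
#' Defines the data-generating situation the pipeline assumes: bilateral
#' subthalamic electrodes with contacts jittered around (+/-12, -14, -7)
#' mm, currents near 2.6 (0.6) mA truncated at `current_min_mA`,
#' covariates age ~ N(62.3, 8.0) years, disease duration ~ N(11.7, 4.5)
#' years and a 21:4 male:female ratio, spherical VTAs from the field
#' model, and outcome changes built from per-scale cohort shifts,
#' covariate loadings, planted voxel-cluster effects and unit-SD Gaussian
#' noise.
#'
#' @param n_patients main cohort size (>= 2 x 4, the minimum-group rule).
#' @param n_validation size of the held-out validation cohort.
#' @param contact_mean_mm list with `left` and `right` mean contact
#'   coordinates.
#' @param contact_jitter_sd_mm per-axis SD of contact jitter.
#' @param current_mean_mA,current_sd_mA,current_min_mA current
#'   distribution (truncated normal).
#' @param scales scale metadata as in [default_scales()].
#' @param planted_effects list of [planted_effect()]s, or `NULL` for a
#'   null cohort.
#' @param covariate_loadings named vector: outcome-change loading per year
#'   of `age` and `duration`, in SD units.
#' @param age_mean,age_sd,duration_mean,duration_sd,p_male covariate
#'   distributions.
#' @param ledd_change_mean,ledd_change_sd distribution of medication
#'   (levodopa-equivalent dose) change in mg.
#' @param noise_sd residual SD of the outcome change in baseline-SD units.
#' @param grid the [common_grid()] masks are rasterized on.
#' @param field a [field_settings()] object.
#' @param seed RNG seed (determines the cohort byte-for-byte).
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_patients = 25L, n_validation = 6L,
                            contact_mean_mm = list(left = c(-12, -14, -7),
                                                   right = c(12, -14, -7)),
                            contact_jitter_sd_mm = 1.5,
                            current_mean_mA = 2.6, current_sd_mA = 0.6,
                            current_min_mA = 0.5,
                            scales = default_scales(),
                            planted_effects = list(planted_effect()),
                            covariate_loadings = c(age = -0.025,
                                                   duration = -0.02),
                            age_mean = 62.3, age_sd = 8.0,
                            duration_mean = 11.7, duration_sd = 4.5,
                            p_male = 21 / 25,
                            ledd_change_mean = -560, ledd_change_sd = 287,
                            noise_sd = 1, grid = default_grid(),
                            field = field_settings(), seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               n_validation = as.integer(n_validation),
               contact_mean_mm = contact_mean_mm,
               contact_jitter_sd_mm = contact_jitter_sd_mm,
               current_mean_mA = current_mean_mA,
               current_sd_mA = current_sd_mA,
               current_min_mA = current_min_mA,
               scales = scales, planted_effects = planted_effects,
               covariate_loadings = covariate_loadings,
               age_mean = age_mean, age_sd = age_sd,
               duration_mean = duration_mean, duration_sd = duration_sd,
               p_male = p_male, ledd_change_mean = ledd_change_mean,
               ledd_change_sd = ledd_change_sd, noise_sd = noise_sd,
               grid = grid, field = field, seed = as.integer(seed))
  class(spec) <- "simulation_spec"
  .validate_spec(spec)
  spec
}

.validate_spec <- function(spec) {
  if (spec$n_patients < 8L)
    stop("n_patients must be at least 8 (twice the minimum group size)",
         call. = FALSE)
  if (spec$n_validation < 2L)
    stop("n_validation must be at least 2", call. = FALSE)
  for (ef in spec$planted_effects) {
    if (!is.finite(ef$radius_mm) || ef$radius_mm <= 0)
      stop("planted effect radius must be > 0", call. = FALSE)
    if (!is.finite(ef$beta))
      stop("planted effect beta must be finite", call. = FALSE)
    if (!ef$scale %in% spec$scales$scale)
      stop("planted effect acts on unknown scale '", ef$scale, "'",
           call. = FALSE)
  }
  if (spec$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  .stopifnot_grid(spec$grid)
  invisible(spec)
}

.rnorm_min <- function(n, mean, sd, min) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < min)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

.draw_patients <- function(spec, n, id_prefix) {
  df <- data.frame(
    id = sprintf("%s%02d", id_prefix, seq_len(n)),
    age = round(.rnorm_min(n, spec$age_mean, spec$age_sd, 30), 1),
    sex = ifelse(stats::runif(n) < spec$p_male, "M", "F"),
    duration_years = round(.rnorm_min(n, spec$duration_mean,
                                      spec$duration_sd, 1), 1),
    most_affected_side = sample(c("left", "right"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  for (h in c("left", "right")) {
    df[[paste0("current_mA_", h)]] <-
      round(.rnorm_min(n, spec$current_mean_mA, spec$current_sd_mA,
                       spec$current_min_mA), 2)
    mu <- spec$contact_mean_mm[[h]]
    ax <- c("x", "y", "z")
    for (a in 1:3) {
      v <- stats::rnorm(n, mu[a], spec$contact_jitter_sd_mm)
      if (a == 1L) {  # contacts must stay on their own side of the midline
        while (any(bad <- if (h == "left") v >= -0.5 else v <= 0.5))
          v[bad] <- stats::rnorm(sum(bad), mu[1], spec$contact_jitter_sd_mm)
      }
      df[[paste0("contact_", ax[a], "_", h)]] <- round(v, 2)
    }
  }
  df
}

.overlap_fractions <- function(vtas, sphere) {
  nsph <- sum(sphere$voxels)
  vapply(vtas, function(m) sum(m$voxels & sphere$voxels) / nsph, numeric(1))
}

# per-patient dose of one planted effect: overlap fraction or center coverage
.effect_dose <- function(vtas, effect, sphere, grid) {
  if (identical(effect$coupling, "binary")) {
    ci <- mm_to_voxel(grid, effect$center_mm)
    vapply(vtas, function(m) as.numeric(m$voxels[ci[1], ci[2], ci[3]]),
           numeric(1))
  } else .overlap_fractions(vtas, sphere)
}

.draw_outcomes <- function(spec, df, vtas, planted_vox) {
  n <- nrow(df)
  frac <- lapply(seq_along(planted_vox), function(e)
    .effect_dose(vtas, spec$planted_effects[[e]], planted_vox[[e]],
                 spec$grid))
  for (k in seq_len(nrow(spec$scales))) {
    sc <- spec$scales[k, ]
    latent <- sc$shift_sd +
      spec$covariate_loadings[["age"]] * (df$age - spec$age_mean) +
      spec$covariate_loadings[["duration"]] *
        (df$duration_years - spec$duration_mean) +
      stats::rnorm(n, 0, spec$noise_sd)
    for (e in seq_along(spec$planted_effects)) {
      ef <- spec$planted_effects[[e]]
      if (ef$scale == sc$scale) latent <- latent + ef$beta * frac[[e]]
    }
    baseline <- stats::rnorm(n, sc$baseline_mean, sc$baseline_sd)
    delta_raw <- sc$baseline_sd * latent *
      if (sc$higher_is_better) 1 else -1
    df[[paste0(sc$scale, "_baseline")]] <- round(baseline, 1)
    df[[paste0(sc$scale, "_followup")]] <- round(baseline + delta_raw, 1)
  }
  df$ledd_change <- round(stats::rnorm(n, spec$ledd_change_mean,
                                       spec$ledd_change_sd), 1)
  df$updrs3_change <- if ("motor" %in% spec$scales$scale)
    df$motor_followup - df$motor_baseline
  else round(stats::rnorm(n, -15.4, 11), 1)
  attr(df, "overlap_fractions") <- frac
  df
}

#' Generate a synthetic cohort
#'
#' Draws a main and a validation cohort from a [simulation_spec()]:
#' covariates, electrode contacts, currents, modelled VTAs, and outcome
#' scores whose change combines the per-scale cohort shift, covariate
#' loadings, the planted voxel-cluster effects (scaled by each patient's
#' fractional VTA overlap with the planted sphere) and Gaussian noise.
#' Raw baseline/follow-up scores are back-constructed so that the
#' declared `higher_is_better` orientation holds. The same seed
#' reproduces the cohort exactly.
#'
#' @param spec a [simulation_spec()].
#' @return A list of class `"dbs_simulation"` with `patients`, `vtas`,
#'   `validation_patients`, `validation_vtas`, `grid`, `planted`
#'   (per-effect sphere masks and overlap fractions) and `spec`.
#' @export
simulate_cohort <- function(spec = simulation_spec()) {
  .validate_spec(spec)
  set.seed(spec$seed)
  planted_vox <- lapply(spec$planted_effects, function(ef)
    rasterize_vta(ef$center_mm, ef$radius_mm, spec$grid, ef$hemisphere,
                  patient_id = paste0("planted_", ef$scale)))
  pat <- .draw_patients(spec, spec$n_patients, "P")
  vtas <- build_vtas(pat, spec$grid, spec$field)
  pat <- .draw_outcomes(spec, pat, vtas, planted_vox)
  val <- .draw_patients(spec, spec$n_validation, "V")
  val_vtas <- build_vtas(val, spec$grid, spec$field)
  val <- .draw_outcomes(spec, val, val_vtas, planted_vox)
  planted <- lapply(seq_along(spec$planted_effects), function(e) {
    c(spec$planted_effects[[e]],
      list(sphere = planted_vox[[e]],
           overlap = attr(pat, "overlap_fractions")[[e]],
           overlap_validation = attr(val, "overlap_fractions")[[e]]))
  })
  attr(pat, "overlap_fractions") <- NULL
  attr(val, "overlap_fractions") <- NULL
  structure(list(patients = structure(pat, scales = spec$scales$scale),
                 vtas = vtas,
                 validation_patients = structure(val,
                                                 scales = spec$scales$scale),
                 validation_vtas = val_vtas,
                 grid = spec$grid, planted = planted, spec = spec),
            class = "dbs_simulation")
}

#' @export
print.dbs_simulation <- function(x, ...) {
  cat(sprintf("Synthetic DBS cohort: %d patients + %d validation (seed %d)\n",
              nrow(x$patients), nrow(x$validation_patients), x$spec$seed))
  cat(sprintf("  scales          : %s\n",
              paste(x$spec$scales$scale, collapse = ", ")))
  if (length(x$planted))
    for (p in x$planted)
      cat(sprintf("  planted effect  : %s, %s hemisphere, beta %g SD, r %g mm at (%g, %g, %g)\n",
                  p$scale, p$hemisphere, p$beta, p$radius_mm,
                  p$center_mm[1], p$center_mm[2], p$center_mm[3]))
  else cat("  planted effect  : none (null cohort)\n")
  invisible(x)
}

#' Write a deterministic fixture suite
#'
#' Generates four small cohorts (null, single planted effect, bilateral
#' planted effects, and the single-effect cohort's validation patients)
#' and writes them in the pipeline's interchange formats: patient CSVs,
#' per-patient NIfTI masks, scale metadata CSV and a YAML config.
#' Regeneration with the same seed is idempotent.
#'
#' @param out_dir output directory (created if needed).
#' @param seed base seed; sub-cohorts use `seed`, `seed + 1`, `seed + 2`.
#' @return Invisibly, the paths written.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- list(
    null = simulation_spec(planted_effects = NULL, seed = seed),
    single_effect = simulation_spec(seed = seed + 1L),
    bilateral = simulation_spec(planted_effects = list(
      planted_effect(hemisphere = "right", center_mm = c(13.5, -12.5, -8.5)),
      planted_effect(hemisphere = "left", center_mm = c(-13.5, -12.5, -8.5))),
      seed = seed + 2L))
  paths <- character()
  write_cohort <- function(name, patients, vtas) {
    d <- file.path(out_dir, name)
    dir.create(file.path(d, "masks"), recursive = TRUE, showWarnings = FALSE)
    p <- file.path(d, "patients.csv")
    write_patient_table(patients, p)
    paths <<- c(paths, p)
    for (m in vtas) {
      mp <- file.path(d, "masks", paste0(m$patient_id, ".nii.gz"))
      write_mask(m, mp)
      paths <<- c(paths, mp)
    }
  }
  for (name in names(specs)) {
    sim <- simulate_cohort(specs[[name]])
    write_cohort(name, sim$patients, sim$vtas)
    if (name == "single_effect")
      write_cohort("validation", sim$validation_patients,
                   sim$validation_vtas)
  }
  sc <- file.path(out_dir, "scales.csv")
  utils::write.csv(default_scales(), sc, row.names = FALSE)
  cf <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(default_config(), cf)
  paths <- c(paths, sc, cf)
  invisible(paths)
}
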