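#' Write a mask or statistical map as NIfTI
#'
#' Masks are written as integer volumes, maps as float volumes, with the
#' grid's voxel-to-mm affine stored in the qform/sform (code 2, aligned to
#' a common space).
#'
#' @param mask a [vta_mask()] (for `write_mask`).
#' @param path output file, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  .write_nifti(array(as.integer(mask$voxels), dim = mask$grid$shape),
               mask$grid, path)
}

#' @rdname write_mask
#' @param map numeric 3-D array on `grid` (for `write_map`).
#' @param grid the [common_grid()] the array lives on.
#' @export
write_map <- function(map, grid, path) {
  .stopifnot_grid(grid)
  if (!identical(dim(map), as.integer(grid$shape)))
    stop("map dimensions do not match the grid shape", call. = FALSE)
  .write_nifti(map, grid, path)
}

.write_nifti <- function(arr, grid, path) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`qform<-`(img, structure(grid_affine(grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' The volume must be single-frame and axis-aligned in RAS orientation;
#' its affine defines the grid. If a reference `grid` is supplied, the
#' file's grid must match it within `tol_mm` (default 1e-3 mm) or an
#' incompatibility error is raised. Values are binarized at > 0.5; an
#' all-zero mask is readable but flagged with a warning and an `"empty"`
#' attribute.
#'
#' @param path NIfTI file.
#' @param grid optional reference [common_grid()] to check against.
#' @param patient_id,hemisphere,source metadata for the returned mask.
#' @param tol_mm affine comparison tolerance in mm.
#' @return A [vta_mask()] with `source = "supplied"` by default.
#' @export
read_mask <- function(path, grid = NULL, patient_id = NA_character_,
                      hemisphere = "bilateral", source = "supplied",
                      tol_mm = 1e-3) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 3L)
    stop("expected a single 3-D NIfTI volume", call. = FALSE)
  fgrid <- .grid_from_xform(RNifti::xform(img), dim(arr))
  if (!is.null(grid)) {
    .stopifnot_grid(grid)
    if (!grids_compatible(grid, fgrid, tol_mm))
      stop(sprintf("mask grid is incompatible with the reference grid (tolerance %g mm)",
                   tol_mm), call. = FALSE)
    fgrid <- grid
  }
  m <- vta_mask(fgrid, arr > 0.5, patient_id, hemisphere, source)
  if (!any(m$voxels)) {
    warning("mask is empty (no nonzero voxels)", call. = FALSE)
    attr(m, "empty") <- TRUE
  }
  m
}

#' Read a statistical map from NIfTI
#' @inheritParams read_mask
#' @return list with `map` (numeric array) and `grid`.
#' @export
read_map <- function(path, grid = NULL, tol_mm = 1e-3) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 3L)
    stop("expected a single 3-D NIfTI volume", call. = FALSE)
  fgrid <- .grid_from_xform(RNifti::xform(img), dim(arr))
  if (!is.null(grid)) {
    if (!grids_compatible(grid, fgrid, tol_mm))
      stop("map grid is incompatible with the reference grid", call. = FALSE)
    fgrid <- grid
  }
  list(map = arr, grid = fgrid)
}

.grid_from_xform <- function(xfm, dims) {
  rot <- xfm[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4 || any(diag(rot) <= 0))
    stop("NIfTI volume is not axis-aligned RAS; reorient it first",
         call. = FALSE)
  common_grid(dims, diag(rot), origin_mm = xfm[1:3, 4])
}

# ---- patient tables ---------------------------------------------------------

.mandatory_cols <- c("id", "age", "sex", "duration_years",
                     "most_affected_side",
                     "current_mA_left", "current_mA_right",
                     "contact_x_left", "contact_y_left", "contact_z_left",
                     "contact_x_right", "contact_y_right", "contact_z_right")

#' Names of outcome scales present in a patient table
#'
#' Scales are detected as column pairs `<scale>_baseline` /
#' `<scale>_followup`.
#'
#' @param patients a patient data frame.
#' @return Character vector of scale names.
#' @export
scale_names <- function(patients) {
  b <- sub("_baseline$", "", grep("_baseline$", names(patients), value = TRUE))
  f <- sub("_followup$", "", grep("_followup$", names(patients), value = TRUE))
  intersect(b, f)
}

#' Load and validate a patient table
#'
#' Reads the CSV interchange format: mandatory columns `id`, `age`, `sex`,
#' `duration_years`, `most_affected_side`, `current_mA_left/right`,
#' `contact_x/y/z_left/right`, one column pair `<scale>_baseline` /
#' `<scale>_followup` per clinical scale, and optional `ledd_change` and
#' `updrs3_change`. A hemisphere is considered implanted when its current
#' is non-missing; an implanted hemisphere needs a positive current and a
#' contact on its own side of the midline (left: x < 0, right: x > 0).
#' Rows violating these invariants are dropped with row-level warnings.
#' A patient missing one timepoint of a scale has both set to `NA`
#' (missing scales are dropped per-analysis, never imputed).
#'
#' @param path CSV file.
#' @return A `data.frame`, one validated row per patient, with the detected
#'   scale names in attribute `"scales"`.
#' @export
load_patient_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("patient table is empty", call. = FALSE)
    return(structure(df, scales = character()))
  }
  missing_cols <- setdiff(.mandatory_cols, names(df))
  if (length(missing_cols))
    stop("patient table format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cc in c("current_mA_left", "current_mA_right")) {
    if (!is.numeric(df[[cc]])) {
      suppressWarnings(num <- as.numeric(df[[cc]]))
      if (any(is.na(num) & !is.na(df[[cc]]) & nzchar(trimws(df[[cc]]))))
        stop(sprintf("non-numeric stimulation current in column '%s'", cc),
             call. = FALSE)
      df[[cc]] <- num
    }
  }
  validate_patients(df)
}

#' @rdname load_patient_table
#' @param patients a patient data frame in the interchange layout.
#' @export
validate_patients <- function(patients) {
  df <- patients
  reasons <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    probs <- character()
    for (h in c("left", "right")) {
      cur <- r[[paste0("current_mA_", h)]]
      if (is.na(cur)) next  # hemisphere not implanted
      if (!is.finite(cur) || cur <= 0)
        probs <- c(probs, sprintf("%s current_mA must be > 0 (got %s)", h, cur))
      cx <- r[[paste0("contact_x_", h)]]
      if (!is.finite(cx))
        probs <- c(probs, sprintf("%s contact coordinates missing", h))
      else if ((h == "left" && cx >= 0) || (h == "right" && cx <= 0))
        probs <- c(probs,
                   sprintf("%s contact at x = %g mm is on the wrong side of the midline",
                           h, cx))
    }
    if (is.na(df$current_mA_left[i]) && is.na(df$current_mA_right[i]))
      probs <- c(probs, "no implanted hemisphere")
    if (!df$most_affected_side[i] %in% c("left", "right"))
      probs <- c(probs, "most_affected_side must be 'left' or 'right'")
    reasons[i] <- paste(probs, collapse = "; ")
  }
  bad <- nzchar(reasons)
  if (any(bad))
    warning(sprintf("rejected %d patient row(s):\n%s", sum(bad),
                    paste(sprintf("  row %d (id %s): %s", which(bad),
                                  df$id[bad], reasons[bad]),
                          collapse = "\n")),
            call. = FALSE)
  df <- df[!bad, , drop = FALSE]
  # a scale observed at only one timepoint is treated as missing
  for (sc in scale_names(df)) {
    b <- paste0(sc, "_baseline"); f <- paste0(sc, "_followup")
    incomplete <- xor(is.na(df[[b]]), is.na(df[[f]]))
    df[[b]][incomplete] <- NA
    df[[f]][incomplete] <- NA
  }
  structure(df, scales = scale_names(df))
}

#' Write a patient table in the interchange CSV layout
#' @param patients a patient data frame.
#' @param path output CSV file.
#' @export
write_patient_table <- function(patients, path) {
  utils::write.csv(patients, path, row.names = FALSE)
  invisible(path)
}

# ---- configuration ----------------------------------------------------------

#' Read a pipeline configuration from YAML
#'
#' Sections `grid`, `field_model`, `statistics` and `prediction` override
#' package defaults. `field_model$conductivity` takes a `value` and a
#' `unit` of `"S/m"` or `"S/mm"` (the value is normalized to S/m).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A nested list with the four sections fully populated.
#' @export
read_vlsm_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (sec in intersect(names(user), names(cfg)))
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  fm <- cfg$field_model
  if (is.list(fm$conductivity)) {
    unit <- fm$conductivity$unit
    val <- as.numeric(fm$conductivity$value)
    if (!unit %in% c("S/m", "S/mm"))
      stop("conductivity unit must be 'S/m' or 'S/mm'", call. = FALSE)
    cfg$field_model$conductivity_S_per_m <-
      if (unit == "S/mm") val * 1000 else val
    cfg$field_model$conductivity <- NULL
  }
  cfg
}

#' @rdname read_vlsm_config
#' @export
default_config <- function() {
  list(
    grid = list(shape = c(48L, 48L, 40L), voxel_size_mm = c(1, 1, 1),
                center_mm = c(0, -14, -7)),
    field_model = list(efield_threshold_V_per_mm = 0.19,
                       conductivity_S_per_m = 0.1, max_radius_mm = 10),
    statistics = list(min_group_n = 4L, n_permutations = 1000L,
                      alpha = 0.05, cluster_forming_p = 0.01,
                      connectivity = 26L, tail = "both",
                      permutation = "manly", null_statistic = "size"),
    prediction = list(tie_rule = "closer")
  )
}

.config_grid <- function(cfg) {
  common_grid(cfg$grid$shape, cfg$grid$voxel_size_mm,
              center_mm = cfg$grid$center_mm)
}
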