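#' Electric-field model settings
#'
#' Parameters of the monopolar point-source field model used to turn a
#' stimulation current into an activation radius: tissue is considered
#' activated where the field magnitude exceeds `efield_threshold_V_per_mm`
#' in a homogeneous isotropic medium of conductivity
#' `conductivity_S_per_m`. The defaults are 0.19 V/mm and 0.1 S/m, the
#' combination that yields clinically plausible 2-4 mm activation radii at
#' typical subthalamic currents. Radii above `max_radius_mm` are capped
#' with a warning.
#'
#' @param efield_threshold_V_per_mm activation threshold, V/mm.
#' @param conductivity_S_per_m tissue conductivity, S/m.
#' @param max_radius_mm cap on the modelled radius, mm.
#' @return An object of class `"field_settings"`.
#' @export
field_settings <- function(efield_threshold_V_per_mm = 0.19,
                           conductivity_S_per_m = 0.1,
                           max_radius_mm = 10) {
  vals <- c(efield_threshold_V_per_mm, conductivity_S_per_m, max_radius_mm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all field-model settings must be strictly positive", call. = FALSE)
  structure(list(efield_threshold_V_per_mm = efield_threshold_V_per_mm,
                 conductivity_S_per_m = conductivity_S_per_m,
                 max_radius_mm = max_radius_mm),
            class = "field_settings")
}

#' Activation radius of a monopolar point source
#'
#' For a point current source I in a homogeneous isotropic medium of
#' conductivity sigma, the field magnitude at distance r is
#' |E|(r) = I / (4 pi sigma r^2). Solving |E|(r) = E_t for the threshold
#' E_t gives the activation radius
#'
#'   r = sqrt(I / (4 pi sigma E_t)),
#'
#' evaluated in consistent units (A, S/mm, V/mm -> mm). The radius grows
#' with the square root of the current and shrinks with threshold and
#' conductivity.
#'
#' @param current_mA stimulation current in mA (vectorized; all > 0).
#' @param settings a [field_settings()] object.
#' @return Activation radius (radii) in mm; values above
#'   `settings$max_radius_mm` are capped with a warning.
#' @examples
#' vta_radius(2.58)  # ~3.29 mm at the default threshold and conductivity
#' @export
vta_radius <- function(current_mA, settings = field_settings()) {
  if (any(!is.finite(current_mA)) || any(current_mA <= 0))
    stop("'current_mA' must be strictly positive", call. = FALSE)
  amps <- current_mA / 1000
  sigma_S_per_mm <- settings$conductivity_S_per_m / 1000
  r <- sqrt(amps / (4 * pi * sigma_S_per_mm *
                      settings$efield_threshold_V_per_mm))
  over <- r > settings$max_radius_mm
  if (any(over)) {
    warning(sprintf("%d radius value(s) capped at max_radius_mm = %g mm",
                    sum(over), settings$max_radius_mm), call. = FALSE)
    r[over] <- settings$max_radius_mm
  }
  r
}

#' Rasterize a spherical VTA onto a grid
#'
#' A voxel belongs to the mask iff its center lies within `radius_mm` of
#' `center_mm` (no partial-volume weighting; downstream stages only need
#' binary masks). If a lateralized sphere crosses the midline, only the
#' voxels on the stated hemisphere's side are kept and a warning is
#' emitted.
#'
#' @param center_mm sphere center (mm, RAS).
#' @param radius_mm sphere radius (mm, > 0).
#' @param grid a [common_grid()].
#' @param hemisphere `"left"`, `"right"` or `"bilateral"`.
#' @param patient_id identifier stored in the mask.
#' @return A [vta_mask()] with `source = "modelled"`.
#' @export
rasterize_vta <- function(center_mm, radius_mm, grid,
                          hemisphere = c("bilateral", "left", "right"),
                          patient_id = NA_character_) {
  .stopifnot_grid(grid)
  hemisphere <- match.arg(hemisphere)
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("'radius_mm' must be positive", call. = FALSE)
  ax <- lapply(1:3, function(a) grid_axis(grid, a))
  near <- lapply(1:3, function(a) {
    which(abs(ax[[a]] - center_mm[a]) <= radius_mm)
  })
  vox <- array(FALSE, grid$shape)
  if (all(lengths(near) > 0)) {
    dx2 <- (ax[[1]][near[[1]]] - center_mm[1])^2
    dy2 <- (ax[[2]][near[[2]]] - center_mm[2])^2
    dz2 <- (ax[[3]][near[[3]]] - center_mm[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius_mm^2
    vox[near[[1]], near[[2]], near[[3]]] <- inside
  }
  if (!any(vox))
    stop("sphere does not cover any voxel center of the grid", call. = FALSE)
  if (hemisphere != "bilateral") {
    xside <- if (hemisphere == "left") ax[[1]] < 0 else ax[[1]] > 0
    dropped <- sum(vox[!xside, , ])
    if (dropped > 0) {
      warning(sprintf(
        "sphere crosses the midline: %d voxel(s) outside the %s hemisphere dropped",
        dropped, hemisphere), call. = FALSE)
      vox[!xside, , ] <- FALSE
    }
    if (!any(vox))
      stop("sphere lies entirely outside the stated hemisphere",
           call. = FALSE)
  }
  vta_mask(grid, vox, patient_id, hemisphere, "modelled")
}

#' Model both hemispheres' VTAs for a cohort
#'
#' Applies [vta_radius()] and [rasterize_vta()] to each implanted
#' hemisphere of each patient row and unions the two spheres into one
#' bilateral mask per patient.
#'
#' @param patients validated patient data frame (see
#'   [load_patient_table()]).
#' @param grid a [common_grid()].
#' @param settings a [field_settings()] object.
#' @return Named list of bilateral [vta_mask()] objects, one per patient.
#' @export
build_vtas <- function(patients, grid, settings = field_settings()) {
  .stopifnot_grid(grid)
  out <- vector("list", nrow(patients))
  names(out) <- patients$id
  for (i in seq_len(nrow(patients))) {
    vox <- array(FALSE, grid$shape)
    for (h in c("left", "right")) {
      cur <- patients[[paste0("current_mA_", h)]][i]
      if (is.na(cur)) next
      ctr <- c(patients[[paste0("contact_x_", h)]][i],
               patients[[paste0("contact_y_", h)]][i],
               patients[[paste0("contact_z_", h)]][i])
      m <- rasterize_vta(ctr, vta_radius(cur, settings), grid,
                         hemisphere = h, patient_id = patients$id[i])
      vox <- vox | m$voxels
    }
    if (!any(vox))
      stop(sprintf("patient %s has no implanted hemisphere", patients$id[i]),
           call. = FALSE)
    out[[i]] <- vta_mask(grid, vox, patients$id[i], "bilateral", "modelled")
  }
  out
}
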