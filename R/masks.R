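#' Construct a VTA mask
#'
#' A binary 3-D mask on a [common_grid()] marking the volume of tissue
#' activated (VTA) of one patient, either modelled from stimulation
#' parameters ([rasterize_vta()]) or supplied externally ([read_mask()]).
#'
#' @param grid a [common_grid()].
#' @param voxels logical (or 0/1) 3-D array matching `grid$shape`.
#' @param patient_id identifier string.
#' @param hemisphere one of `"left"`, `"right"`, `"bilateral"`.
#' @param source one of `"modelled"`, `"supplied"`.
#' @return An object of class `"vta_mask"`.
#' @export
vta_mask <- function(grid, voxels, patient_id = NA_character_,
                     hemisphere = c("bilateral", "left", "right"),
                     source = c("modelled", "supplied")) {
  .stopifnot_grid(grid)
  hemisphere <- match.arg(hemisphere)
  source <- match.arg(source)
  voxels <- array(as.logical(voxels), dim = dim(voxels))
  if (!identical(dim(voxels), as.integer(grid$shape)))
    stop("mask dimensions do not match the grid shape", call. = FALSE)
  if (hemisphere != "bilateral" && any(voxels)) {
    x <- grid_axis(grid, 1L)[arrayInd(which(voxels), grid$shape)[, 1L]]
    ok <- if (hemisphere == "left") all(x < 0) else all(x > 0)
    if (!ok)
      stop(sprintf("%s-hemisphere mask has voxels on the wrong side of x = 0",
                   hemisphere), call. = FALSE)
  }
  structure(list(grid = grid, voxels = voxels,
                 patient_id = as.character(patient_id),
                 hemisphere = hemisphere, source = source),
            class = "vta_mask")
}

#' @export
print.vta_mask <- function(x, ...) {
  cat(sprintf("VTA mask: patient %s, %s hemisphere, %s, %d voxels\n",
              x$patient_id, x$hemisphere, x$source, sum(x$voxels)))
  invisible(x)
}

#' Mirror a mask across the midline
#'
#' Maps every nonzero voxel at mm coordinate (x, y, z) to (-x, y, z).
#' Used for motor analyses where patients whose most affected body side is
#' the right are mirrored so that the most affected side is treated as the
#' left in every subject. Applying the flip twice is the identity, and on
#' an x-symmetric grid the voxel count is preserved.
#'
#' @param mask a [vta_mask()].
#' @return The flipped [vta_mask()]; the `hemisphere` field is mirrored too.
#' @export
flip_lr <- function(mask) {
  grid <- mask$grid
  x <- grid_axis(grid, 1L)
  # index that each x column maps onto under x -> -x
  jreal <- (-x - grid$origin_mm[1L]) / grid$voxel_size_mm[1L] + 1
  j <- round(jreal)
  valid <- abs(jreal - j) < 1e-6 & j >= 1 & j <= grid$shape[1L]
  nz_cols <- which(apply(mask$voxels, 1L, any))
  lost <- setdiff(nz_cols, which(valid))
  if (length(lost))
    stop(sprintf(
      "grid is not x-symmetric: %d nonzero voxel column(s) at x = %s mm have no mirror voxel",
      length(lost), paste(signif(x[lost], 4), collapse = ", ")),
      call. = FALSE)
  out <- array(FALSE, grid$shape)
  out[j[valid], , ] <- mask$voxels[valid, , ]
  hemi <- switch(mask$hemisphere, left = "right", right = "left",
                 bilateral = "bilateral")
  vta_mask(grid, out, mask$patient_id, hemi, mask$source)
}

#' Center of mass of a VTA
#'
#' Unweighted mean of the mm coordinates of the nonzero voxel centers,
#' optionally restricted to one hemisphere of a bilateral mask (a
#' lateralized cluster can only be meaningfully distanced from the VTA on
#' its own side).
#'
#' @param mask a [vta_mask()].
#' @param hemisphere `"bilateral"` (all nonzero voxels), `"left"`
#'   (x < 0 only) or `"right"` (x > 0 only).
#' @return Numeric length-3 mm coordinate.
#' @export
vta_center <- function(mask, hemisphere = c("bilateral", "left", "right")) {
  hemisphere <- match.arg(hemisphere)
  idx <- which(mask$voxels)
  if (!length(idx)) stop("empty mask has no center", call. = FALSE)
  mm <- voxel_to_mm(mask$grid, arrayInd(idx, mask$grid$shape))
  if (hemisphere == "left") mm <- mm[mm[, 1L] < 0, , drop = FALSE]
  if (hemisphere == "right") mm <- mm[mm[, 1L] > 0, , drop = FALSE]
  if (!nrow(mm))
    stop(sprintf("mask has no voxels in the %s hemisphere", hemisphere),
         call. = FALSE)
  colMeans(mm)
}
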