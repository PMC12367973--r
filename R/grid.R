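#' Define a common voxel grid
#'
#' All masks and statistical maps in the package live on a shared voxel
#' lattice in RAS millimetre space (+x = right, +y = anterior,
#' +z = superior), the orientation convention of MNI-style common spaces.
#' Voxel indices are 1-based and refer to voxel centers; `origin_mm` is the
#' mm coordinate of the center of voxel `(1, 1, 1)`.
#'
#' The grid must span the midline (`x = 0` mm) on the left-right axis so
#' that hemisphere assignment and left-right flipping are well defined.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm positive numeric vector of length 3, voxel edge
#'   lengths in mm (a scalar is recycled).
#' @param origin_mm mm coordinate of the center of voxel `(1, 1, 1)`.
#'   Exactly one of `origin_mm` and `center_mm` must be given.
#' @param center_mm alternatively, the mm coordinate of the grid center;
#'   the origin is derived so the grid is centered there.
#' @return An object of class `"common_grid"` with fields `shape`,
#'   `voxel_size_mm` and `origin_mm`.
#' @seealso [default_grid()], [mm_to_voxel()], [voxel_to_mm()]
#' @examples
#' g <- common_grid(c(48, 48, 40), 1, center_mm = c(0, -14, -7))
#' voxel_to_mm(g, c(1, 1, 1))
#' @export
common_grid <- function(shape, voxel_size_mm = c(1, 1, 1), origin_mm = NULL,
                        center_mm = NULL) {
  shape <- as.integer(round(shape))
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be three integers >= 1", call. = FALSE)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be three positive numbers", call. = FALSE)
  if (is.null(origin_mm) == is.null(center_mm))
    stop("give exactly one of 'origin_mm' or 'center_mm'", call. = FALSE)
  if (!is.null(center_mm)) {
    center_mm <- as.numeric(center_mm)
    origin_mm <- center_mm - (shape - 1L) / 2 * voxel_size_mm
  }
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("'origin_mm' must be three finite numbers", call. = FALSE)
  g <- structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                      origin_mm = origin_mm),
                 class = "common_grid")
  # midline must be representable: x axis spans negative and positive mm
  xr <- grid_axis(g, 1L)
  if (min(xr) >= 0 || max(xr) <= 0)
    stop("grid does not span the x = 0 mm midline plane", call. = FALSE)
  g
}

#' Default grid for synthetic subthalamic work
#'
#' A 48 x 48 x 40 voxel lattice at 1 mm isotropic resolution centered on
#' (0, -14, -7) mm, large enough to contain both subthalamic regions and
#' small enough to keep permutation testing fast.
#'
#' @return A [common_grid()] object.
#' @export
default_grid <- function() {
  common_grid(c(48L, 48L, 40L), c(1, 1, 1), center_mm = c(0, -14, -7))
}

#' @export
print.common_grid <- function(x, ...) {
  cat("Common voxel grid (RAS)\n")
  cat(sprintf("  shape      : %d x %d x %d voxels\n",
              x$shape[1], x$shape[2], x$shape[3]))
  cat(sprintf("  voxel size : %g x %g x %g mm\n",
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  cat(sprintf("  origin     : (%g, %g, %g) mm at voxel (1,1,1)\n",
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

#' Voxel-center mm coordinates along one axis
#' @param grid a [common_grid()].
#' @param axis axis number 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of voxel-center coordinates in mm.
#' @export
grid_axis <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 1L) *
    grid$voxel_size_mm[axis]
}

#' 4 x 4 voxel-to-mm affine of a grid
#'
#' Maps 1-based voxel indices to RAS mm coordinates of voxel centers.
#' The grid is axis-aligned, so the rotation part is diagonal.
#'
#' @param grid a [common_grid()].
#' @return A 4 x 4 numeric matrix.
#' @export
grid_affine <- function(grid) {
  aff <- diag(4)
  diag(aff)[1:3] <- grid$voxel_size_mm
  # NIfTI xforms map 0-based indices; our voxel (1,1,1) is index (0,0,0)
  aff[1:3, 4] <- grid$origin_mm
  aff
}

#' Convert mm coordinates to voxel indices
#'
#' Returns the index of the voxel whose center is nearest to the given
#' point. Inverse of [voxel_to_mm()] up to rounding (within half a voxel).
#'
#' @param grid a [common_grid()].
#' @param point_mm numeric vector of length 3, or an n x 3 matrix of points.
#' @return Integer vector of length 3 (or n x 3 matrix) of 1-based indices.
#' @export
mm_to_voxel <- function(grid, point_mm) {
  p <- rbind(point_mm)
  if (ncol(p) != 3L) stop("'point_mm' must have 3 columns", call. = FALSE)
  idx <- round(sweep(sweep(p, 2L, grid$origin_mm, "-"), 2L,
                     grid$voxel_size_mm, "/")) + 1
  ax <- c("x", "y", "z")
  for (a in 1:3) {
    bad <- idx[, a] < 1 | idx[, a] > grid$shape[a]
    if (any(bad))
      stop(sprintf("point out of grid bounds on the %s axis (mm %g)",
                   ax[a], p[which(bad)[1], a]), call. = FALSE)
  }
  storage.mode(idx) <- "integer"
  if (is.null(dim(point_mm)) && length(point_mm) == 3L) idx[1, ] else idx
}

#' Convert voxel indices to mm coordinates
#'
#' @param grid a [common_grid()].
#' @param index integer vector of length 3 (1-based), or an n x 3 matrix.
#' @return Numeric vector (or matrix) of voxel-center mm coordinates.
#' @export
voxel_to_mm <- function(grid, index) {
  i <- rbind(index)
  if (ncol(i) != 3L) stop("'index' must have 3 columns", call. = FALSE)
  mm <- sweep(sweep(i - 1, 2L, grid$voxel_size_mm, "*"), 2L,
              grid$origin_mm, "+")
  if (is.null(dim(index)) && length(index) == 3L) mm[1, ] else mm
}

#' Test two grids for compatibility
#'
#' Grids are compatible when shapes match exactly and voxel sizes and
#' origins agree within `tol_mm` (NIfTI headers store the affine in
#' floating point, so exact equality is too strict).
#'
#' @param a,b [common_grid()] objects.
#' @param tol_mm tolerance in mm on voxel size and origin entries.
#' @return Logical scalar.
#' @export
grids_compatible <- function(a, b, tol_mm = 1e-3) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size_mm - b$voxel_size_mm)) <= tol_mm &&
    max(abs(a$origin_mm - b$origin_mm)) <= tol_mm
}

.stopifnot_grid <- function(grid) {
  if (!inherits(grid, "common_grid"))
    stop("expected a 'common_grid' object", call. = FALSE)
  invisible(grid)
}
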