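#' Regular voxel grid
#'
#' Defines the geometry shared by all dose and structure volumes: array
#' shape, physical voxel spacing and the position of the grid corner.
#' Voxel centers sit at \code{origin + (index - 0.5) * spacing} in
#' physical millimetres (1-based array indices), so a grid spans
#' \code{shape * spacing} mm per axis starting at \code{origin}.
#'
#' @param shape integer vector of length 3, array dimensions (x, y, z).
#' @param spacing_mm numeric vector of length 3 (or scalar), strictly
#'   positive voxel spacing in mm. Default 1 mm isotropic, the grid
#'   resolution on which clinical SRS dose distributions are calculated.
#' @param origin_mm numeric vector of length 3 (or scalar), physical
#'   position of the grid corner in mm. Default 0.
#' @return An object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(shape, spacing_mm = 1, origin_mm = 0) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be 3 positive integers")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("'spacing_mm' must be strictly positive on all axes")
  origin_mm <- rep_len(as.numeric(origin_mm), 3L)
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 origin_mm = origin_mm),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d, spacing %s mm, origin (%s) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(format(x$spacing_mm), collapse = " x "),
              paste(format(x$origin_mm), collapse = ", ")))
  invisible(x)
}

#' Physical volume of one voxel in cm^3
#' @param grid a \code{voxel_grid}.
#' @return scalar, voxel volume in cm^3.
#' @export
voxel_volume_cm3 <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing_mm) / 1000
}

#' Voxel-center coordinates along each axis
#'
#' @param grid a \code{voxel_grid}.
#' @return list of three numeric vectors (x, y, z center positions, mm).
#' @export
axis_coords_mm <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  lapply(1:3, function(a)
    grid$origin_mm[a] + (seq_len(grid$shape[a]) - 0.5) * grid$spacing_mm[a])
}

#' Squared physical distance of every voxel center from a point
#'
#' Built from per-axis squared offsets with two outer sums, so no full
#' 3-column coordinate matrix is ever allocated.
#'
#' @param grid a \code{voxel_grid}.
#' @param point_mm numeric length 3, physical position in mm.
#' @return 3D array of squared distances (mm^2) with dim \code{grid$shape}.
#' @export
dist2_from_point <- function(grid, point_mm) {
  ax <- axis_coords_mm(grid)
  dx2 <- (ax[[1]] - point_mm[1])^2
  dy2 <- (ax[[2]] - point_mm[2])^2
  dz2 <- (ax[[3]] - point_mm[3])^2
  array(outer(outer(dx2, dy2, "+"), dz2, "+"), dim = grid$shape)
}

#' Physical coordinates (mm) of voxels given array indices
#' @param grid a \code{voxel_grid}.
#' @param index_matrix integer matrix with 3 columns (1-based i, j, k).
#' @return numeric matrix with 3 columns of physical mm coordinates.
#' @export
index_to_mm <- function(grid, index_matrix) {
  index_matrix <- matrix(as.numeric(index_matrix), ncol = 3)
  sweep(sweep(index_matrix - 0.5, 2, grid$spacing_mm, "*"),
        2, grid$origin_mm, "+")
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

check_same_grid <- function(a, b, what = "objects") {
  if (!same_grid(a, b))
    stop(sprintf("%s do not share one voxel grid", what))
  invisible(TRUE)
}
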