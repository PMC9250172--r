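#' Anatomical roles recognised by the pipeline
#' @export
STRUCTURE_ROLES <- c("brain", "GTV", "PTV", "hippocampus_L", "hippocampus_R",
                     "brainstem", "optic_apparatus", "lens", "derived")

#' Binary structure mask on a voxel grid
#'
#' @param name structure name (unique within a structure set).
#' @param role one of \code{STRUCTURE_ROLES}.
#' @param grid a \code{voxel_grid}.
#' @param voxels logical (or 0/1) 3D array with dim equal to the grid shape.
#' @return object of class \code{structure_mask}.
#' @export
structure_mask <- function(name, role, grid, voxels) {
  stopifnot(inherits(grid, "voxel_grid"))
  role <- match.arg(role, STRUCTURE_ROLES)
  if (!is.array(voxels) || !identical(dim(voxels), grid$shape) &&
      !identical(as.integer(dim(voxels)), grid$shape))
    stop(sprintf("mask '%s': voxel array shape does not match grid", name))
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop(sprintf("mask '%s' contains NA voxels", name))
  structure(list(name = as.character(name), role = role, grid = grid,
                 voxels = voxels),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("structure_mask '%s' (%s): %d voxels, %.3f cm^3\n",
              x$name, x$role, sum(x$voxels), volume_cm3(x)))
  invisible(x)
}

#' Structure volume in cm^3 (voxel count times voxel volume)
#' @param mask a \code{structure_mask}.
#' @return scalar volume in cm^3.
#' @export
volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$voxels) * voxel_volume_cm3(mask$grid)
}

#' @rdname mask_algebra
#' @export
mask_union <- function(a, b, name = paste(a$name, b$name, sep = "+")) {
  check_same_grid(a$grid, b$grid, "masks")
  structure_mask(name, "derived", a$grid, a$voxels | b$voxels)
}

#' Boolean mask algebra
#'
#' \code{mask_subtract} removes the voxels of \code{b} from \code{a}; it is
#' how the healthy-brain structure (brain minus all gross tumor volumes) is
#' built. \code{mask_union} and \code{mask_intersect} are the companion set
#' operations.
#'
#' @param a,b \code{structure_mask} objects on one grid.
#' @param name name for the derived mask.
#' @return a \code{structure_mask} with role \code{"derived"}.
#' @rdname mask_algebra
#' @export
mask_subtract <- function(a, b, name = paste(a$name, b$name, sep = "-")) {
  check_same_grid(a$grid, b$grid, "masks")
  structure_mask(name, "derived", a$grid, a$voxels & !b$voxels)
}

#' @rdname mask_algebra
#' @export
mask_intersect <- function(a, b, name = paste(a$name, b$name, sep = "&")) {
  check_same_grid(a$grid, b$grid, "masks")
  structure_mask(name, "derived", a$grid, a$voxels & b$voxels)
}

#' Union of a list of masks
#' @param masks list of \code{structure_mask} on one grid.
#' @param name name for the derived mask.
#' @return a \code{structure_mask}.
#' @export
mask_union_all <- function(masks, name = "union") {
  stopifnot(length(masks) >= 1)
  v <- masks[[1]]$voxels
  for (m in masks[-1]) {
    check_same_grid(masks[[1]]$grid, m$grid, "masks")
    v <- v | m$voxels
  }
  structure_mask(name, "derived", masks[[1]]$grid, v)
}

#' Named collection of structure masks sharing one grid
#'
#' Holds the full anatomy of one plan: exactly one brain mask, paired
#' GTV/PTV targets and any organs at risk. The \code{gtv_to_ptv_map} pairs
#' each gross tumor volume with the planning target volume derived from it;
#' after merging of close PTVs several GTVs may map to one PTV.
#'
#' @param grid a \code{voxel_grid}.
#' @param masks list of \code{structure_mask} objects (named by structure).
#' @param gtv_to_ptv_map named character vector: names are GTV structure
#'   names, values the partner PTV structure names.
#' @return object of class \code{structure_set}.
#' @export
structure_set <- function(grid, masks, gtv_to_ptv_map) {
  stopifnot(inherits(grid, "voxel_grid"))
  names(masks) <- vapply(masks, `[[`, "", "name")
  for (m in masks) check_same_grid(grid, m$grid, "structure set masks")
  roles <- vapply(masks, `[[`, "", "role")
  if (sum(roles == "brain") != 1L)
    stop("structure set must contain exactly one brain mask")
  gtvs <- names(masks)[roles == "GTV"]
  if (!all(gtvs %in% names(gtv_to_ptv_map)))
    stop("every GTV must have a PTV partner in gtv_to_ptv_map")
  if (!all(gtv_to_ptv_map[gtvs] %in% names(masks)))
    stop("gtv_to_ptv_map refers to PTV masks not present in the set")
  structure(list(grid = grid, masks = masks,
                 gtv_to_ptv_map = gtv_to_ptv_map[gtvs]),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  roles <- vapply(x$masks, `[[`, "", "role")
  cat(sprintf("structure_set: %d masks (%d targets) on %d x %d x %d grid\n",
              length(x$masks), sum(roles == "GTV"),
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}

#' Extract masks of a given role from a structure set
#' @param set a \code{structure_set}.
#' @param role one of \code{STRUCTURE_ROLES}.
#' @return list of \code{structure_mask} (possibly empty).
#' @export
masks_by_role <- function(set, role) {
  role <- match.arg(role, STRUCTURE_ROLES)
  Filter(function(m) m$role == role, set$masks)
}
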