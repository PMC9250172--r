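#' Isotropic margin expansion of a binary mask
#'
#' Grows a structure by a physical margin: the result contains every voxel
#' whose center lies within \code{margin_mm} (Euclidean distance, physical
#' mm) of some voxel center of the input mask. This is the geometric
#' GTV-to-PTV expansion used in SRS planning (default clinical margin
#' 1 mm). Implemented as dilation with the exact Euclidean ball of voxel
#' offsets scaled by the grid spacing, so it is correct for anisotropic
#' spacing and exact under the voxel-center membership convention.
#'
#' Note that a binary mask samples its structure at voxel centers, so the
#' expanded volume systematically underestimates the continuous Minkowski
#' expansion when the margin is comparable to the spacing (about 5-15 per
#' cent for millimetre-scale spheres at 1 mm margin and spacing). When
#' sub-voxel geometry is available (contours, analytic shapes), expand it
#' directly and rasterize once instead.
#'
#' @param mask a non-empty \code{structure_mask}.
#' @param margin_mm non-negative margin in mm.
#' @param name name of the expanded mask (default \code{<name>_exp}).
#' @param role role of the expanded mask (default \code{"derived"}).
#' @return a \code{structure_mask} that is a superset of the input.
#' @export
expand_margin <- function(mask, margin_mm, name = paste0(mask$name, "_exp"),
                          role = "derived") {
  stopifnot(inherits(mask, "structure_mask"))
  if (!is.finite(margin_mm) || margin_mm < 0)
    stop("'margin_mm' must be a non-negative real")
  if (!any(mask$voxels)) stop(sprintf("mask '%s' is empty", mask$name))
  if (margin_mm == 0)
    return(structure_mask(name, role, mask$grid, mask$voxels))

  sp <- mask$grid$spacing_mm
  sh <- mask$grid$shape
  reach <- floor(margin_mm / sp)
  offs <- expand.grid(di = -reach[1]:reach[1], dj = -reach[2]:reach[2],
                      dk = -reach[3]:reach[3])
  d2 <- (offs$di * sp[1])^2 + (offs$dj * sp[2])^2 + (offs$dk * sp[3])^2
  offs <- offs[d2 <= margin_mm^2 + 1e-9, , drop = FALSE]

  # warn when the expansion is truncated by the grid boundary
  idx <- which(mask$voxels, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  if (any(lo - reach < 1) || any(hi + reach > sh))
    warning(sprintf("margin expansion of '%s' clipped to the grid extent",
                    mask$name))

  out <- mask$voxels
  v <- mask$voxels
  for (r in seq_len(nrow(offs))) {
    o <- c(offs$di[r], offs$dj[r], offs$dk[r])
    if (all(o == 0)) next
    src <- lapply(1:3, function(a) max(1, 1 - o[a]):min(sh[a], sh[a] - o[a]))
    dst <- lapply(1:3, function(a) (src[[a]][1] + o[a]):(src[[a]][length(src[[a]])] + o[a]))
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] | v[src[[1]], src[[2]], src[[3]]]
  }
  structure_mask(name, role, mask$grid, out)
}

boundary_voxels <- function(mask) {
  # voxels of the mask with at least one face-neighbor outside it;
  # computed inside the mask's padded bounding box only
  ijk <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(ijk) == 0L) return(ijk)
  sh <- dim(mask$voxels)
  lo <- pmax(apply(ijk, 2, min) - 1L, 1L)
  hi <- pmin(apply(ijk, 2, max) + 1L, sh)
  v <- mask$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  bs <- dim(v)
  if (any(bs < 3)) {
    b <- which(v, arr.ind = TRUE)
  } else {
    core <- v
    core[1, , ] <- core[bs[1], , ] <- FALSE
    core[, 1, ] <- core[, bs[2], ] <- FALSE
    core[, , 1] <- core[, , bs[3]] <- FALSE
    ix <- 2:(bs[1] - 1); iy <- 2:(bs[2] - 1); iz <- 2:(bs[3] - 1)
    core[ix, iy, iz] <- core[ix, iy, iz] &
      v[ix - 1, iy, iz] & v[ix + 1, iy, iz] &
      v[ix, iy - 1, iz] & v[ix, iy + 1, iz] &
      v[ix, iy, iz - 1] & v[ix, iy, iz + 1]
    b <- which(v & !core, arr.ind = TRUE)
  }
  # mask voxels on the grid boundary have no neighbor there: still surface
  sweep(b, 2, lo - 1L, "+")
}

boundary_coords_mm <- function(mask) index_to_mm(mask$grid, boundary_voxels(mask))

min_cross_dist_mm <- function(pa, pb) {
  # minimum Euclidean distance between two point sets (mm), chunked
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(Inf)
  step <- max(1L, floor(2e7 / max(1L, nrow(pb))))
  best <- Inf
  for (s in seq(1L, nrow(pa), by = step)) {
    e <- min(s + step - 1L, nrow(pa))
    chunk <- pa[s:e, , drop = FALSE]
    d2 <- outer(rowSums(chunk^2), rowSums(pb^2), "+") -
      2 * tcrossprod(chunk, pb)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

#' Minimum surface distance between two structures
#'
#' The minimum Euclidean distance (physical mm) between any voxel center of
#' one mask and any voxel center of the other; 0 when the masks share a
#' voxel. Used for the close-PTV merging rule and for the
#' lesion-near-hippocampus proximity test.
#'
#' @param a,b non-empty \code{structure_mask} objects on one grid.
#' @return non-negative scalar distance in mm.
#' @export
surface_distance_mm <- function(a, b) {
  check_same_grid(a$grid, b$grid, "masks")
  if (!any(a$voxels)) stop(sprintf("mask '%s' is empty", a$name))
  if (!any(b$voxels)) stop(sprintf("mask '%s' is empty", b$name))
  if (any(a$voxels & b$voxels)) return(0)
  min_cross_dist_mm(boundary_coords_mm(a), boundary_coords_mm(b))
}

#' Merge structures closer than a distance threshold
#'
#' Structures whose pairwise surface distance is below \code{threshold_mm}
#' are unioned into one; merging is the transitive closure of the pairwise
#' relation, so a chain of close structures becomes a single one. This is
#' the planning rule that treats PTVs closer than 5 mm as one target to
#' keep the maximum dose between neighbouring lesions under control.
#'
#' @param masks list of non-empty \code{structure_mask} on one grid.
#' @param threshold_mm positive distance threshold in mm (merge when
#'   distance is strictly below it).
#' @return list of \code{structure_mask}; merged masks are named by
#'   joining member names with \code{"+"} and carry a \code{members}
#'   attribute (integer indices into the input list). Output order follows
#'   the first member's input index.
#' @export
merge_close_structures <- function(masks, threshold_mm) {
  stopifnot(length(masks) >= 1, threshold_mm > 0)
  n <- length(masks)
  if (n == 1L) {
    attr(masks[[1]], "members") <- 1L
    return(masks)
  }
  for (m in masks[-1]) check_same_grid(masks[[1]]$grid, m$grid, "masks")
  coords <- lapply(masks, boundary_coords_mm)
  full <- lapply(masks, `[[`, "voxels")
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- if (any(full[[i]] & full[[j]])) 0
         else min_cross_dist_mm(coords[[i]], coords[[j]])
    adj[i, j] <- adj[j, i] <- d < threshold_mm
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(seq_len(n), comp)
  groups <- groups[order(vapply(groups, min, 0L))]
  lapply(groups, function(ix) {
    ix <- sort(ix)
    if (length(ix) == 1L) {
      out <- masks[[ix]]
    } else {
      out <- mask_union_all(masks[ix],
                            name = paste(vapply(masks[ix], `[[`, "", "name"),
                                         collapse = "+"))
      roles <- unique(vapply(masks[ix], `[[`, "", "role"))
      if (length(roles) == 1L) out$role <- roles
    }
    attr(out, "members") <- ix
    out
  })
}

connectivity_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  nz <- abs(offs$di) + abs(offs$dj) + abs(offs$dk)
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  offs <- offs[keep, ]
  # one offset per unordered neighbor pair
  offs[offs$dk > 0 | (offs$dk == 0 & offs$dj > 0) |
         (offs$dk == 0 & offs$dj == 0 & offs$di > 0), ]
}

#' Connected components of a binary mask
#'
#' Partitions the mask voxels into maximal connected components under
#' 6-, 18- or 26-connectivity. Labels are deterministic: components are
#' numbered by the scan order (column-major) of their first voxel.
#' 26-connectivity is the default used for isodose clusters, whose thin
#' shells are frequently diagonal-connected.
#'
#' @param mask a \code{structure_mask} (may be empty).
#' @param connectivity 6, 18 or 26.
#' @return list with \code{labels} (integer 3D array, 0 = background),
#'   \code{n} (component count) and \code{sizes} (voxel counts per label).
#' @export
connected_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "structure_mask"))
  sh <- mask$grid$shape
  labels <- array(0L, sh)
  idx <- which(mask$voxels)              # ascending = column-major scan order
  if (length(idx) == 0L)
    return(list(labels = labels, n = 0L, sizes = integer(0)))

  vid <- integer(prod(sh))
  vid[idx] <- seq_along(idx)
  offs <- connectivity_offsets(connectivity)
  lin <- array(seq_len(prod(sh)), sh)
  edges <- vector("list", nrow(offs))
  v <- mask$voxels
  for (r in seq_len(nrow(offs))) {
    o <- c(offs$di[r], offs$dj[r], offs$dk[r])
    src <- lapply(1:3, function(a) max(1, 1 - o[a]):min(sh[a], sh[a] - o[a]))
    dst <- lapply(1:3, function(a) src[[a]] + o[a])
    s <- lin[src[[1]], src[[2]], src[[3]]]
    d <- lin[dst[[1]], dst[[2]], dst[[3]]]
    both <- v[s] & v[d]
    edges[[r]] <- cbind(vid[s[both]], vid[d[both]])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_graph(t(edges), n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel by first occurrence in scan order
  relab <- integer(max(memb))
  relab[unique(memb)] <- seq_along(unique(memb))
  memb <- relab[memb]
  labels[idx] <- memb
  list(labels = labels, n = max(memb), sizes = tabulate(memb))
}
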