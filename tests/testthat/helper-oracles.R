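# Independent oracles used to freeze expected values. Each deliberately
# uses a different algorithm than the package implementation.

# Signed-rank test by explicit enumeration of the 2^n sign-assignment
# matrix (the implementation builds the distribution incrementally).
oracle_signed_rank <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  p <- min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
  list(statistic = w, p_value = p)
}

# Brute-force margin expansion: every grid voxel against every mask voxel
# center (O(N*M); small grids only).
oracle_expand_voxels <- function(mask, margin_mm) {
  g <- mask$grid
  src <- index_to_mm(g, which(mask$voxels, arr.ind = TRUE))
  all_ijk <- as.matrix(expand.grid(seq_len(g$shape[1]), seq_len(g$shape[2]),
                                   seq_len(g$shape[3])))
  pts <- index_to_mm(g, all_ijk)
  hit <- logical(nrow(pts))
  for (s in seq_len(nrow(src))) {
    d2 <- (pts[, 1] - src[s, 1])^2 + (pts[, 2] - src[s, 2])^2 +
      (pts[, 3] - src[s, 3])^2
    hit <- hit | d2 <= margin_mm^2 + 1e-9
  }
  out <- array(FALSE, g$shape)
  out[all_ijk] <- hit
  out
}

# Flood-fill connected components (recursive frontier BFS over an explicit
# neighbor list; the implementation goes through an igraph edge list).
oracle_components <- function(voxels, connectivity) {
  sh <- dim(voxels)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = nz == 1, "18" = nz >= 1 & nz <= 2,
                      "26" = nz >= 1), , drop = FALSE]
  lab <- array(0L, sh)
  nextlab <- 0L
  todo <- which(voxels, arr.ind = TRUE)
  for (row in seq_len(nrow(todo))) {
    p0 <- todo[row, ]
    if (lab[p0[1], p0[2], p0[3]] > 0L) next
    nextlab <- nextlab + 1L
    frontier <- matrix(p0, 1, 3)
    lab[p0[1], p0[2], p0[3]] <- nextlab
    while (nrow(frontier) > 0L) {
      nbr <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o)
        sweep(frontier, 2, offs[o, ], "+")))
      keep <- nbr[, 1] >= 1 & nbr[, 1] <= sh[1] &
        nbr[, 2] >= 1 & nbr[, 2] <= sh[2] &
        nbr[, 3] >= 1 & nbr[, 3] <= sh[3]
      nbr <- nbr[keep, , drop = FALSE]
      keep <- voxels[nbr] & lab[nbr] == 0L
      nbr <- unique(nbr[keep, , drop = FALSE])
      if (nrow(nbr) > 0L) lab[nbr] <- nextlab
      frontier <- nbr
    }
  }
  lab
}

sphere_volume_cm3 <- function(r_mm) 4 / 3 * pi * r_mm^3 / 1000

# small centered grid helper
centered_grid <- function(extent_mm, spacing_mm = 1) {
  n <- ceiling(extent_mm / spacing_mm)
  list(grid = voxel_grid(rep(n, 3), spacing_mm),
       center = rep(n * spacing_mm / 2, 3))
}
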