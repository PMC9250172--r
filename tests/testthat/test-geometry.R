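test_that("margin expansion of a lesion sphere matches its exact oracle", {
  cg <- centered_grid(40)
  r0 <- (3 * 0.16 * 1000 / (4 * pi))^(1 / 3)   # 0.16 cm^3 lesion, r = 3.37 mm
  gtv <- sphere_mask(cg$grid, cg$center, r0, "gtv", "GTV")
  ptv <- expand_margin(gtv, 1, role = "PTV")
  expect_true(all(ptv$voxels[gtv$voxels]))
  expect_identical(ptv$voxels, oracle_expand_voxels(gtv, 1))
  # discrete expansion underestimates the continuous Minkowski volume by
  # O(spacing): strictly below it, but within the small-sphere envelope
  vol_expect <- sphere_volume_cm3(r0 + 1)      # 0.35 cm^3
  expect_lt(volume_cm3(ptv), vol_expect)
  expect_gt(volume_cm3(ptv), 0.8 * vol_expect)
})

test_that("zero margin is the identity and expansion is monotone", {
  cg <- centered_grid(40)
  m <- sphere_mask(cg$grid, cg$center, 4, "m")
  expect_identical(expand_margin(m, 0)$voxels, m$voxels)
  prev <- m
  for (margin in c(0.5, 1, 2, 3.5)) {
    cur <- expand_margin(m, margin)
    expect_true(all(cur$voxels[prev$voxels]))   # superset of smaller margin
    expect_gte(volume_cm3(cur), volume_cm3(prev))
    prev <- cur
  }
})

test_that("margin expansion equals the brute-force distance oracle on a cube", {
  g <- voxel_grid(c(20, 20, 20), 1)
  v <- array(FALSE, g$shape); v[6:15, 6:15, 6:15] <- TRUE  # 10 mm cube
  cube <- structure_mask("cube", "derived", g, v)
  for (margin in c(1, 2.5)) {
    expect_identical(expand_margin(cube, margin)$voxels,
                     oracle_expand_voxels(cube, margin))
  }
})

test_that("margin expansion rejects empty masks and warns when clipped", {
  g <- voxel_grid(c(10, 10, 10), 1)
  empty <- structure_mask("e", "derived", g, array(FALSE, g$shape))
  expect_error(expand_margin(empty, 1), "empty")
  edge <- sphere_mask(g, c(2, 5, 5), 1.2, "edge")
  expect_warning(expand_margin(edge, 3), "clipped")
})

test_that("surface distance recovers center distance minus radii", {
  cg <- centered_grid(40)
  a <- sphere_mask(cg$grid, cg$center - c(10, 0, 0), 2, "a")
  b <- sphere_mask(cg$grid, cg$center + c(10, 0, 0), 2, "b")
  d <- surface_distance_mm(a, b)
  expect_lt(abs(d - 16), sqrt(3) * max(cg$grid$spacing_mm))
  expect_equal(surface_distance_mm(b, a), d)           # symmetry
  expect_equal(surface_distance_mm(a, a), 0)           # identity
  ab <- mask_union(a, expand_margin(a, 1))
  expect_equal(surface_distance_mm(a, ab), 0)          # overlap
  empty <- structure_mask("e", "derived", cg$grid, array(FALSE, cg$grid$shape))
  expect_error(surface_distance_mm(a, empty), "empty")
})

test_that("close-structure merging applies the 5 mm rule transitively", {
  cg <- centered_grid(60)
  r <- 3
  # transverse coordinates on voxel centers so the rasterized spheres
  # reach their full nominal equator
  mk <- function(x, nm) sphere_mask(cg$grid, c(cg$center[1] + x, 29.5, 29.5),
                                    r, nm, "PTV")
  # gap 3 mm (< 5): centers 2r + 3 apart
  two_close <- merge_close_structures(list(mk(-4.5, "p1"), mk(4.5, "p2")), 5)
  expect_length(two_close, 1L)
  expect_identical(attr(two_close[[1]], "members"), 1:2)
  # gap 16 mm (> 5): unchanged
  two_far <- merge_close_structures(list(mk(-11, "p1"), mk(11, "p2")), 5)
  expect_length(two_far, 2L)
  expect_identical(two_far[[1]]$name, "p1")
  # chain: A-B gap 3, B-C gap 3, A-C gap 12 -> one structure
  chain <- list(mk(-9, "A"), mk(0, "B"), mk(9, "C"))
  expect_gt(surface_distance_mm(chain[[1]], chain[[3]]), 5)
  merged <- merge_close_structures(chain, 5)
  expect_length(merged, 1L)
  expect_identical(attr(merged[[1]], "members"), 1:3)
})

test_that("merging is permutation-invariant and preserves the voxel union", {
  cg <- centered_grid(60)
  masks <- list(
    sphere_mask(cg$grid, cg$center + c(-9, 0, 0), 3, "A", "PTV"),
    sphere_mask(cg$grid, cg$center + c(0, 0, 0), 3, "B", "PTV"),
    sphere_mask(cg$grid, cg$center + c(20, 15, 0), 3, "C", "PTV"))
  m1 <- merge_close_structures(masks, 5)
  m2 <- merge_close_structures(rev(masks), 5)
  expect_length(m2, length(m1))
  u <- function(ms) mask_union_all(ms)$voxels
  expect_identical(u(m1), u(masks))
  expect_identical(u(m2), u(masks))
})

test_that("mask subtraction does volume arithmetic and restores with union", {
  cg <- centered_grid(40)
  brain <- sphere_mask(cg$grid, cg$center, 18, "brain", "brain")
  g1 <- sphere_mask(cg$grid, cg$center + c(-8, 0, 0), 3, "g1", "GTV")
  g2 <- sphere_mask(cg$grid, cg$center + c(8, 0, 0), 3, "g2", "GTV")
  empty <- structure_mask("e", "derived", cg$grid, array(FALSE, cg$grid$shape))
  expect_identical(mask_subtract(brain, empty)$voxels, brain$voxels)
  expect_equal(volume_cm3(mask_subtract(brain, brain)), 0)
  healthy <- mask_subtract(mask_subtract(brain, g1), g2)
  expect_equal(volume_cm3(healthy),
               volume_cm3(brain) - volume_cm3(g1) - volume_cm3(g2))
  # subtract then union with the removed intersection restores the mask
  restored <- mask_union(mask_subtract(brain, g1), mask_intersect(brain, g1))
  expect_identical(restored$voxels, brain$voxels)
})

test_that("connected components match a flood-fill oracle", {
  cg <- centered_grid(30)
  two <- mask_union(sphere_mask(cg$grid, cg$center - c(8, 0, 0), 3, "a"),
                    sphere_mask(cg$grid, cg$center + c(8, 0, 0), 3, "b"))
  cc <- connected_components(two, 26)
  expect_identical(cc$n, 2L)
  expect_identical(sum(cc$sizes), sum(two$voxels))

  empty <- structure_mask("e", "derived", cg$grid, array(FALSE, cg$grid$shape))
  expect_identical(connected_components(empty)$n, 0L)

  # two blocks joined by one diagonal voxel: connected only diagonally
  g <- voxel_grid(c(12, 12, 12), 1)
  v <- array(FALSE, g$shape)
  v[2:4, 2:4, 2:4] <- TRUE; v[6:8, 6:8, 6:8] <- TRUE
  v[5, 5, 5] <- TRUE
  bridged <- structure_mask("br", "derived", g, v)
  expect_identical(connected_components(bridged, 26)$n, 1L)
  expect_gt(connected_components(bridged, 6)$n, 1L)

  set.seed(42)
  for (conn in c(6, 18, 26)) {
    v <- array(stats::runif(10^3) < 0.25, c(10, 10, 10))
    m <- structure_mask("r", "derived", voxel_grid(c(10, 10, 10), 1), v)
    got <- connected_components(m, conn)
    want <- oracle_components(v, conn)
    expect_identical(got$n, max(want))
    # same partition: labels must be a bijection of the oracle labels
    expect_identical(sort(got$sizes), sort(tabulate(want[want > 0L])))
    pairs <- table(got$labels[v], want[v])
    expect_true(all(rowSums(pairs > 0) == 1) && all(colSums(pairs > 0) == 1))
  }
})

test_that("component labels follow scan order deterministically", {
  g <- voxel_grid(c(10, 10, 10), 1)
  v <- array(FALSE, g$shape)
  v[8, 8, 8] <- TRUE          # later in column-major scan
  v[2, 2, 2] <- TRUE          # first in scan order
  cc <- connected_components(structure_mask("m", "derived", g, v), 6)
  expect_identical(cc$labels[2, 2, 2], 1L)
  expect_identical(cc$labels[8, 8, 8], 2L)
})
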