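make_uniform_plan <- function(dose_in = 20, dose_out = 0, r = 6,
                              extent = 30) {
  cg <- centered_grid(extent)
  m <- sphere_mask(cg$grid, cg$center, r, "ptv", "PTV")
  d <- array(dose_out, cg$grid$shape)
  d[m$voxels] <- dose_in
  list(dose = dose_grid(cg$grid, d), mask = m, cg = cg)
}

test_that("cumulative DVH starts at structure volume and matches V_xGy", {
  p <- make_uniform_plan(20)
  dvh <- cumulative_dvh(p$dose, p$mask, 0.5)
  expect_equal(dvh$volume_cm3[1], volume_cm3(p$mask))
  expect_true(all(diff(dvh$volume_cm3) <= 0))
  expect_true(all(dvh$volume_cm3[dvh$dose_Gy <= 20] == volume_cm3(p$mask)))
  expect_true(all(dvh$volume_cm3[dvh$dose_Gy > 20] == 0))
  # half the mask at 10 Gy, half at 20 Gy: step to 50% volume above 10
  v <- which(p$mask$voxels)
  d2 <- array(0, p$cg$grid$shape)
  d2[v[seq_len(floor(length(v) / 2))]] <- 10
  d2[v[(floor(length(v) / 2) + 1):length(v)]] <- 20
  dose2 <- dose_grid(p$cg$grid, d2)
  dvh2 <- cumulative_dvh(dose2, p$mask, 1)
  for (edge in c(0, 5, 10, 15, 20, 21))
    expect_equal(dvh2$volume_cm3[match(edge, dvh2$dose_Gy)],
                 volume_at_dose(dose2, p$mask, edge))
  expect_equal(volume_at_dose(dose2, p$mask, 15) / volume_cm3(p$mask), 0.5,
               tolerance = 0.01)
  expect_error(cumulative_dvh(p$dose, p$mask, 0), "positive")
})

test_that("volume at dose counts closed-threshold voxels", {
  p <- make_uniform_plan(13)
  for (th in c(5, 8, 10, 12, 13))
    expect_equal(volume_at_dose(p$dose, p$mask, th), volume_cm3(p$mask))
  expect_equal(volume_at_dose(p$dose, p$mask, 13.01), 0)
})

test_that("isodose volumes of the radial kernel match closed-form radii", {
  cg <- centered_grid(50)
  kp <- kernel_params(1.383)
  r <- sqrt(dist2_from_point(cg$grid, cg$center))
  dose <- dose_grid(cg$grid, array(radial_dose(r, 5, 20, kp), cg$grid$shape))
  brain <- sphere_mask(cg$grid, cg$center, 24, "brain", "brain")
  for (th in c(12, 13.5, 16)) {
    r_iso <- 5 * (20 / th)^(1 / 1.383)   # invert PD*(R/r)^k = th
    expect_equal(volume_at_dose(dose, brain, th), sphere_volume_cm3(r_iso),
                 tolerance = 0.05)
  }
})

test_that("dose at volume fraction is the sorted-voxel quantile", {
  p <- make_uniform_plan(20)
  expect_equal(dose_at_volume_fraction(p$dose, p$mask, 0.02), 20)
  # 1000-voxel mask with the 20 hottest voxels at 26 Gy
  g <- voxel_grid(c(10, 10, 10), 1)
  m <- structure_mask("m", "derived", g, array(TRUE, g$shape))
  d <- array(20, g$shape); d[1:20] <- 26
  dd <- dose_grid(g, d)
  expect_equal(dose_at_volume_fraction(dd, m, 0.02), 26)
  expect_equal(dose_at_volume_fraction(dd, m, 0.021), 20)
  expect_equal(dose_at_volume_fraction(dd, m, 1), 20)     # minimum dose
  d[5] <- 3; expect_equal(dose_at_volume_fraction(dose_grid(g, d), m, 1), 3)
  expect_error(dose_at_volume_fraction(dd, m, 0), "fraction")
})

test_that("mean dose matches a brute-force sum", {
  g <- voxel_grid(c(8, 8, 8), 1)
  m <- sphere_mask(g, c(4, 4, 4), 3, "m")
  set.seed(1)
  d <- array(stats::runif(8^3, 0, 25), g$shape)
  dd <- dose_grid(g, d)
  expect_equal(mean_dose(dd, m), sum(d[m$voxels]) / sum(m$voxels),
               tolerance = 1e-12)
  expect_equal(mean_dose(dose_grid(g, array(7, g$shape)), m), 7)
})

test_that("coverage is the exact voxel fraction at prescription", {
  p <- make_uniform_plan(20)
  expect_equal(coverage_percent(p$dose, p$mask, 20), 100)
  expect_equal(coverage_percent(p$dose, p$mask, 20.5), 0)
  g <- voxel_grid(c(10, 10, 10), 1)
  v <- array(FALSE, g$shape); v[1:100] <- TRUE
  m <- structure_mask("m", "PTV", g, v)
  d <- array(0, g$shape); d[1:98] <- 20
  expect_equal(coverage_percent(dose_grid(g, d), m, 20), 98)
})

test_that("Paddick CI hits its analytic limits", {
  # prescription isodose voxel set == PTV -> exactly 1
  p <- make_uniform_plan(20, dose_out = 11)
  expect_equal(paddick_ci(p$dose, p$mask, 20), 1)
  # concentric spheres: PTV r=5 covered, isodose r=6 -> ratio of volumes
  cg <- centered_grid(30)
  ptv <- sphere_mask(cg$grid, cg$center, 5, "ptv", "PTV")
  iso <- sphere_mask(cg$grid, cg$center, 6, "iso")
  d <- array(0, cg$grid$shape); d[iso$voxels] <- 20
  ci <- paddick_ci(dose_grid(cg$grid, d), ptv, 20)
  expect_equal(ci, sphere_volume_cm3(5) / sphere_volume_cm3(6),  # 0.5787
               tolerance = 0.05)
  # disjoint isodose and PTV -> 0
  far <- sphere_mask(cg$grid, cg$center + c(10, 0, 0), 3, "far")
  d2 <- array(0, cg$grid$shape); d2[far$voxels] <- 20
  expect_equal(paddick_ci(dose_grid(cg$grid, d2), ptv, 20), 0)
  # no prescription isodose at all -> 0 with warning
  expect_warning(
    ci0 <- paddick_ci(dose_grid(cg$grid, array(1, cg$grid$shape)), ptv, 20),
    "CI")
  expect_equal(ci0, 0)
})

test_that("gradient index is 1 for a step dose and errors without isodose", {
  p <- make_uniform_plan(20, dose_out = 0, r = 7)
  expect_equal(gradient_index(p$dose, 20), 1)
  expect_gte(gradient_index(p$dose, 25 / 2), 1)
  expect_error(gradient_index(p$dose, 25), "undefined")
})

test_that("V12 clusters partition the healthy-brain hot volume", {
  cg <- centered_grid(80)
  kp <- kernel_params(1.383)
  brain <- sphere_mask(cg$grid, cg$center, 38, "brain", "brain")
  mk_dose <- function(centers) {
    d <- array(0, cg$grid$shape)
    for (cn in centers) {
      r <- sqrt(dist2_from_point(cg$grid, cn))
      d <- d + radial_dose(r, 4, 20, kp)
    }
    dose_grid(cg$grid, d)
  }
  g1 <- sphere_mask(cg$grid, cg$center - c(15, 0, 0), 3, "g1", "GTV")
  g2 <- sphere_mask(cg$grid, cg$center + c(15, 0, 0), 3, "g2", "GTV")

  # far apart: one cluster per lesion, each tagged with its own GTV
  far <- v12_cluster_volumes(mk_dose(list(cg$center - c(15, 0, 0),
                                          cg$center + c(15, 0, 0))),
                             brain, list(g1, g2))
  expect_identical(nrow(far$clusters), 2L)
  expect_setequal(far$clusters$gtvs, c("g1", "g2"))
  expect_equal(sum(far$clusters$volume_cm3), far$total_cm3,
               tolerance = 1e-12)

  # close lesions: bridged shells merge into one cluster with both GTVs
  g1c <- sphere_mask(cg$grid, cg$center - c(4, 0, 0), 3, "g1", "GTV")
  g2c <- sphere_mask(cg$grid, cg$center + c(4, 0, 0), 3, "g2", "GTV")
  near <- v12_cluster_volumes(mk_dose(list(cg$center - c(4, 0, 0),
                                           cg$center + c(4, 0, 0))),
                              brain, list(g1c, g2c))
  expect_identical(nrow(near$clusters), 1L)
  expect_identical(near$clusters$n_gtvs, 2L)
  expect_setequal(strsplit(near$clusters$gtvs, ",")[[1]], c("g1", "g2"))

  # nothing above threshold
  none <- v12_cluster_volumes(dose_grid(cg$grid, array(1, cg$grid$shape)),
                              brain, list(g1, g2))
  expect_identical(nrow(none$clusters), 0L)
  expect_equal(none$total_cm3, 0)
})
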