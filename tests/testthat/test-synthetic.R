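test_that("the radial kernel hits its anchor points", {
  for (k in c(1.207, 1.383, 3)) {
    kp <- kernel_params(k, hot_ratio = 1.25)
    R <- 4.4; pd <- 20
    expect_equal(radial_dose(0, R, pd, kp), 1.25 * pd)
    expect_equal(radial_dose(R, R, pd, kp), pd)
    expect_equal(radial_dose(R * 2^(1 / k), R, pd, kp), pd / 2)
    # nonincreasing in r and continuous across the taper start
    r <- seq(0, 60, by = 0.05)
    d <- radial_dose(r, R, pd, kp)
    expect_true(all(diff(d) <= 1e-9))
    r_t <- kp$taper_start * R * 2^(1 / k)
    expect_equal(radial_dose(r_t - 1e-9, R, pd, kp),
                 radial_dose(r_t + 1e-9, R, pd, kp), tolerance = 1e-6)
  }
})

make_two_lesion_patient <- function(gap_mm, spacing = 1) {
  cg <- centered_grid(70, spacing)
  brain <- sphere_mask(cg$grid, cg$center, 32, "brain", "brain")
  dx <- (gap_mm + 2 * 4) / 2   # PTV radius 4: centers give the stated gap
  mk <- function(s, nm, role, r) sphere_mask(cg$grid, cg$center + c(s, 0, 0),
                                             r, nm, role)
  set <- structure_set(cg$grid,
                       list(brain = brain,
                            gtv01 = mk(-dx, "gtv01", "GTV", 3),
                            gtv02 = mk(dx, "gtv02", "GTV", 3),
                            ptv01 = mk(-dx, "ptv01", "PTV", 4),
                            ptv02 = mk(dx, "ptv02", "PTV", 4)),
                       c(gtv01 = "ptv01", gtv02 = "ptv02"))
  lesions <- data.frame(
    gtv_name = c("gtv01", "gtv02"), ptv_name = c("ptv01", "ptv02"),
    x_mm = cg$center[1] + c(-dx, dx), y_mm = cg$center[2],
    z_mm = cg$center[3], gtv_radius_mm = 3, radius_mm = 4,
    gtv_volume_cm3 = sphere_volume_cm3(3), prescription_Gy = 20)
  structure(list(patient_id = 1L, structures = set, lesions = lesions,
                 prescriptions = c(gtv01 = 20, gtv02 = 20),
                 near_hippocampus = FALSE, ipsilateral = NA_character_,
                 doses = NULL, seed = 0L),
            class = "synthetic_patient")
}

test_that("an isolated lesion reproduces the closed-form gradient index", {
  cg <- centered_grid(70)
  brain <- sphere_mask(cg$grid, cg$center, 32, "brain", "brain")
  set <- structure_set(
    cg$grid,
    list(brain = brain,
         gtv01 = sphere_mask(cg$grid, cg$center, 3, "gtv01", "GTV"),
         ptv01 = sphere_mask(cg$grid, cg$center, 4, "ptv01", "PTV")),
    c(gtv01 = "ptv01"))
  lesions <- data.frame(gtv_name = "gtv01", ptv_name = "ptv01",
                        x_mm = cg$center[1], y_mm = cg$center[2],
                        z_mm = cg$center[3], gtv_radius_mm = 3,
                        radius_mm = 4, gtv_volume_cm3 = sphere_volume_cm3(3),
                        prescription_Gy = 20)
  pat <- structure(list(patient_id = 1L, structures = set, lesions = lesions,
                        prescriptions = c(gtv01 = 20),
                        near_hippocampus = FALSE, doses = NULL, seed = 0L),
                   class = "synthetic_patient")
  for (k in c(1.383, 3)) {
    dose <- compose_plan_dose(pat, kernel_params(k, bath_fraction = 0))
    m <- evaluate_plan(dose, set, c(gtv01 = 20),
                       metrics = c("targets", "brain"))
    expect_equal(m$coverage_percent, 100)
    expect_equal(m$gi, 2^(3 / k), tolerance = 0.05)
    expect_gt(m$ci, 0.8)
  }
})

test_that("superposition bridges the dose between adjacent lesions", {
  pat <- make_two_lesion_patient(gap_mm = 6)
  kp <- kernel_params(1.383, bath_fraction = 0)
  dose <- compose_plan_dose(pat, kp)
  cg_center <- pat$structures$grid$shape / 2  # midpoint voxel index
  mid <- dose$dose[cg_center[1], cg_center[2], cg_center[3]]
  # each lesion center is 7 mm from the midpoint
  single <- radial_dose(7, 4, 20, kp)
  expect_gt(mid, single)
  expect_equal(mid, 2 * single, tolerance = 0.05)
  # zero lesions is an error
  pat0 <- pat; pat0$lesions <- pat$lesions[0, ]
  expect_error(compose_plan_dose(pat0, kp), "no lesions")
  # a lesion outside the brain is an error
  patx <- pat; patx$lesions$x_mm[1] <- 1
  expect_error(compose_plan_dose(patx, kp), "outside brain")
})

test_that("cohort generation is reproducible and respects the samplers", {
  spec <- cohort_spec(n_patients = 4, seed = 99, spacing_mm = 2.5)
  c1 <- generate_cohort(spec, compose_doses = FALSE)
  c2 <- generate_cohort(spec, compose_doses = FALSE)
  for (i in seq_along(c1)) {
    expect_identical(c1[[i]]$lesions, c2[[i]]$lesions)
    expect_identical(c1[[i]]$near_hippocampus, c2[[i]]$near_hippocampus)
  }
  les <- do.call(rbind, lapply(c1, `[[`, "lesions"))
  expect_true(all(les$gtv_volume_cm3 >= 0.07 & les$gtv_volume_cm3 <= 2.1))
  expect_true(all(les$prescription_Gy %in% c(18, 20)))
  counts <- vapply(c1, function(p) nrow(p$lesions), 0L)
  expect_true(all(counts >= 2 & counts <= 25))
})

test_that("the volume and count samplers are calibrated to the cohort", {
  set.seed(7)
  vols <- srsdosim:::sample_clipped_lognormal(2000, log(0.16), 0.45,
                                              c(0.07, 2.1))
  expect_lt(abs(stats::median(vols) - 0.16) / 0.16, 0.2)
  expect_true(all(vols >= 0.07 & vols <= 2.1))
  counts <- srsdosim:::sample_clipped_lognormal(2000, log(9), 0.55,
                                                c(2, 25), round_to = TRUE)
  expect_true(stats::median(counts) >= 8 && stats::median(counts) <= 10)
  expect_gt(mean(counts > 10), 0.25)   # a large >10-lesion stratum
})

test_that("paired techniques share anatomy and a near-hippocampus lesion is forced", {
  spec <- cohort_spec(n_patients = 3, seed = 5, spacing_mm = 2.5,
                      near_hippocampus_fraction = 1 / 3)
  cohort <- generate_cohort(spec)
  expect_identical(sum(vapply(cohort, `[[`, TRUE, "near_hippocampus")), 1L)
  for (p in cohort) {
    expect_named(p$doses, c("DCAT", "VMAT"))
    # same structures object, different dose
    expect_identical(p$doses$DCAT$grid, p$doses$VMAT$grid)
    expect_gt(max(abs(p$doses$DCAT$dose - p$doses$VMAT$dose)), 0)
    if (p$near_hippocampus) {
      expect_lt(min(p$hippocampus_distance_mm), 5)
      expect_true(p$ipsilateral %in% c("L", "R"))
    }
  }
})
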