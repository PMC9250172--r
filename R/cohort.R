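#' Analytic ellipsoid / sphere masks
#'
#' Rasterize an ellipsoid (voxel-center membership) onto a grid. Used to
#' build the synthetic anatomy: brain, hippocampi, brainstem, optic
#' apparatus, lens.
#'
#' @param grid a \code{voxel_grid}.
#' @param center_mm physical center, mm.
#' @param semi_axes_mm semi-axis lengths, mm (scalar for a sphere).
#' @param name,role mask name and role.
#' @return a \code{structure_mask}.
#' @export
ellipsoid_mask <- function(grid, center_mm, semi_axes_mm, name,
                           role = "derived") {
  semi_axes_mm <- rep_len(semi_axes_mm, 3L)
  ax <- axis_coords_mm(grid)
  u2 <- lapply(1:3, function(a) ((ax[[a]] - center_mm[a]) / semi_axes_mm[a])^2)
  v <- array(outer(outer(u2[[1]], u2[[2]], "+"), u2[[3]], "+") <= 1,
             dim = grid$shape)
  structure_mask(name, role, grid, v)
}

#' @rdname ellipsoid_mask
#' @param radius_mm sphere radius, mm.
#' @export
sphere_mask <- function(grid, center_mm, radius_mm, name, role = "derived") {
  ellipsoid_mask(grid, center_mm, rep(radius_mm, 3), name, role)
}

#' Synthetic cranial anatomy
#'
#' Builds the fixed anatomy every synthetic patient shares: a ~1400 cm^3
#' ellipsoidal brain, two hippocampi, a brainstem, the optic apparatus and
#' the lenses, all as analytic ellipsoids at fixed anatomical offsets on a
#' grid that encloses them with a small pad. Axes: x lateral, y
#' posterior-anterior, z inferior-superior, origin at the grid corner.
#'
#' @param spacing_mm isotropic voxel spacing in mm (default 1, the grid
#'   resolution of clinical SRS dose calculations).
#' @param brain_semi_axes_mm brain ellipsoid semi-axes (default
#'   c(82, 68, 60) mm, i.e. 1401 cm^3).
#' @param pad_mm grid pad beyond the widest structure.
#' @return list with \code{grid}, \code{masks} (named list of
#'   \code{structure_mask}), \code{brain_center_mm},
#'   \code{brain_semi_axes_mm} and \code{hippocampi} (per-side center and
#'   semi-axes, used by the lesion placer).
#' @export
build_anatomy <- function(spacing_mm = 1,
                          brain_semi_axes_mm = c(82, 68, 60),
                          pad_mm = 6) {
  stopifnot(spacing_mm > 0, all(brain_semi_axes_mm > 0))
  half <- c(brain_semi_axes_mm[1], brain_semi_axes_mm[2] + 8,
            brain_semi_axes_mm[3]) + pad_mm
  shape <- ceiling(2 * half / spacing_mm)
  grid <- voxel_grid(shape, spacing_mm, 0)
  C <- shape * spacing_mm / 2            # brain center

  off <- function(d) C + d
  hip <- list(
    L = list(center = off(c(-26, -8, -18)), axes = c(7, 16, 7)),
    R = list(center = off(c(+26, -8, -18)), axes = c(7, 16, 7)))
  masks <- list(
    brain = ellipsoid_mask(grid, C, brain_semi_axes_mm, "brain", "brain"),
    hippocampus_L = ellipsoid_mask(grid, hip$L$center, hip$L$axes,
                                   "hippocampus_L", "hippocampus_L"),
    hippocampus_R = ellipsoid_mask(grid, hip$R$center, hip$R$axes,
                                   "hippocampus_R", "hippocampus_R"),
    brainstem = ellipsoid_mask(grid, off(c(0, -6, -32)), c(11, 13, 26),
                               "brainstem", "brainstem"),
    optic_apparatus = ellipsoid_mask(grid, off(c(0, 34, -20)), c(18, 8, 4),
                                     "optic_apparatus", "optic_apparatus"),
    lens = mask_union(
      sphere_mask(grid, off(c(-26, brain_semi_axes_mm[2] + 4, -16)), 4, "lens_L"),
      sphere_mask(grid, off(c(+26, brain_semi_axes_mm[2] + 4, -16)), 4, "lens_R"),
      name = "lens"))
  masks$lens$role <- "lens"
  masks$lens$name <- "lens"
  # analytic definitions kept for the lesion placer (OAR avoidance)
  oars <- list(
    brainstem = list(center = off(c(0, -6, -32)), axes = c(11, 13, 26)),
    optic_apparatus = list(center = off(c(0, 34, -20)), axes = c(18, 8, 4)),
    lens_L = list(center = off(c(-26, brain_semi_axes_mm[2] + 4, -16)),
                  axes = c(4, 4, 4)),
    lens_R = list(center = off(c(+26, brain_semi_axes_mm[2] + 4, -16)),
                  axes = c(4, 4, 4)))
  # hippocampus boundary coordinates, cached for proximity tests
  hip$L$boundary_mm <- boundary_coords_mm(masks$hippocampus_L)
  hip$R$boundary_mm <- boundary_coords_mm(masks$hippocampus_R)
  list(grid = grid, masks = masks, brain_center_mm = C,
       brain_semi_axes_mm = brain_semi_axes_mm, hippocampi = hip,
       oars = oars)
}

#' Specification of a synthetic paired cohort
#'
#' Parameters of the cohort generator, defaulting to the composition of a
#' 36-patient multi-met SRS series: 2-25 lesions per patient (median 9,
#' about half the patients above 10), per-lesion GTV volumes lognormal
#' with median 0.16 cm^3 clipped to [0.07, 2.1] cm^3, prescriptions of
#' 18 or 20 Gy (18 Gy for ~3% of lesions), a 1 mm GTV-to-PTV margin, PTVs
#' closer than 5 mm merged into one target, and one patient in six with a
#' lesion within 5 mm of a hippocampus. Both arms of a pair share the
#' anatomy and lesions and differ only in the dose kernel.
#'
#' @param n_patients number of patients.
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @param spacing_mm voxel spacing of the shared grid.
#' @param margin_mm GTV-to-PTV margin (default 1 mm).
#' @param merge_threshold_mm PTVs with surface distance below this are
#'   merged into one target (default 5 mm).
#' @param lesion_count_meanlog,lesion_count_sdlog lognormal parameters of
#'   the per-patient lesion count, rounded and resampled into
#'   \code{lesion_count_range}.
#' @param lesion_count_range inclusive bounds on the lesion count.
#' @param gtv_meanlog,gtv_sdlog lognormal parameters of per-lesion GTV
#'   volume (cm^3), resampled into \code{gtv_range_cm3}.
#' @param gtv_range_cm3 inclusive bounds on per-lesion GTV volume.
#' @param fraction_18Gy probability a lesion is prescribed 18 Gy rather
#'   than 20 Gy.
#' @param near_hippocampus_fraction fraction of patients forced to have a
#'   lesion within 5 mm of one hippocampus.
#' @param techniques named list of \code{kernel_params}, one per arm.
#' @param separation_gap_mm extra center-to-center clearance added to the
#'   sum of the two PTV radii when placing lesions (0 keeps the default
#'   just-touching-PTV regime; negative values force close pairs).
#' @param max_place_attempts rejection-sampling budget per lesion.
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_patients = 36, seed = 1, spacing_mm = 1,
                        margin_mm = 1, merge_threshold_mm = 5,
                        lesion_count_meanlog = log(9),
                        lesion_count_sdlog = 0.55,
                        lesion_count_range = c(2L, 25L),
                        gtv_meanlog = log(0.16), gtv_sdlog = 0.45,
                        gtv_range_cm3 = c(0.07, 2.1),
                        fraction_18Gy = 11 / 367,
                        near_hippocampus_fraction = 6 / 36,
                        techniques = default_techniques(),
                        separation_gap_mm = 0,
                        max_place_attempts = 5000) {
  stopifnot(n_patients >= 1, spacing_mm > 0, margin_mm >= 0,
            merge_threshold_mm > 0,
            lesion_count_range[1] >= 1,
            lesion_count_range[2] >= lesion_count_range[1],
            gtv_range_cm3[1] > 0, gtv_range_cm3[2] > gtv_range_cm3[1],
            fraction_18Gy >= 0, fraction_18Gy <= 1,
            near_hippocampus_fraction >= 0, near_hippocampus_fraction <= 1,
            length(techniques) >= 1)
  for (t in techniques) stopifnot(inherits(t, "kernel_params"))
  spec <- as.list(environment())
  class(spec) <- "cohort_spec"
  spec
}

gtv_radius_mm <- function(volume_cm3) (3 * volume_cm3 * 1000 / (4 * pi))^(1 / 3)

sample_clipped_lognormal <- function(n, meanlog, sdlog, range, round_to = NULL) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, meanlog, sdlog)
    if (!is.null(round_to)) x <- round(x)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

ellipsoid_radius_along <- function(axes, v) 1 / sqrt(sum((v / axes)^2))

inside_eroded_brain <- function(p, anatomy, clearance_mm) {
  ax <- anatomy$brain_semi_axes_mm - clearance_mm
  all(ax > 0) &&
    sum(((p - anatomy$brain_center_mm) / ax)^2) <= 1
}

place_lesions <- function(spec, anatomy, radii_mm, near_hippocampus) {
  n <- length(radii_mm)
  centers <- matrix(NA_real_, n, 3)
  ptv_r <- radii_mm + spec$margin_mm
  C <- anatomy$brain_center_mm
  bb <- anatomy$brain_semi_axes_mm
  attempts <- 0L

  sep_ok <- function(i, p) {
    if (i == 1L) return(TRUE)
    prev <- seq_len(i - 1L)
    d <- sqrt(rowSums((centers[prev, , drop = FALSE] -
                         matrix(p, i - 1L, 3, byrow = TRUE))^2))
    all(d >= ptv_r[i] + ptv_r[prev] + spec$separation_gap_mm)
  }

  oar_ok <- function(i, p) {
    # keep the ~12 Gy shell (about 1.6 x PTV radius) off serial OARs,
    # as a clinical optimizer would
    clear <- 1.7 * ptv_r[i] + 2
    for (o in anatomy$oars)
      if (sum(((p - o$center) / (o$axes + clear))^2) <= 1) return(FALSE)
    TRUE
  }

  hippo_ok <- function(i, p, forced) {
    # the < 5 mm hippocampus proximity subgroup is a controlled parameter:
    # only the forced lesion may come close, every other lesion keeps
    # clearance beyond the 5 mm proximity band
    if (forced) return(TRUE)
    clear <- 5 + radii_mm[i] + 2 * spec$spacing_mm
    for (h in anatomy$hippocampi[c("L", "R")])
      if (sum(((p - h$center) / (h$axes + clear))^2) <= 1) return(FALSE)
    TRUE
  }

  for (i in seq_len(n)) {
    placed <- FALSE
    clearance <- ptv_r[i] + 2 * spec$spacing_mm
    while (!placed) {
      attempts <- attempts + 1L
      if (attempts > spec$max_place_attempts)
        stop("lesion placement failed after ", spec$max_place_attempts,
             " attempts")
      if (i == 1L && near_hippocampus) {
        # seed one lesion just outside a hippocampus surface (< 5 mm gap)
        side <- sample(c("L", "R"), 1)
        hp <- anatomy$hippocampi[[side]]
        v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
        gap <- stats::runif(1, 0.5, 4)
        p <- hp$center + v * (ellipsoid_radius_along(hp$axes, v) +
                                radii_mm[i] + gap)
      } else {
        p <- C + (stats::runif(3) * 2 - 1) * bb
      }
      forced <- i == 1L && near_hippocampus
      if (inside_eroded_brain(p, anatomy, clearance) && oar_ok(i, p) &&
          hippo_ok(i, p, forced) && sep_ok(i, p))
        placed <- TRUE
    }
    centers[i, ] <- p
  }
  centers
}

#' Generate one synthetic patient
#'
#' Draws lesion count, volumes and prescriptions, places the lesions in
#' the brain, rasterizes GTVs (spheres) and PTVs (spheres grown by the
#' margin), merges PTVs closer than the threshold, and optionally composes
#' the paired dose grids. Consumes the current RNG stream; call within
#' \code{\link{generate_cohort}} for seeded reproducibility.
#'
#' @param spec a \code{cohort_spec}.
#' @param anatomy shared anatomy from \code{\link{build_anatomy}}.
#' @param patient_id integer id.
#' @param near_hippocampus force one lesion within 5 mm of a hippocampus.
#' @param compose_doses also compute the paired dose grids.
#' @return object of class \code{synthetic_patient}.
#' @export
generate_patient <- function(spec, anatomy, patient_id,
                             near_hippocampus = FALSE,
                             compose_doses = TRUE) {
  n_les <- as.integer(sample_clipped_lognormal(
    1, spec$lesion_count_meanlog, spec$lesion_count_sdlog,
    spec$lesion_count_range, round_to = TRUE))
  vols <- sample_clipped_lognormal(n_les, spec$gtv_meanlog, spec$gtv_sdlog,
                                   spec$gtv_range_cm3)
  radii <- gtv_radius_mm(vols)
  pds <- ifelse(stats::runif(n_les) < spec$fraction_18Gy, 18, 20)
  centers <- tryCatch(
    place_lesions(spec, anatomy, radii, near_hippocampus),
    error = function(e) stop("patient ", patient_id, ": ",
                             conditionMessage(e)))

  grid <- anatomy$grid
  gtv_names <- sprintf("gtv%02d", seq_len(n_les))
  gtvs <- lapply(seq_len(n_les), function(i)
    sphere_mask(grid, centers[i, ], radii[i], gtv_names[i], "GTV"))
  ptvs <- lapply(seq_len(n_les), function(i)
    sphere_mask(grid, centers[i, ], radii[i] + spec$margin_mm,
                sprintf("ptv%02d", i), "PTV"))
  merged <- merge_close_structures(ptvs, spec$merge_threshold_mm)
  map <- character(0)
  for (m in merged) for (ix in attr(m, "members"))
    map[gtv_names[ix]] <- m$name

  masks <- c(anatomy$masks, gtvs, merged)
  set <- structure_set(grid, masks, map)

  # proximity to the hippocampi (for the < 5 mm subgroup analysis),
  # from the analytic geometry so the flag is independent of grid spacing
  dist_hip <- vapply(c(L = "L", R = "R"), function(side) {
    hp <- anatomy$hippocampi[[side]]
    min(vapply(seq_len(n_les), function(i) {
      v <- centers[i, ] - hp$center
      nv <- sqrt(sum(v^2))
      nv - ellipsoid_radius_along(hp$axes, v / nv) - radii[i]
    }, 0))
  }, 0)
  names(dist_hip) <- c("hippocampus_L", "hippocampus_R")
  near <- min(dist_hip) < 5
  ipsi <- if (near) c("L", "R")[which.min(dist_hip)] else NA_character_

  lesions <- data.frame(
    gtv_name = gtv_names, ptv_name = unname(map[gtv_names]),
    x_mm = centers[, 1], y_mm = centers[, 2], z_mm = centers[, 3],
    gtv_radius_mm = radii, radius_mm = radii + spec$margin_mm,
    gtv_volume_cm3 = vols, prescription_Gy = pds)

  patient <- structure(
    list(patient_id = patient_id, structures = set, lesions = lesions,
         prescriptions = stats::setNames(pds, gtv_names),
         near_hippocampus = near, ipsilateral = ipsi,
         hippocampus_distance_mm = dist_hip,
         doses = NULL, seed = spec$seed),
    class = "synthetic_patient")
  if (compose_doses)
    patient$doses <- compose_pair_doses(patient, spec$techniques)
  patient
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf(paste0("synthetic_patient %d: %d lesions, total GTV %.2f cm^3,",
                     " %s\n"),
              x$patient_id, nrow(x$lesions), sum(x$lesions$gtv_volume_cm3),
              if (x$near_hippocampus)
                sprintf("lesion < 5 mm from hippocampus (%s)", x$ipsilateral)
              else "no lesion near hippocampus"))
  invisible(x)
}

#' Generate a synthetic paired cohort
#'
#' Reproducible under the spec seed: the same spec yields bit-identical
#' lesion lists and masks on every run. The configured fraction of
#' patients (rounded to a count) receives at least one lesion within 5 mm
#' of a hippocampus; these patients are spread deterministically over the
#' cohort.
#'
#' @param spec a \code{cohort_spec}.
#' @param compose_doses compute paired dose grids per patient (set FALSE
#'   for geometry-only cohorts).
#' @return list of \code{synthetic_patient}.
#' @export
generate_cohort <- function(spec, compose_doses = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  anatomy <- build_anatomy(spec$spacing_mm)
  n_near <- round(spec$near_hippocampus_fraction * spec$n_patients)
  near_ids <- if (n_near > 0)
    unique(round(seq(1, spec$n_patients, length.out = n_near))) else integer(0)
  lapply(seq_len(spec$n_patients), function(i)
    generate_patient(spec, anatomy, i, near_hippocampus = i %in% near_ids,
                     compose_doses = compose_doses))
}

#' Evaluate a paired cohort into per-patient records
#'
#' Generates (patient by patient, doses discarded after use, so memory
#' stays flat) and evaluates both arms of every patient, returning the
#' cohort records consumed by \code{\link{summarize_cohort}}.
#'
#' @param spec a \code{cohort_spec}, or a pre-generated cohort (list of
#'   \code{synthetic_patient} with doses).
#' @param metrics metric groups passed to \code{\link{evaluate_plan}}.
#' @param limits policy limits.
#' @return list of \code{cohort_record} objects: patient descriptors plus
#'   one \code{plan_metrics} per technique.
#' @export
evaluate_cohort <- function(spec,
                            metrics = c("targets", "brain", "clusters",
                                        "oar", "policy"),
                            limits = policy_limits()) {
  if (inherits(spec, "cohort_spec")) {
    set.seed(spec$seed)
    anatomy <- build_anatomy(spec$spacing_mm)
    n_near <- round(spec$near_hippocampus_fraction * spec$n_patients)
    near_ids <- if (n_near > 0)
      unique(round(seq(1, spec$n_patients, length.out = n_near)))
      else integer(0)
    records <- vector("list", spec$n_patients)
    for (i in seq_len(spec$n_patients)) {
      p <- generate_patient(spec, anatomy, i,
                            near_hippocampus = i %in% near_ids,
                            compose_doses = TRUE)
      records[[i]] <- cohort_record(p, metrics = metrics, limits = limits)
    }
    records
  } else {
    lapply(spec, cohort_record, metrics = metrics, limits = limits)
  }
}

#' Build the paired record of one evaluated patient
#' @param patient a \code{synthetic_patient} with composed doses.
#' @inheritParams evaluate_cohort
#' @return object of class \code{cohort_record}.
#' @export
cohort_record <- function(patient,
                          metrics = c("targets", "brain", "clusters",
                                      "oar", "policy"),
                          limits = policy_limits()) {
  stopifnot(inherits(patient, "synthetic_patient"))
  if (is.null(patient$doses)) stop("patient has no composed doses")
  pm <- lapply(patient$doses, evaluate_plan,
               structures = patient$structures,
               prescriptions = patient$prescriptions,
               metrics = metrics, limits = limits)
  structure(list(
    patient_id = patient$patient_id,
    lesion_count = nrow(patient$lesions),
    total_gtv_cm3 = sum(patient$lesions$gtv_volume_cm3),
    total_ptv_cm3 = sum(vapply(
      unique(patient$lesions$ptv_name), function(p)
        volume_cm3(patient$structures$masks[[p]]), 0)),
    near_hippocampus = patient$near_hippocampus,
    ipsilateral = patient$ipsilateral,
    metrics = pm), class = "cohort_record")
}
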