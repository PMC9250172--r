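#' Write a dose grid or structure mask as NIfTI
#'
#' Doses are stored as float32 in Gy, masks as uint8 0/1; grid spacing is
#' carried in the NIfTI pixdim. Masks additionally get a JSON sidecar
#' (same path with .json extension) holding name, role and, for targets,
#' prescription and GTV/PTV partnership.
#'
#' @param x a \code{dose_grid} or \code{structure_mask}.
#' @param path output path (.nii or .nii.gz).
#' @param sidecar optional named list merged into the mask sidecar.
#' @return the path, invisibly.
#' @export
write_volume <- function(x, path, sidecar = NULL) {
  if (inherits(x, "dose_grid")) {
    img <- RNifti::asNifti(x$dose)
    RNifti::pixdim(img) <- x$grid$spacing_mm
    RNifti::writeNifti(img, path, datatype = "float")
  } else if (inherits(x, "structure_mask")) {
    img <- RNifti::asNifti(array(as.integer(x$voxels), dim(x$voxels)))
    RNifti::pixdim(img) <- x$grid$spacing_mm
    RNifti::writeNifti(img, path, datatype = "uint8")
    meta <- c(list(name = x$name, role = x$role), sidecar)
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  } else stop("x must be a dose_grid or structure_mask")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read a NIfTI volume as a dose grid or structure mask
#'
#' @param path NIfTI file path.
#' @param kind \code{"dose"} or \code{"mask"}.
#' @param scale multiplicative dose scaling applied on read (doses are
#'   stored in Gy; use when importing grids stored in other units).
#' @param expect_grid optional \code{voxel_grid}; error if the file's
#'   geometry disagrees.
#' @return a \code{dose_grid} or \code{structure_mask}.
#' @export
read_volume <- function(path, kind = c("dose", "mask"), scale = 1,
                        expect_grid = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  a <- array(as.numeric(img), dim(img)[1:3])
  grid <- voxel_grid(dim(a), sp, 0)
  if (!is.null(expect_grid) && !same_grid(grid, expect_grid))
    stop("grid mismatch in ", path, ": spacing/shape differ from the plan grid")
  if (kind == "dose") return(dose_grid(grid, a * scale))
  meta <- list(name = tools::file_path_sans_ext(basename(path)),
               role = "derived")
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    js <- jsonlite::read_json(sc)
    meta$name <- js$name %||% meta$name
    meta$role <- js$role %||% meta$role
    attr_extra <- js[setdiff(names(js), c("name", "role"))]
  } else attr_extra <- NULL
  m <- structure_mask(meta$name, meta$role, grid, a > 0.5)
  attr(m, "sidecar") <- attr_extra
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write one synthetic patient as a directory tree
#'
#' Per technique a dose NIfTI, per structure a mask NIfTI with sidecar,
#' plus \code{manifest.json}: patient id, lesion table, prescriptions,
#' GTV-to-PTV map, proximity flags, seed and config hash.
#'
#' @param patient a \code{synthetic_patient} with composed doses.
#' @param dir output directory (created).
#' @param config optional \code{run_config} whose hash is embedded.
#' @return \code{dir}, invisibly.
#' @export
write_patient <- function(patient, dir, config = NULL) {
  stopifnot(inherits(patient, "synthetic_patient"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tn in names(patient$doses))
    write_volume(patient$doses[[tn]],
                 file.path(dir, sprintf("dose_%s.nii.gz", tn)))
  map <- patient$structures$gtv_to_ptv_map
  for (m in patient$structures$masks) {
    sc <- list()
    if (m$role == "GTV") {
      sc$prescription_Gy <- unname(patient$prescriptions[m$name])
      sc$gtv_partner <- unname(map[m$name])
    }
    write_volume(m, file.path(dir, sprintf("mask_%s.nii.gz", m$name)),
                 sidecar = sc)
  }
  manifest <- list(
    patient_id = patient$patient_id,
    seed = patient$seed,
    lesions = patient$lesions,
    prescriptions = as.list(patient$prescriptions),
    gtv_to_ptv_map = as.list(map),
    near_hippocampus = patient$near_hippocampus,
    ipsilateral = patient$ipsilateral,
    techniques = names(patient$doses),
    config_hash = if (!is.null(config)) config_hash(config) else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", null = "null")
  invisible(dir)
}

#' Read a patient directory written by \code{\link{write_patient}}
#' @param dir patient directory.
#' @return a \code{synthetic_patient} (doses and structures restored; all
#'   volumes must share one grid).
#' @export
read_patient <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no such file: ", mf_path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  doses <- list()
  grid <- NULL
  bad <- character(0)
  for (tn in mf$techniques) {
    p <- file.path(dir, sprintf("dose_%s.nii.gz", tn))
    d <- read_volume(p, "dose")
    if (is.null(grid)) grid <- d$grid
    else if (!same_grid(grid, d$grid)) bad <- c(bad, p)
    doses[[tn]] <- d
  }
  masks <- list()
  for (p in Sys.glob(file.path(dir, "mask_*.nii.gz"))) {
    m <- read_volume(p, "mask")
    if (!same_grid(grid, m$grid)) bad <- c(bad, p)
    masks[[m$name]] <- m
  }
  if (length(bad))
    stop("grid spacing/shape mismatch across plan files: ",
         paste(bad, collapse = ", "))
  set <- structure_set(grid, masks, unlist(mf$gtv_to_ptv_map))
  structure(list(
    patient_id = mf$patient_id, structures = set,
    lesions = as.data.frame(mf$lesions),
    prescriptions = unlist(mf$prescriptions),
    near_hippocampus = mf$near_hippocampus,
    ipsilateral = mf$ipsilateral %||% NA_character_,
    doses = doses, seed = mf$seed), class = "synthetic_patient")
}

#' Flatten plan metrics to a one-row data.frame
#' @param metrics a \code{plan_metrics}.
#' @param id optional patient/plan identifier column.
#' @param technique optional technique label column.
#' @return one-row data.frame of the scalar plan metrics.
#' @export
metrics_to_row <- function(metrics, id = NA, technique = NA_character_) {
  stopifnot(inherits(metrics, "plan_metrics"))
  g <- function(f) if (is.null(metrics[[f]])) NA_real_ else metrics[[f]]
  data.frame(
    id = id, technique = technique,
    n_targets = if (is.null(metrics$targets)) NA_integer_
                else nrow(metrics$targets),
    coverage_percent = g("coverage_percent"), ci = g("ci"), gi = g("gi"),
    ptv_mean_Gy = g("ptv_mean_Gy"),
    ptv_d2_cumulative_Gy = g("ptv_d2_cumulative_Gy"),
    brain_mean_Gy = g("brain_mean_Gy"),
    v5_cm3 = g("v5_cm3"), v8_cm3 = g("v8_cm3"),
    v10_cm3 = g("v10_cm3"), v12_cm3 = g("v12_cm3"),
    hippocampus_L_mean_Gy = g("hippocampus_L_mean_Gy"),
    hippocampus_R_mean_Gy = g("hippocampus_R_mean_Gy"),
    brainstem_max_Gy = if (is.null(metrics$oar_max_Gy)) NA_real_
                       else metrics$oar_max_Gy[["brainstem"]],
    optic_apparatus_max_Gy = if (is.null(metrics$oar_max_Gy)) NA_real_
                             else metrics$oar_max_Gy[["optic_apparatus"]],
    lens_max_Gy = if (is.null(metrics$oar_max_Gy)) NA_real_
                  else metrics$oar_max_Gy[["lens"]],
    policy_pass = if (is.null(metrics$policy)) NA else metrics$policy$pass)
}

#' Export plan metrics as JSON
#' @param metrics a \code{plan_metrics}.
#' @param path output .json path.
#' @return the path, invisibly.
#' @export
write_plan_metrics <- function(metrics, path) {
  stopifnot(inherits(metrics, "plan_metrics"))
  out <- metrics[setdiff(names(metrics), "grid")]
  out$policy <- if (!is.null(metrics$policy))
    metrics$policy[c("pass", "failures", "warnings")] else NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", pretty = TRUE)
  invisible(path)
}

#' Flatten cohort records to plan- and patient-level tables
#' @param records list of \code{cohort_record}.
#' @return list of data.frames: \code{plans} (one row per patient x
#'   technique) and \code{patients} (one row per patient).
#' @export
cohort_tables <- function(records) {
  plans <- do.call(rbind, unlist(lapply(records, function(r)
    lapply(names(r$metrics), function(tn)
      metrics_to_row(r$metrics[[tn]], id = r$patient_id, technique = tn))),
    recursive = FALSE))
  patients <- do.call(rbind, lapply(records, function(r) data.frame(
    id = r$patient_id, lesion_count = r$lesion_count,
    total_gtv_cm3 = r$total_gtv_cm3, total_ptv_cm3 = r$total_ptv_cm3,
    near_hippocampus = r$near_hippocampus,
    ipsilateral = r$ipsilateral %||% NA_character_)))
  list(plans = plans, patients = patients)
}

#' Rebuild cohort records from flattened metric tables
#'
#' Inverse of \code{\link{cohort_tables}} for the scalar metrics: lets a
#' comparison stage consume the CSV written by an evaluation stage without
#' re-running dosimetry. Per-target and cluster detail is not recoverable
#' from the flat table and is left NULL.
#'
#' @param plans data.frame as written by \code{cohort_tables()$plans}.
#' @param patients data.frame as written by \code{cohort_tables()$patients}.
#' @return list of \code{cohort_record}.
#' @export
cohort_records_from_tables <- function(plans, patients) {
  scalar_fields <- c("coverage_percent", "ci", "gi", "ptv_mean_Gy",
                     "ptv_d2_cumulative_Gy", "brain_mean_Gy",
                     "v5_cm3", "v8_cm3", "v10_cm3", "v12_cm3",
                     "hippocampus_L_mean_Gy", "hippocampus_R_mean_Gy")
  lapply(seq_len(nrow(patients)), function(i) {
    pid <- patients$id[i]
    rows <- plans[plans$id == pid, , drop = FALSE]
    pm <- lapply(seq_len(nrow(rows)), function(r) {
      m <- as.list(rows[r, scalar_fields])
      m$oar_max_Gy <- c(brainstem = rows$brainstem_max_Gy[r],
                        optic_apparatus = rows$optic_apparatus_max_Gy[r],
                        lens = rows$lens_max_Gy[r])
      class(m) <- "plan_metrics"
      m
    })
    names(pm) <- rows$technique
    structure(list(patient_id = pid,
                   lesion_count = patients$lesion_count[i],
                   total_gtv_cm3 = patients$total_gtv_cm3[i],
                   total_ptv_cm3 = patients$total_ptv_cm3[i],
                   near_hippocampus = patients$near_hippocampus[i],
                   ipsilateral = patients$ipsilateral[i],
                   metrics = pm), class = "cohort_record")
  })
}

#' Validated run configuration
#'
#' Bundles every tunable of the pipeline so it can be hashed and embedded
#' verbatim in output manifests: re-running with the same config and seed
#' reproduces outputs.
#'
#' @param spacing_mm,margin_mm,merge_threshold_mm geometry settings.
#' @param limits policy limits (\code{\link{policy_limits}}).
#' @param techniques named list of \code{kernel_params}.
#' @param lesion_count_threshold stratification boundary on lesion count.
#' @param seed integer RNG seed.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(spacing_mm = 1, margin_mm = 1,
                       merge_threshold_mm = 5,
                       limits = policy_limits(),
                       techniques = default_techniques(),
                       lesion_count_threshold = 10, seed = 1) {
  stopifnot(spacing_mm > 0, margin_mm >= 0, merge_threshold_mm > 0,
            lesion_count_threshold >= 1, seed == round(seed))
  structure(list(spacing_mm = spacing_mm, margin_mm = margin_mm,
                 merge_threshold_mm = merge_threshold_mm, limits = limits,
                 techniques = techniques,
                 lesion_count_threshold = lesion_count_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' MD5 hash of a run configuration
#' @param config a \code{run_config} (or any jsonlite-serializable list).
#' @return character MD5 of the canonical JSON serialization.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}
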