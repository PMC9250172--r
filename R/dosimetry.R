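#' Cumulative dose-volume histogram
#'
#' For each dose bin edge b, the absolute volume (cm^3) of the structure
#' receiving at least b Gy. The curve starts at the full structure volume
#' (bin 0) and is nonincreasing. "Receiving at least" uses the closed
#' threshold \code{dose >= b}, consistent with all V_xGy metrics in the
#' package.
#'
#' @param dose a \code{dose_grid}.
#' @param mask a non-empty \code{structure_mask} on the same grid.
#' @param bin_width_Gy positive bin width (default 0.1 Gy).
#' @return data.frame with columns \code{dose_Gy} (ascending bin edges
#'   from 0 past the structure maximum) and \code{volume_cm3}, plus a
#'   \code{structure} attribute.
#' @export
cumulative_dvh <- function(dose, mask, bin_width_Gy = 0.1) {
  check_same_grid(dose$grid, mask$grid, "dose and mask")
  if (!is.finite(bin_width_Gy) || bin_width_Gy <= 0)
    stop("'bin_width_Gy' must be a positive real")
  d <- dose$dose[mask$voxels]
  if (length(d) == 0L) stop(sprintf("mask '%s' is empty", mask$name))
  edges <- seq(0, max(d) + bin_width_Gy, by = bin_width_Gy)
  # voxels with dose >= edge, via one sort + findInterval
  ds <- sort(d)
  n_below <- findInterval(edges, ds, left.open = TRUE)  # count of ds < edge
  vol <- (length(ds) - n_below) * voxel_volume_cm3(dose$grid)
  out <- data.frame(dose_Gy = edges, volume_cm3 = vol)
  attr(out, "structure") <- mask$name
  out
}

#' Absolute volume receiving at least a threshold dose
#'
#' V_xGy inside a structure: the number of structure voxels with
#' \code{dose >= threshold_Gy} times the voxel volume. On the healthy
#' brain (brain minus GTV) with thresholds 5, 8, 10 and 12 Gy these are
#' the V5Gy-V12Gy metrics; V12Gy is the standard radionecrosis-risk
#' surrogate after single-fraction SRS.
#'
#' @param dose a \code{dose_grid}.
#' @param mask a \code{structure_mask} on the same grid.
#' @param threshold_Gy dose threshold in Gy.
#' @return volume in cm^3.
#' @export
volume_at_dose <- function(dose, mask, threshold_Gy) {
  check_same_grid(dose$grid, mask$grid, "dose and mask")
  sum(dose$dose[mask$voxels] >= threshold_Gy) * voxel_volume_cm3(dose$grid)
}

#' Dose covering a volume fraction of a structure (DVH inverse)
#'
#' The largest dose d such that at least \code{fraction} of the structure
#' volume receives >= d. \code{fraction = 0.02} gives D2%, the near-maximum
#' dose metric used by the plan-acceptance policy. Computed by exact voxel
#' sorting, not from an interpolated histogram, so results are grid-exact
#' and reproducible.
#'
#' @param dose a \code{dose_grid}.
#' @param mask a non-empty \code{structure_mask} on the same grid.
#' @param fraction volume fraction in (0, 1]; 1 returns the structure
#'   minimum dose.
#' @return dose in Gy.
#' @export
dose_at_volume_fraction <- function(dose, mask, fraction) {
  check_same_grid(dose$grid, mask$grid, "dose and mask")
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("'fraction' must lie in (0, 1]")
  d <- dose$dose[mask$voxels]
  if (length(d) == 0L) stop(sprintf("mask '%s' is empty", mask$name))
  k <- ceiling(fraction * length(d))       # need >= k voxels at or above d
  sort(d, decreasing = TRUE)[k]
}

#' Mean structure dose
#' @param dose a \code{dose_grid}.
#' @param mask a non-empty \code{structure_mask} on the same grid.
#' @return mean dose in Gy over the structure voxels.
#' @export
mean_dose <- function(dose, mask) {
  check_same_grid(dose$grid, mask$grid, "dose and mask")
  d <- dose$dose[mask$voxels]
  if (length(d) == 0L) stop(sprintf("mask '%s' is empty", mask$name))
  mean(d)
}

#' Maximum structure dose
#' @param dose a \code{dose_grid}.
#' @param mask a non-empty \code{structure_mask} on the same grid.
#' @return maximum dose in Gy over the structure voxels.
#' @export
max_dose <- function(dose, mask) {
  check_same_grid(dose$grid, mask$grid, "dose and mask")
  d <- dose$dose[mask$voxels]
  if (length(d) == 0L) stop(sprintf("mask '%s' is empty", mask$name))
  max(d)
}

#' Target coverage by the prescription dose
#'
#' Percentage of the PTV volume receiving at least the prescription dose.
#' The acceptance policy requires >= 98% for every PTV.
#'
#' @param dose a \code{dose_grid}.
#' @param ptv a non-empty \code{structure_mask} on the same grid.
#' @param pd_Gy prescription dose in Gy.
#' @return coverage in percent (0-100).
#' @export
coverage_percent <- function(dose, ptv, pd_Gy) {
  check_same_grid(dose$grid, ptv$grid, "dose and PTV")
  stopifnot(pd_Gy > 0)
  d <- dose$dose[ptv$voxels]
  if (length(d) == 0L) stop(sprintf("PTV '%s' is empty", ptv$name))
  100 * sum(d >= pd_Gy) / length(d)
}

#' Paddick conformity index
#'
#' CI = (V_PI,PTV / V_PTV) * (V_PI,PTV / V_PI), where V_PI is the volume
#' covered by 100% of the prescription dose, V_PI,PTV the PTV volume so
#' covered, and V_PTV the PTV volume. The first factor is target coverage,
#' the second selectivity; the product is 1 exactly when the prescription
#' isodose voxel set coincides with the PTV.
#'
#' @param dose a \code{dose_grid}.
#' @param ptv a non-empty \code{structure_mask} on the same grid.
#' @param pd_Gy prescription dose in Gy.
#' @param region optional \code{structure_mask} restricting where V_PI is
#'   counted (used for per-target evaluation of multi-target plans with
#'   differing prescriptions); default the whole grid.
#' @return CI in [0, 1]; 0 with a warning when no voxel reaches the
#'   prescription dose.
#' @export
paddick_ci <- function(dose, ptv, pd_Gy, region = NULL) {
  check_same_grid(dose$grid, ptv$grid, "dose and PTV")
  stopifnot(pd_Gy > 0)
  if (!any(ptv$voxels)) stop(sprintf("PTV '%s' is empty", ptv$name))
  iso <- dose$dose >= pd_Gy
  if (!is.null(region)) {
    check_same_grid(dose$grid, region$grid, "dose and region")
    iso <- iso & region$voxels
  }
  v_pi <- sum(iso)
  if (v_pi == 0) {
    warning("no voxel reaches the prescription dose; CI defined as 0")
    return(0)
  }
  v_ptv <- sum(ptv$voxels)
  v_pi_ptv <- sum(iso & ptv$voxels)
  (v_pi_ptv / v_ptv) * (v_pi_ptv / v_pi)
}

#' Gradient index
#'
#' GI = V_50% / V_PI: the ratio of the volume covered by half the
#' prescription dose to the volume covered by the full prescription dose,
#' both counted over the whole grid (the definition carries no structure
#' restriction). Lower is steeper dose falloff; an ideal step dose gives
#' exactly 1, and GI >= 1 always since the 50% isodose region contains the
#' 100% region.
#'
#' @param dose a \code{dose_grid}.
#' @param pd_Gy prescription dose in Gy.
#' @return GI >= 1.
#' @export
gradient_index <- function(dose, pd_Gy) {
  stopifnot(inherits(dose, "dose_grid"), pd_Gy > 0)
  v_pi <- sum(dose$dose >= pd_Gy)
  if (v_pi == 0) stop("no voxel reaches the prescription dose; GI undefined")
  sum(dose$dose >= 0.5 * pd_Gy) / v_pi
}

#' Healthy-brain 12 Gy isodose clusters around the lesions
#'
#' The supra-threshold voxels of the healthy brain (brain minus all GTVs)
#' are partitioned into connected components: the rings of normal tissue
#' around each lesion that receive at least \code{threshold_Gy}. When the
#' 12 Gy shells of close lesions bridge, the touching rings form a single
#' merged cluster, reported with every GTV it surrounds. Cluster volumes
#' always sum to the total healthy-brain V_threshold.
#'
#' @param dose a \code{dose_grid}.
#' @param brain brain \code{structure_mask}.
#' @param gtvs list of GTV \code{structure_mask}s.
#' @param threshold_Gy isodose threshold (default 12 Gy).
#' @param connectivity component connectivity (default 26).
#' @return list with \code{clusters}, a data.frame (columns
#'   \code{cluster}, \code{volume_cm3}, \code{gtvs} comma-joined GTV
#'   names, \code{n_gtvs}), and \code{total_cm3}.
#' @export
v12_cluster_volumes <- function(dose, brain, gtvs, threshold_Gy = 12,
                                connectivity = 26) {
  check_same_grid(dose$grid, brain$grid, "dose and brain")
  healthy <- brain$voxels
  for (g in gtvs) {
    check_same_grid(dose$grid, g$grid, "dose and GTV")
    healthy <- healthy & !g$voxels
  }
  supra <- healthy & (dose$dose >= threshold_Gy)
  vv <- voxel_volume_cm3(dose$grid)
  if (!any(supra)) {
    return(list(clusters = data.frame(cluster = integer(0),
                                      volume_cm3 = numeric(0),
                                      gtvs = character(0),
                                      n_gtvs = integer(0)),
                total_cm3 = 0))
  }
  cc <- connected_components(
    structure_mask("v_supra", "derived", dose$grid, supra), connectivity)
  # a cluster belongs to every GTV it touches (cluster labels within the
  # 26-neighborhood of the GTV voxels)
  gtv_names <- vapply(gtvs, `[[`, "", "name")
  sh <- dose$grid$shape
  touches <- vector("list", cc$n)
  for (gi in seq_along(gtvs)) {
    ijk <- which(gtvs[[gi]]$voxels, arr.ind = TRUE)
    labs <- integer(0)
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      i <- pmin(pmax(ijk[, 1] + di, 1L), sh[1])
      j <- pmin(pmax(ijk[, 2] + dj, 1L), sh[2])
      k <- pmin(pmax(ijk[, 3] + dk, 1L), sh[3])
      labs <- c(labs, cc$labels[cbind(i, j, k)])
    }
    for (l in unique(labs[labs > 0L]))
      touches[[l]] <- c(touches[[l]], gi)
  }
  clusters <- data.frame(
    cluster = seq_len(cc$n),
    volume_cm3 = cc$sizes * vv,
    gtvs = vapply(touches, function(ix)
      paste(gtv_names[ix], collapse = ","), ""),
    n_gtvs = vapply(touches, length, 0L))
  list(clusters = clusters, total_cm3 = sum(supra) * vv)
}
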