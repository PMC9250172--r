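#' Clinical plan-acceptance limits
#'
#' The policy used to accept a multi-target SRS plan: every PTV covered by
#' the prescription dose over at least 98% of its volume; PTV D2% below
#' 130% of the prescription (soft limit, warning); D2% of the cumulative
#' PTV not above 135% of the prescription (hard limit, rejection); and
#' maximum doses of 12, 8 and 2 Gy to brainstem, optic apparatus and lens.
#'
#' @param coverage_min_percent minimum per-PTV coverage (percent).
#' @param d2_warn_ratio per-PTV D2% warning threshold as a multiple of PD.
#' @param d2_reject_ratio cumulative-PTV D2% rejection threshold.
#' @param oar_max_Gy named numeric vector of OAR maximum-dose limits.
#' @return list of policy limits.
#' @export
policy_limits <- function(coverage_min_percent = 98,
                          d2_warn_ratio = 1.30,
                          d2_reject_ratio = 1.35,
                          oar_max_Gy = c(brainstem = 12,
                                         optic_apparatus = 8,
                                         lens = 2)) {
  list(coverage_min_percent = coverage_min_percent,
       d2_warn_ratio = d2_warn_ratio,
       d2_reject_ratio = d2_reject_ratio,
       oar_max_Gy = oar_max_Gy)
}

#' Check a plan against the acceptance policy
#'
#' @param metrics a \code{plan_metrics} object from \code{\link{evaluate_plan}}.
#' @param limits policy limits from \code{\link{policy_limits}}.
#' @return list with \code{pass} (logical: no hard violation),
#'   \code{failures} and \code{warnings} (character reasons), and
#'   \code{rules}, a data.frame of every rule verdict.
#' @export
check_policy <- function(metrics, limits = policy_limits()) {
  stopifnot(inherits(metrics, "plan_metrics"))
  rules <- list(); failures <- character(0); warnings <- character(0)
  add <- function(rule, structure, value, limit, level, ok) {
    rules[[length(rules) + 1L]] <<- data.frame(
      rule = rule, structure = structure, value = value, limit = limit,
      level = level, ok = ok)
    if (!ok) {
      msg <- sprintf("%s: %s %.3f vs limit %.3f", structure, rule, value, limit)
      if (level == "reject") failures <<- c(failures, msg)
      else warnings <<- c(warnings, msg)
    }
  }
  tg <- metrics$targets
  for (i in seq_len(nrow(tg))) {
    add("coverage >= min", tg$name[i], tg$coverage_percent[i],
        limits$coverage_min_percent, "reject",
        tg$coverage_percent[i] >= limits$coverage_min_percent)
    add("D2% < warn ratio x PD", tg$name[i], tg$d2_Gy[i],
        limits$d2_warn_ratio * tg$prescription_Gy[i], "warn",
        tg$d2_Gy[i] < limits$d2_warn_ratio * tg$prescription_Gy[i])
  }
  pd_ref <- max(tg$prescription_Gy)
  add("cumulative D2% <= reject ratio x PD", "PTV_cumulative",
      metrics$ptv_d2_cumulative_Gy, limits$d2_reject_ratio * pd_ref,
      "reject", metrics$ptv_d2_cumulative_Gy <= limits$d2_reject_ratio * pd_ref)
  for (o in names(limits$oar_max_Gy)) {
    if (!o %in% names(metrics$oar_max_Gy) ||
        is.na(metrics$oar_max_Gy[[o]])) next
    add("max dose <= limit", o, metrics$oar_max_Gy[[o]],
        limits$oar_max_Gy[[o]], "reject",
        metrics$oar_max_Gy[[o]] <= limits$oar_max_Gy[[o]])
  }
  list(pass = length(failures) == 0L, failures = failures,
       warnings = warnings, rules = do.call(rbind, rules))
}

nearest_target_cells <- function(grid, centers_mm) {
  # per-voxel index of the nearest target center (Euclidean, physical mm)
  best_d2 <- dist2_from_point(grid, centers_mm[1, ])
  cell <- array(1L, grid$shape)
  if (nrow(centers_mm) > 1) {
    for (t in 2:nrow(centers_mm)) {
      d2 <- dist2_from_point(grid, centers_mm[t, ])
      upd <- d2 < best_d2
      cell[upd] <- t
      best_d2[upd] <- d2[upd]
    }
  }
  cell
}

mask_centroid_mm <- function(mask) {
  colMeans(index_to_mm(mask$grid, which(mask$voxels, arr.ind = TRUE)))
}

#' Evaluate one SRS plan
#'
#' Computes the full set of per-plan dosimetric metrics: per-target
#' coverage, Paddick CI and D2%; plan-level CI (volume-weighted mean over
#' targets) and gradient index; healthy-brain (brain minus GTV) mean dose
#' and V5/V8/V10/V12Gy with the per-lesion 12 Gy cluster decomposition;
#' hippocampal mean doses; OAR maxima; and the acceptance-policy verdict.
#'
#' For multi-target plans each voxel is attributed to its nearest target
#' (by PTV centroid distance): per-target CI counts V_PI inside that cell
#' with the target's own prescription, and the gradient index uses the
#' per-voxel local prescription, which reduces to the plain global ratio
#' when all targets share one prescription.
#'
#' @param dose a \code{dose_grid}.
#' @param structures a \code{structure_set} (brain, GTV/PTV pairs, OARs).
#' @param prescriptions named numeric vector of prescription doses in Gy,
#'   one per GTV name. A merged PTV takes the maximum prescription of its
#'   member GTVs.
#' @param brain_thresholds_Gy thresholds for healthy-brain V_xGy
#'   (default 5, 8, 10, 12).
#' @param metrics character subset of
#'   \code{c("targets", "brain", "clusters", "oar", "policy")} to compute;
#'   restricting it speeds up large cohort sweeps.
#' @param limits policy limits (see \code{\link{policy_limits}}).
#' @return object of class \code{plan_metrics}.
#' @export
evaluate_plan <- function(dose, structures, prescriptions,
                          brain_thresholds_Gy = c(5, 8, 10, 12),
                          metrics = c("targets", "brain", "clusters",
                                      "oar", "policy"),
                          limits = policy_limits()) {
  stopifnot(inherits(dose, "dose_grid"), inherits(structures, "structure_set"))
  check_same_grid(dose$grid, structures$grid, "dose and structures")
  metrics <- match.arg(metrics, several.ok = TRUE)
  vv <- voxel_volume_cm3(dose$grid)
  gtv_masks <- masks_by_role(structures, "GTV")
  gtv_names <- vapply(gtv_masks, `[[`, "", "name")
  if (!all(gtv_names %in% names(prescriptions)))
    stop("prescriptions must name every GTV: missing ",
         paste(setdiff(gtv_names, names(prescriptions)), collapse = ", "))
  out <- list(grid = dose$grid)

  # per-PTV prescription: max over member GTVs (conservative after merging)
  ptv_names <- unique(unname(structures$gtv_to_ptv_map))
  ptv_pd <- vapply(ptv_names, function(p)
    max(prescriptions[names(structures$gtv_to_ptv_map)[
      structures$gtv_to_ptv_map == p]]), 0)

  if ("targets" %in% metrics) {
    ptvs <- structures$masks[ptv_names]
    centers <- t(vapply(ptvs, mask_centroid_mm, numeric(3)))
    multi_pd <- length(unique(ptv_pd)) > 1L || length(ptvs) > 1L
    cell <- if (multi_pd) nearest_target_cells(dose$grid, centers) else NULL

    rows <- vector("list", length(ptvs))
    v50_sum <- 0; vpi_sum <- 0
    for (i in seq_along(ptvs)) {
      p <- ptvs[[i]]; pd <- ptv_pd[[i]]
      region <- if (multi_pd)
        structure_mask("cell", "derived", dose$grid, cell == i) else NULL
      iso_in <- if (multi_pd) (dose$dose >= pd) & region$voxels
                else dose$dose >= pd
      vpi <- sum(iso_in); v50 <- if (multi_pd)
        sum((dose$dose >= 0.5 * pd) & region$voxels)
        else sum(dose$dose >= 0.5 * pd)
      v50_sum <- v50_sum + v50; vpi_sum <- vpi_sum + vpi
      rows[[i]] <- data.frame(
        name = p$name, prescription_Gy = pd,
        coverage_percent = coverage_percent(dose, p, pd),
        ci = paddick_ci(dose, p, pd, region = region),
        d2_Gy = dose_at_volume_fraction(dose, p, 0.02),
        mean_Gy = mean_dose(dose, p),
        v_ptv_cm3 = volume_cm3(p),
        v_pi_cm3 = vpi * vv,
        v_pi_ptv_cm3 = sum(iso_in & p$voxels) * vv)
    }
    out$targets <- do.call(rbind, rows)
    w <- out$targets$v_ptv_cm3
    out$ci <- sum(out$targets$ci * w) / sum(w)
    if (vpi_sum == 0) stop("no voxel reaches the prescription dose; GI undefined")
    out$gi <- v50_sum / vpi_sum
    out$v_pi_total_cm3 <- vpi_sum * vv
    out$v50_total_cm3 <- v50_sum * vv
    ptv_all <- mask_union_all(unname(ptvs), "PTV_cumulative")
    out$ptv_d2_cumulative_Gy <- dose_at_volume_fraction(dose, ptv_all, 0.02)
    out$ptv_mean_Gy <- mean_dose(dose, ptv_all)
    out$coverage_percent <- sum(out$targets$coverage_percent * w) / sum(w)
  }

  brain <- masks_by_role(structures, "brain")[[1]]
  healthy <- brain$voxels
  for (g in gtv_masks) healthy <- healthy & !g$voxels
  healthy_mask <- structure_mask("brain-GTV", "derived", dose$grid, healthy)

  if ("brain" %in% metrics) {
    d <- dose$dose[healthy]
    out$brain_mean_Gy <- mean(d)
    vx <- vapply(brain_thresholds_Gy, function(th) sum(d >= th) * vv, 0)
    names(vx) <- sprintf("v%g_cm3", brain_thresholds_Gy)
    out$brain_vx_cm3 <- vx
    out$v5_cm3 <- vx[["v5_cm3"]]; out$v8_cm3 <- vx[["v8_cm3"]]
    out$v10_cm3 <- vx[["v10_cm3"]]; out$v12_cm3 <- vx[["v12_cm3"]]
  }

  if ("clusters" %in% metrics) {
    cl <- v12_cluster_volumes(dose, brain, gtv_masks)
    out$v12_clusters <- cl$clusters
    out$v12_cluster_total_cm3 <- cl$total_cm3
  }

  if ("oar" %in% metrics) {
    hl <- masks_by_role(structures, "hippocampus_L")
    hr <- masks_by_role(structures, "hippocampus_R")
    out$hippocampus_L_mean_Gy <- if (length(hl)) mean_dose(dose, hl[[1]]) else NA_real_
    out$hippocampus_R_mean_Gy <- if (length(hr)) mean_dose(dose, hr[[1]]) else NA_real_
    oar_roles <- c("brainstem", "optic_apparatus", "lens")
    out$oar_max_Gy <- vapply(oar_roles, function(r) {
      m <- masks_by_role(structures, r)
      if (length(m)) max_dose(dose, m[[1]]) else NA_real_
    }, 0)
  }

  class(out) <- "plan_metrics"
  if ("policy" %in% metrics) {
    if (!"targets" %in% metrics)
      stop("policy check requires target metrics")
    out$policy <- check_policy(out, limits)
  }
  out
}

#' @export
print.plan_metrics <- function(x, ...) {
  cat("plan_metrics\n")
  if (!is.null(x$targets))
    cat(sprintf("  targets: %d | coverage %.1f%% | CI %.3f | GI %.2f\n",
                nrow(x$targets), x$coverage_percent, x$ci, x$gi))
  if (!is.null(x$brain_mean_Gy))
    cat(sprintf("  brain-GTV: mean %.2f Gy | V12 %.2f | V10 %.2f | V8 %.2f | V5 %.2f cm^3\n",
                x$brain_mean_Gy, x$v12_cm3, x$v10_cm3, x$v8_cm3, x$v5_cm3))
  if (!is.null(x$policy))
    cat(sprintf("  policy: %s%s\n", if (x$policy$pass) "pass" else "FAIL",
                if (length(x$policy$warnings))
                  sprintf(" (%d warnings)", length(x$policy$warnings)) else ""))
  invisible(x)
}
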