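#' Paired two-tailed Wilcoxon signed-rank test
#'
#' Zero differences are discarded (Wilcoxon's original treatment) and the
#' remaining absolute differences are ranked with midranks for ties. The
#' statistic is the sum of ranks of the positive differences. The exact
#' two-tailed p-value enumerates all 2^n sign assignments of the observed
#' ranks (valid with midrank ties), used when the effective n is at most
#' \code{exact_limit} or when \code{mode = "exact"}; otherwise the normal
#' approximation with tie correction and a 0.5 continuity correction is
#' used. Two-tailed p is \code{min(1, 2 * min(P(W <= w), P(W >= w)))}.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param mode \code{"auto"}, \code{"exact"} or \code{"approx"}.
#' @param exact_limit largest effective n for which \code{"auto"} uses
#'   exact enumeration (default 12).
#' @return list with \code{statistic} (W), \code{p_value},
#'   \code{n_effective} and \code{method}.
#' @export
wilcoxon_signed_rank <- function(a, b, mode = c("auto", "exact", "approx"),
                                 exact_limit = 12L) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop("paired vectors differ in length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                method = "degenerate"))
  }
  if (n < 2L && mode != "exact")
    mode <- "exact"                       # approximation meaningless at n = 1
  r <- rank(abs(d))                       # midranks for ties
  w <- sum(r[d > 0])

  if (mode == "exact" || (mode == "auto" && n <= exact_limit)) {
    # distribution of W over all 2^n sign assignments of the observed ranks
    dist_w <- 0
    for (ri in r) dist_w <- as.vector(outer(dist_w, c(0, ri), "+"))
    p_le <- mean(dist_w <= w + 1e-9)
    p_ge <- mean(dist_w >= w - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(w - mu) * 0.5
    z <- (w - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation, tie and continuity corrected"
  }
  list(statistic = w, p_value = p, n_effective = n, method = method)
}

#' Percent difference between paired arm values
#'
#' \code{100 * (b - a) / b}: the reduction achieved by arm a expressed as
#' a percentage of arm b (the larger, shallower-gradient arm in the
#' default pairing).
#'
#' @param a,b numeric vectors (a = steep-gradient arm, b = comparison
#'   arm / denominator).
#' @return percent differences; \code{NA} with a warning where b = 0.
#' @export
percent_difference <- function(a, b) {
  out <- 100 * (b - a) / b
  if (any(b == 0)) {
    warning("percent difference undefined where denominator is 0; NA")
    out[b == 0] <- NA_real_
  }
  out
}

#' Split cohort records into strata
#'
#' @param records list of \code{cohort_record}.
#' @param rule either \code{list(type = "lesion_count", threshold = 10)}
#'   (strata \code{<= threshold} vs \code{> threshold}) or
#'   \code{list(type = "total_gtv", threshold_cm3 = 2)} (total GTV below
#'   vs at/above the threshold), or \code{NULL} for a single stratum.
#' @return named list of record sublists (disjoint, exhaustive; empty
#'   strata are kept and reported empty).
#' @export
stratify <- function(records, rule) {
  stopifnot(length(records) >= 1)
  if (is.null(rule)) return(list(all = records))
  if (rule$type == "lesion_count") {
    th <- rule$threshold
    lc <- vapply(records, `[[`, 0, "lesion_count")
    out <- list(records[lc <= th], records[lc > th])
    names(out) <- c(sprintf("2-%d lesions", th), sprintf(">%d lesions", th))
  } else if (rule$type == "total_gtv") {
    th <- rule$threshold_cm3
    tv <- vapply(records, `[[`, 0, "total_gtv_cm3")
    out <- list(records[tv < th], records[tv >= th])
    names(out) <- c(sprintf("total GTV < %g cm3", th),
                    sprintf("total GTV >= %g cm3", th))
  } else stop("unknown stratification rule: ", rule$type)
  out
}

cohort_metric_extractors <- function() {
  g <- function(field) function(m) m[[field]]
  list(
    coverage_percent = g("coverage_percent"),
    ci = g("ci"),
    gi = g("gi"),
    ptv_mean_Gy = g("ptv_mean_Gy"),
    ptv_d2_cumulative_Gy = g("ptv_d2_cumulative_Gy"),
    brain_mean_Gy = g("brain_mean_Gy"),
    v12_cm3 = g("v12_cm3"),
    v10_cm3 = g("v10_cm3"),
    v8_cm3 = g("v8_cm3"),
    v5_cm3 = g("v5_cm3"),
    hippocampus_L_mean_Gy = g("hippocampus_L_mean_Gy"),
    hippocampus_R_mean_Gy = g("hippocampus_R_mean_Gy"))
}

#' Compare one metric across the two arms of a cohort
#'
#' @param records list of \code{cohort_record}.
#' @param metric metric name (see \code{\link{summarize_cohort}}) or a
#'   function \code{plan_metrics -> scalar}.
#' @param arms names of the two techniques to compare (default the first
#'   two of each record).
#' @param mode Wilcoxon mode.
#' @return list with per-arm values, summaries, Wilcoxon statistic and
#'   p-value, counts of patients where each arm is lower, and the median
#'   percent difference (arm B as denominator).
#' @export
compare_metric <- function(records, metric, arms = NULL,
                           mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (is.character(metric)) {
    fn <- cohort_metric_extractors()[[metric]]
    if (is.null(fn)) stop("unknown metric: ", metric)
    name <- metric
  } else {
    fn <- metric
    name <- deparse(substitute(metric))
  }
  if (is.null(arms)) arms <- names(records[[1]]$metrics)[1:2]
  va <- vapply(records, function(r) as.numeric(fn(r$metrics[[arms[1]]])), 0)
  vb <- vapply(records, function(r) as.numeric(fn(r$metrics[[arms[2]]])), 0)
  keep <- !is.na(va) & !is.na(vb)
  va <- va[keep]; vb <- vb[keep]
  n <- length(va)
  if (n < 2L) stop("need at least 2 complete pairs for metric ", name)
  wt <- wilcoxon_signed_rank(va, vb, mode = mode)
  summ <- function(x) c(mean = mean(x), sd = stats::sd(x),
                        median = stats::median(x), min = min(x), max = max(x))
  pd <- suppressWarnings(percent_difference(va, vb))
  list(metric = name, arms = arms, n = n,
       values_a = va, values_b = vb,
       summary_a = summ(va), summary_b = summ(vb),
       wilcoxon_statistic = wt$statistic, p_value = wt$p_value,
       n_effective = wt$n_effective,
       count_a_lower = sum(va < vb), count_b_lower = sum(vb < va),
       ties = sum(va == vb),
       percent_difference_median = stats::median(pd, na.rm = TRUE))
}

#' Cohort summary tables (paired arm comparison)
#'
#' For every metric (and stratum, if a rule is given): per-arm mean (SD),
#' median and range, the paired two-tailed Wilcoxon signed-rank p-value,
#' the count of patients in which each arm is lower, and the median
#' percent difference with arm B as denominator. Row order is
#' deterministic (strata in rule order, metrics in the documented order)
#' and the result is invariant to the order of patients.
#'
#' @param records list of \code{cohort_record}.
#' @param metrics character vector of metric names (default: target
#'   coverage, CI, GI, PTV mean and cumulative D2%, healthy-brain mean
#'   dose, V12/V10/V8/V5Gy and both hippocampal mean doses).
#' @param strata_rule optional stratification rule (see
#'   \code{\link{stratify}}).
#' @param arms names of the two techniques (default first two).
#' @param mode Wilcoxon mode.
#' @return data.frame, one row per stratum x metric. Empty strata yield
#'   rows with \code{n} and \code{NA} statistics.
#' @export
summarize_cohort <- function(records,
                             metrics = names(cohort_metric_extractors()),
                             strata_rule = NULL, arms = NULL,
                             mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  strata <- stratify(records, strata_rule)
  rows <- list()
  for (s in names(strata)) {
    recs <- strata[[s]]
    for (m in metrics) {
      if (length(recs) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = s, metric = m, n = length(recs),
          mean_a = NA_real_, sd_a = NA_real_, median_a = NA_real_,
          min_a = NA_real_, max_a = NA_real_,
          mean_b = NA_real_, sd_b = NA_real_, median_b = NA_real_,
          min_b = NA_real_, max_b = NA_real_,
          wilcoxon_statistic = NA_real_, p_value = NA_real_,
          count_a_lower = NA_integer_, count_b_lower = NA_integer_,
          ties = NA_integer_, percent_difference_median = NA_real_)
        next
      }
      cmp <- compare_metric(recs, m, arms = arms, mode = mode)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, metric = m, n = cmp$n,
        mean_a = cmp$summary_a[["mean"]], sd_a = cmp$summary_a[["sd"]],
        median_a = cmp$summary_a[["median"]],
        min_a = cmp$summary_a[["min"]], max_a = cmp$summary_a[["max"]],
        mean_b = cmp$summary_b[["mean"]], sd_b = cmp$summary_b[["sd"]],
        median_b = cmp$summary_b[["median"]],
        min_b = cmp$summary_b[["min"]], max_b = cmp$summary_b[["max"]],
        wilcoxon_statistic = cmp$wilcoxon_statistic,
        p_value = cmp$p_value,
        count_a_lower = cmp$count_a_lower,
        count_b_lower = cmp$count_b_lower, ties = cmp$ties,
        percent_difference_median = cmp$percent_difference_median)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plain-text rendering of a cohort summary table
#' @param summary data.frame from \code{\link{summarize_cohort}}.
#' @param arms arm labels for the header.
#' @return character vector of lines (also printed invisibly usable with
#'   \code{writeLines}).
#' @export
render_summary_table <- function(summary, arms = c("A", "B")) {
  fmt <- function(m, s, md, lo, hi)
    sprintf("%7.2f (%5.2f) | %7.2f | %7.2f-%-7.2f", m, s, md, lo, hi)
  lines <- c(sprintf("%-28s %-14s %-45s %-45s %-8s %s",
                     "metric", "stratum",
                     sprintf("%s: mean (SD) | median | range", arms[1]),
                     sprintf("%s: mean (SD) | median | range", arms[2]),
                     "p", "median %diff"))
  for (i in seq_len(nrow(summary))) {
    r <- summary[i, ]
    lines <- c(lines, sprintf(
      "%-28s %-14s %-45s %-45s %-8s %s",
      r$metric, r$stratum,
      if (is.na(r$mean_a)) "-" else
        fmt(r$mean_a, r$sd_a, r$median_a, r$min_a, r$max_a),
      if (is.na(r$mean_b)) "-" else
        fmt(r$mean_b, r$sd_b, r$median_b, r$min_b, r$max_b),
      if (is.na(r$p_value)) "-" else format.pval(r$p_value, digits = 3),
      if (is.na(r$percent_difference_median)) "-" else
        sprintf("%.1f%%", r$percent_difference_median)))
  }
  lines
}
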