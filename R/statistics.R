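# Nonparametric group statistics on the cohort table: Kruskal-Wallis
# omnibus, pairwise Mann-Whitney with Bonferroni, per-electrode contrasts
# with Benjamini-Hochberg FDR, and Kendall correlation with the CRS-R
# score. All tests are two-sided and deterministic given the table.

new_test_result <- function(test, contrast, statistic, p,
                            p_adjusted = p, correction = "none",
                            n_per_group = NA, extra = NULL) {
  out <- data.frame(test = test, contrast = contrast,
                    statistic = statistic, p = p,
                    p_adjusted = pmin(p_adjusted, 1),
                    correction = correction,
                    n_per_group = paste(n_per_group, collapse = "/"),
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

check_metric <- function(table, metric) {
  if (!metric %in% names(table)) stopf("metric `%s` not in table", metric)
  if (!"group" %in% names(table)) stopf("table needs a `group` column")
  invisible(TRUE)
}

#' Kruskal-Wallis omnibus test across diagnosis groups
#'
#' Rank-based H test (with tie correction) of a cohort-table metric
#' across all groups.
#'
#' @param table Cohort data frame with `group` and the metric column.
#' @param metric Name of the metric column.
#' @return A one-row test-result data frame.
#' @export
kruskal_wallis <- function(table, metric) {
  check_metric(table, metric)
  x <- table[[metric]]; grp <- factor(table$group)
  ok <- !is.na(x)
  x <- x[ok]; grp <- droplevels(grp[ok])
  sizes <- table(grp)
  if (length(sizes) < 2 || any(sizes < 2))
    stopf("Kruskal-Wallis needs >= 2 groups with >= 2 observations")
  kt <- stats::kruskal.test(x, grp)
  new_test_result("kruskal-wallis",
                  paste(levels(grp), collapse = " vs "),
                  unname(kt$statistic), kt$p.value,
                  n_per_group = as.integer(sizes))
}

#' Pairwise Mann-Whitney U tests with Bonferroni correction
#'
#' Two-sided Wilcoxon rank-sum tests for every pair of groups (exact
#' when sample sizes permit and there are no ties), with adjusted
#' `p = min(1, m * p)` for `m` comparisons (3 for three groups).
#'
#' @param table Cohort data frame.
#' @param metric Metric column name.
#' @return Data frame with one row per pairwise contrast.
#' @export
pairwise_mwu_bonferroni <- function(table, metric) {
  check_metric(table, metric)
  grp <- factor(table$group)
  lv <- levels(grp)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  m <- length(pairs)
  do.call(rbind, lapply(pairs, function(pr) {
    xa <- table[[metric]][grp == pr[1]]
    xb <- table[[metric]][grp == pr[2]]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (!length(xa) || !length(xb))
      stopf("empty group in contrast %s vs %s", pr[1], pr[2])
    wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = NULL))
    new_test_result("mann-whitney-u", paste(pr, collapse = " vs "),
                    unname(wt$statistic), wt$p.value,
                    p_adjusted = m * wt$p.value,
                    correction = "bonferroni",
                    n_per_group = c(length(xa), length(xb)))
  }))
}

#' Per-electrode group contrast with FDR correction
#'
#' Runs a between-group test per electrode on a per-electrode metric
#' family (columns `<metric>_<channel>`), then applies Benjamini-
#' Hochberg step-up FDR correction across the 30 electrodes at level
#' `q`. With two groups the test is Mann-Whitney, with three or more
#' Kruskal-Wallis. The returned significance mask is suitable for
#' topographic export.
#'
#' @param table Cohort data frame with the 30 per-electrode columns.
#' @param electrode_metric Column prefix, e.g. `"cv_degree"` or
#'   `"cv_bc"`.
#' @param q FDR level (default 0.05).
#' @param groups Optional subset of groups to contrast (default: all).
#' @return Data frame, one row per electrode, with raw and BH-adjusted
#'   p-values and a logical `significant` column.
#' @export
per_electrode_contrast <- function(table, electrode_metric, q = 0.05,
                                   groups = NULL) {
  channels <- doc_montage()$name
  cols <- paste0(electrode_metric, "_", channels)
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stopf("missing electrode columns: %s", paste(missing, collapse = ", "))
  if (!is.null(groups)) table <- table[table$group %in% groups, , drop = FALSE]
  grp <- droplevels(factor(table$group))
  if (nlevels(grp) < 2) stopf("need at least 2 groups to contrast")
  res <- lapply(seq_along(channels), function(k) {
    x <- table[[cols[k]]]
    ok <- !is.na(x)
    g <- droplevels(grp[ok]); xx <- x[ok]
    # an electrode whose metric is undefined (NA) for most of a group
    # cannot be tested; report NA rather than abort the battery
    if (nlevels(g) < 2 || any(table(g) < 2) || stats::sd(xx) == 0)
      return(c(stat = NA_real_, p = NA_real_))
    if (nlevels(g) == 2) {
      wt <- suppressWarnings(
        stats::wilcox.test(xx[g == levels(g)[1]], xx[g == levels(g)[2]]))
      c(stat = unname(wt$statistic), p = wt$p.value)
    } else {
      kt <- stats::kruskal.test(xx, g)
      c(stat = unname(kt$statistic), p = kt$p.value)
    }
  })
  p_raw <- vapply(res, `[[`, numeric(1), "p")
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  data.frame(electrode = channels,
             test = if (nlevels(grp) == 2) "mann-whitney-u" else "kruskal-wallis",
             contrast = paste(levels(grp), collapse = " vs "),
             statistic = vapply(res, `[[`, numeric(1), "stat"),
             p = p_raw, p_adjusted = p_adj,
             correction = "fdr_bh",
             significant = !is.na(p_adj) & p_adj <= q,
             stringsAsFactors = FALSE)
}

#' Per-electrode session-effect Friedman test (fidelity mode)
#'
#' Within one group, tests per electrode whether the per-session values
#' of an electrode metric differ across the five sessions, treating
#' patients as blocks (the repeated-measures reading of the electrode-
#' level test), with BH correction across electrodes.
#'
#' @param session_table Long data frame with columns `patient_id`,
#'   `group`, `session`, and `<metric>_<channel>` columns of per-session
#'   electrode values.
#' @param electrode_metric Column prefix, e.g. `"degree"` or `"bc"`.
#' @param group Group label to test within.
#' @param q FDR level.
#' @return Data frame, one row per electrode.
#' @export
per_electrode_friedman <- function(session_table, electrode_metric,
                                   group, q = 0.05) {
  channels <- doc_montage()$name
  cols <- paste0(electrode_metric, "_", channels)
  missing <- setdiff(cols, names(session_table))
  if (length(missing))
    stopf("missing electrode columns: %s", paste(missing, collapse = ", "))
  st <- session_table[session_table$group == group, , drop = FALSE]
  if (!nrow(st)) stopf("no rows for group `%s`", group)
  res <- lapply(cols, function(cl) {
    ft <- stats::friedman.test(st[[cl]],
                               groups = factor(st$session),
                               blocks = factor(st$patient_id))
    c(stat = unname(ft$statistic), p = ft$p.value)
  })
  p_raw <- vapply(res, `[[`, numeric(1), "p")
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  data.frame(electrode = channels, test = "friedman",
             contrast = sprintf("sessions within %s", group),
             statistic = vapply(res, `[[`, numeric(1), "stat"),
             p = p_raw, p_adjusted = p_adj, correction = "fdr_bh",
             significant = p_adj <= q, stringsAsFactors = FALSE)
}

#' Kendall correlation with the consciousness score
#'
#' Tie-corrected Kendall tau-b between a cohort metric and the CRS-R
#' score, with two-sided p-value.
#'
#' @param table Cohort data frame.
#' @param metric Metric column name.
#' @param score Score column name (default `"crsr"`).
#' @return A one-row test-result data frame with a `tau` column.
#' @export
kendall_correlation <- function(table, metric, score = "crsr") {
  check_metric(table, metric)
  if (!score %in% names(table)) stopf("score column `%s` not in table", score)
  x <- table[[metric]]; y <- table[[score]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stopf("Kendall correlation needs >= 3 patients")
  if (stats::sd(x) == 0) stopf("metric `%s` is constant", metric)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", exact = FALSE))
  new_test_result("kendall", sprintf("%s vs %s", metric, score),
                  unname(ct$statistic), ct$p.value,
                  n_per_group = length(x),
                  extra = data.frame(tau = unname(ct$estimate)))
}

#' Full group-statistics battery on a cohort table
#'
#' Omnibus and pairwise contrasts for the scalar network and variability
#' metrics, per-electrode FDR-corrected contrasts for the degree and
#' betweenness CV vectors, and Kendall correlations of the CV metrics
#' with the CRS-R score.
#'
#' @param table Cohort table (see [cohort_table()]).
#' @param q FDR level for per-electrode contrasts.
#' @return An object of class `group_statistics` (list of tidy data
#'   frames: `omnibus`, `pairwise`, `per_electrode`, `correlations`).
#' @export
group_statistics <- function(table, q = 0.05) {
  scalar_metrics <- intersect(
    c("avg_degree", "cpl", "cc", "bc_mean", "nmi_mean", "gev",
      "cv_cpl", "cv_cc", "cv_bc_mean"), names(table))
  omnibus <- do.call(rbind, lapply(scalar_metrics, function(m)
    cbind(metric = m, kruskal_wallis(table, m))))
  pairwise <- do.call(rbind, lapply(scalar_metrics, function(m)
    cbind(metric = m, pairwise_mwu_bonferroni(table, m))))
  per_electrode <- do.call(rbind, lapply(
    intersect(c("cv_degree", "cv_bc"),
              unique(sub("_[^_]+$", "", grep("^cv_(degree|bc)_",
                                             names(table), value = TRUE)))),
    function(m) cbind(metric = m, per_electrode_contrast(table, m, q))))
  correlations <- do.call(rbind, lapply(
    intersect(c("cv_cpl", "cv_cc", "cv_bc_mean"), scalar_metrics),
    function(m) kendall_correlation(table, m)))
  structure(list(omnibus = omnibus, pairwise = pairwise,
                 per_electrode = per_electrode,
                 correlations = correlations, q = q),
            class = "group_statistics")
}

#' @export
print.group_statistics <- function(x, ...) {
  cat("<group_statistics>\n")
  cat(sprintf("  omnibus: %d tests; pairwise: %d; per-electrode: %d (FDR q=%.2f); correlations: %d\n",
              nrow(x$omnibus), nrow(x$pairwise),
              nrow(x$per_electrode %||% data.frame()), x$q,
              nrow(x$correlations)))
  if (nrow(x$correlations))
    for (i in seq_len(nrow(x$correlations)))
      cat(sprintf("  tau(%s) = %+.3f (p = %.4g)\n",
                  x$correlations$contrast[i], x$correlations$tau[i],
                  x$correlations$p_adjusted[i]))
  invisible(x)
}
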