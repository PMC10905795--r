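# Large-timescale variability statistics across the five daily sessions:
# NMI between module partitions of neighbouring session patterns, global
# explained variance of the mean pattern, and coefficients of variation
# of every network metric.

#' Module partition of a connectivity pattern
#'
#' Community detection by greedy modularity maximisation on the weighted
#' graph (the field-default way to turn a connectivity pattern into
#' modules; the algorithm is injectable in [session_nmi()]).
#'
#' @param cm A session-scope `connectivity_matrix` (or weight matrix).
#' @param seed Accepted for interface stability; the greedy algorithm is
#'   deterministic.
#' @return An object of class `module_partition`: `assignment` (named
#'   node -> module id, ids contiguous from 1) and `n_modules`.
#' @export
partition_modules <- function(cm, seed = 1) {
  g <- weighted_graph(cm)
  if (all(g$weights == 0)) stopf("empty graph: no edges to partition")
  ig <- as_igraph(g)
  memb <- with_seed(seed, igraph::membership(
    igraph::cluster_fast_greedy(ig, weights = igraph::E(ig)$weight)))
  ids <- as.integer(factor(as.integer(memb), levels = unique(as.integer(memb))))
  structure(list(assignment = stats::setNames(ids, g$names),
                 n_modules = max(ids)),
            class = "module_partition")
}

#' Normalised mutual information between two module partitions
#'
#' Evaluates, from the contingency table `N_ij` of module overlaps,
#'
#' `NMI(A,B) = -2 sum_ij N_ij log(N_ij N / (N_i N_j)) /
#'             (sum_i N_i log(N_i / N) + sum_j N_j log(N_j / N))`
#'
#' which ranges from 0 (independent partitions) to 1 (identical
#' partitions). `0 log 0` terms are treated as 0; when both partitions
#' are the single trivial module (zero denominator) they are identical
#' and the value is 1.
#'
#' @param a,b `module_partition` objects (or assignment vectors) over the
#'   same node set.
#' @return NMI value in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  av <- if (inherits(a, "module_partition")) a$assignment else a
  bv <- if (inherits(b, "module_partition")) b$assignment else b
  if (length(av) != length(bv))
    stopf("partitions cover different node sets")
  if (!is.null(names(av)) && !is.null(names(bv))) {
    if (!setequal(names(av), names(bv)))
      stopf("partitions cover different node sets")
    bv <- bv[names(av)]
  }
  N <- length(av)
  tab <- table(av, bv)
  Ni <- rowSums(tab); Nj <- colSums(tab)
  xlogy <- function(x, y) ifelse(x > 0, x * log(y), 0)
  num <- -2 * sum(xlogy(tab, ifelse(tab > 0, tab * N / outer(Ni, Nj), 1)))
  den <- sum(xlogy(Ni, Ni / N)) + sum(xlogy(Nj, Nj / N))
  if (den == 0) return(1)  # both trivial single-module partitions
  val <- num / den
  min(max(val, 0), 1)
}

#' NMI series across the five session patterns
#'
#' Partitions each session pattern and computes the NMI of the four
#' neighbouring pairs (T1-T2, T2-T3, T3-T4, T4-T5).
#'
#' @param patterns List of exactly 5 session-scope connectivity matrices
#'   in temporal order.
#' @param seed Passed to the partitioner.
#' @param partition_fun Partitioning function, `function(cm, seed)`;
#'   defaults to [partition_modules()].
#' @return List with `series` (4 values), `mean`, and the `partitions`.
#' @export
session_nmi <- function(patterns, seed = 1,
                        partition_fun = partition_modules) {
  if (length(patterns) != 5)
    stopf("expected exactly 5 session patterns, got %d", length(patterns))
  parts <- lapply(patterns, partition_fun, seed = seed)
  series <- vapply(1:4, function(k) nmi(parts[[k]], parts[[k + 1]]),
                   numeric(1))
  names(series) <- paste0("T", 1:4, "-T", 2:5)
  list(series = series, mean = mean(series), partitions = parts)
}

#' Global explained variance of the average connectivity pattern
#'
#' Vectorises each pattern's upper triangle `p_k`, forms the template
#' `g = mean_k p_k`, and reports
#' `GEV = sum_k corr(p_k, g)^2 ||p_k||^2 / sum_k ||p_k||^2`,
#' the share of pattern energy explained by the average template
#' (microstate-literature definition). Bounded in `[0, 1]`.
#'
#' @param patterns List of >= 2 connectivity matrices (or weight
#'   matrices) over the same channels.
#' @return Scalar GEV.
#' @export
gev <- function(patterns) {
  if (length(patterns) < 2) stopf("GEV needs at least 2 patterns")
  vecs <- lapply(patterns, function(p) {
    v <- if (inherits(p, "connectivity_matrix")) p$values else p
    v[upper.tri(v)]
  })
  if (length(unique(lengths(vecs))) != 1)
    stopf("patterns have different sizes")
  if (any(vapply(vecs, stats::sd, numeric(1)) == 0))
    stopf("constant (zero-variance) pattern: GEV undefined")
  g <- Reduce(`+`, vecs) / length(vecs)
  if (stats::sd(g) == 0) stopf("constant template: GEV undefined")
  norms <- vapply(vecs, function(p) sum(p^2), numeric(1))
  cors <- vapply(vecs, function(p) stats::cor(p, g), numeric(1))
  sum(cors^2 * norms) / sum(norms)
}

#' Relative coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the arithmetic
#' mean; the population (n) variant is available via `population = TRUE`.
#'
#' @param values Numeric series (>= 2 values, nonzero mean).
#' @param population Use the population SD.
#' @param zero_mean `"error"` (default) rejects a zero mean; `"na"`
#'   returns `NA` instead (used for per-electrode vectors where a metric
#'   can be identically zero).
#' @return Scalar CV.
#' @export
cv <- function(values, population = FALSE, zero_mean = c("error", "na")) {
  zero_mean <- match.arg(zero_mean)
  if (length(values) < 2) stopf("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) {
    if (zero_mean == "na") return(NA_real_)
    stopf("CV undefined: mean is zero")
  }
  s <- stats::sd(values)
  if (population) s <- s * sqrt((length(values) - 1) / length(values))
  s / m
}

#' Assemble the per-patient variability summary
#'
#' Combines the NMI series and mean, the GEV, the CV of each scalar
#' network metric (CPL, CC, mean BC) and the per-electrode CV vectors of
#' degree and betweenness across the five sessions.
#'
#' @param session_metrics List of 5 `network_metrics` (temporal order).
#' @param patterns List of the 5 session connectivity matrices.
#' @param seed Partitioning seed.
#' @param population Use population SDs in the CVs.
#' @return An object of class `patient_variability`.
#' @export
patient_variability <- function(session_metrics, patterns, seed = 1,
                                population = FALSE) {
  if (length(session_metrics) != 5 || length(patterns) != 5)
    stopf("expected 5 sessions of metrics and patterns")
  sn <- session_nmi(patterns, seed = seed)
  get_series <- function(field)
    vapply(session_metrics, function(m) m[[field]], numeric(1))
  deg <- do.call(rbind, lapply(session_metrics, `[[`, "degree"))
  bc <- do.call(rbind, lapply(session_metrics, `[[`, "bc"))
  structure(list(
    nmi_series = sn$series,
    nmi_mean = sn$mean,
    gev = gev(patterns),
    cv_cpl = cv(get_series("cpl"), population),
    cv_cc = cv(get_series("cc"), population),
    cv_bc_mean = cv(get_series("bc_mean"), population),
    cv_degree = apply(deg, 2, cv, population = population, zero_mean = "na"),
    cv_bc = apply(bc, 2, cv, population = population, zero_mean = "na"),
    mean_metrics = list(
      cpl = mean(get_series("cpl")), cc = mean(get_series("cc")),
      bc_mean = mean(get_series("bc_mean")),
      degree = colMeans(deg), bc = colMeans(bc))),
    class = "patient_variability")
}

#' @export
print.patient_variability <- function(x, ...) {
  cat(sprintf("<patient_variability> NMI mean %.3f | GEV %.3f | CV(CPL) %.3f | CV(CC) %.3f | CV(BC) %.3f\n",
              x$nmi_mean, x$gev, x$cv_cpl, x$cv_cc, x$cv_bc_mean))
  invisible(x)
}
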