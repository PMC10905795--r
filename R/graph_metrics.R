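# Weighted graph metrics on unthresholded wPLI networks.
#
# Edges carry the wPLI weight as connection strength; shortest-path
# computations use the length map l_ij = 1 / w_ij (strongest coupling =
# shortest distance), absent edges have infinite length. No thresholding
# is applied anywhere.

#' Construct a weighted graph from a connectivity matrix
#'
#' @param weights Symmetric non-negative matrix with zero diagonal
#'   (wPLI values), or a `connectivity_matrix`.
#' @param channel_names Optional node names.
#' @return An object of class `weighted_graph` with fields `n`, `weights`
#'   and `lengths` (`1/weights`, `Inf` for absent edges).
#' @export
weighted_graph <- function(weights, channel_names = NULL) {
  if (inherits(weights, "connectivity_matrix")) {
    channel_names <- channel_names %||% weights$channel_names
    weights <- weights$values
  }
  if (!is_symmetric_matrix(weights))
    stopf("`weights` must be a symmetric matrix")
  if (any(weights < 0)) stopf("weights must be non-negative")
  if (any(diag(weights) != 0)) stopf("diagonal must be zero")
  n <- nrow(weights)
  channel_names <- channel_names %||% rownames(weights) %||%
    paste0("n", seq_len(n))
  dimnames(weights) <- list(channel_names, channel_names)
  lengths <- ifelse(weights > 0, 1 / weights, Inf)
  diag(lengths) <- 0
  structure(list(n = n, weights = weights, lengths = lengths,
                 names = channel_names),
            class = "weighted_graph")
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Shortest-path distance matrix
#'
#' Dijkstra distances on edge lengths `1/weight`; unreachable pairs get
#' `Inf`.
#'
#' @param g A [weighted_graph()].
#' @return Symmetric distance matrix with zero diagonal.
#' @export
shortest_path_matrix <- function(g) {
  if (g$n < 2) stopf("need at least 2 nodes")
  ig <- as_igraph(g)
  d <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
  dimnames(d) <- list(g$names, g$names)
  d
}

#' Characteristic path length
#'
#' `L = (1/n) sum_i sum_{j != i} d_ij / (n - 1)`, the average shortest
#' path length over all ordered node pairs. Pairs with no connecting
#' path are excluded from the average with a warning
#' (`disconnected = "exclude"`, the default) or propagate `Inf`
#' (`disconnected = "inf"`).
#'
#' @param g A [weighted_graph()].
#' @param disconnected How to treat unreachable pairs.
#' @return Scalar L.
#' @export
characteristic_path_length <- function(g,
                                       disconnected = c("exclude", "inf")) {
  disconnected <- match.arg(disconnected)
  d <- shortest_path_matrix(g)
  off <- d[row(d) != col(d)]
  if (all(is.infinite(off))) stopf("graph is fully disconnected")
  if (any(is.infinite(off))) {
    if (disconnected == "inf") return(Inf)
    warnf("%d unreachable pair(s) excluded from the path-length average",
          sum(is.infinite(off)))
    off <- off[is.finite(off)]
  }
  mean(off)
}

#' Clustering coefficient (weighted, unthresholded)
#'
#' Weighted generalisation by geometric-mean triangle intensity: with
#' weights normalised by their maximum, `t_i = 1/2 * sum_{j,h}
#' (w_ij w_ih w_jh)^(1/3)` and `C_i = 2 t_i / (k_i (k_i - 1))`, where
#' `k_i` counts nonzero-weight neighbours; `C_i = 0` for `k_i < 2`. On
#' binary (0/1) graphs this reduces exactly to the triangle-fraction
#' formula.
#'
#' @param g A [weighted_graph()].
#' @return List with `cc` (network mean) and `ci` (per-node values).
#' @export
clustering_coefficient <- function(g) {
  w <- g$weights
  mx <- max(w)
  ci <- rep(0, g$n)
  if (mx > 0) {
    m <- (w / mx)^(1 / 3)
    t_i <- diag(m %*% m %*% m) / 2
    k_i <- rowSums(w > 0)
    nz <- k_i >= 2
    ci[nz] <- 2 * t_i[nz] / (k_i[nz] * (k_i[nz] - 1))
  }
  names(ci) <- g$names
  list(cc = mean(ci), ci = ci)
}

#' Betweenness centrality (weighted, normalised)
#'
#' `b_i = 1/((n-1)(n-2)) * sum_{h != j, h != i, j != i} rho_hj(i) /
#' rho_hj` with shortest paths on lengths `1/weight` and fractional
#' counting of tied shortest paths; the ordered-pair normalisation keeps
#' `b_i` in `[0, 1]`.
#'
#' @param g A [weighted_graph()] with at least 3 nodes.
#' @return Named per-node vector of betweenness values.
#' @export
betweenness_centrality <- function(g) {
  if (g$n < 3) stopf("betweenness needs at least 3 nodes")
  ig <- as_igraph(g)
  b <- igraph::betweenness(ig, weights = 1 / igraph::E(ig)$weight,
                           directed = FALSE)
  stats::setNames(2 * as.numeric(b) / ((g$n - 1) * (g$n - 2)), g$names)
}

#' Network metrics of a session connectivity pattern
#'
#' Bundles characteristic path length, clustering coefficient,
#' betweenness centrality and node degree of the unthresholded weighted
#' wPLI graph.
#'
#' @param cm A session-scope `connectivity_matrix` (or a weight matrix).
#' @param disconnected Passed to [characteristic_path_length()].
#' @return An object of class `network_metrics` with fields `cpl`, `cc`,
#'   `ci`, `bc`, `bc_mean`, `degree`.
#' @export
network_metrics <- function(cm, disconnected = "exclude") {
  if (inherits(cm, "connectivity_matrix")) {
    if (cm$scope != "session")
      stopf("network_metrics expects a session-scope pattern")
    g <- weighted_graph(cm)
  } else {
    g <- weighted_graph(cm)
  }
  cc <- clustering_coefficient(g)
  bc <- betweenness_centrality(g)
  structure(list(
    cpl = characteristic_path_length(g, disconnected),
    cc = cc$cc, ci = cc$ci,
    bc = bc, bc_mean = mean(bc),
    degree = stats::setNames(rowSums(g$weights), g$names)),
    class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("<network_metrics> CPL %.3f | CC %.4f | mean BC %.4f | mean degree %.3f\n",
              x$cpl, x$cc, x$bc_mean, mean(x$degree)))
  invisible(x)
}
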