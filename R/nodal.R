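#' Weighted degree centrality
#'
#' Sum of the weights of all surviving edges incident to each node,
#' `D_i = sum_j w_ij`.
#'
#' @param g a `thresholded_graph` (or symmetric weight matrix).
#' @return numeric vector, one value per node.
#' @export
degree_centrality <- function(g) {
  w <- if (inherits(g, "thresholded_graph")) g$weights else g
  rowSums(w)
}

#' Weighted nodal efficiency
#'
#' Mean inverse shortest-path length from each node to every other node,
#' `E_i = (1/(N-1)) sum_j 1/L_ij`, with edge lengths 1/w so that strong
#' connections are short, and unreachable pairs contributing 0.
#'
#' @param g a `thresholded_graph` (or symmetric weight matrix).
#' @return numeric vector in [0, 1] per node (1 on a complete unit-weight
#'   graph, 0 for an isolated node).
#' @export
nodal_efficiency <- function(g) {
  w <- if (inherits(g, "thresholded_graph")) g$weights else g
  n <- nrow(w)
  if (n < 2) return(rep(0, n))
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  if (igraph::ecount(ig) == 0) return(rep(0, n))
  d <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (n - 1)
}

#' Integrate per-cost nodal values over the cost grid
#'
#' Area under the metric-versus-cost curve by the trapezoidal rule,
#' producing one cost-integrated composite value per node. The grid may be
#' supplied in either orientation; costs are sorted internally.
#'
#' @param values_by_cost numeric matrix, one row per cost with rownames equal
#'   to the cost values (as produced by [metrics_over_costs()]), columns are
#'   nodes; a plain vector is treated as a single node.
#' @param grid cost grid (length >= 2); every grid cost must be present among
#'   the rows.
#' @return numeric vector of per-node AUC composites.
#' @export
integrate_over_costs <- function(values_by_cost, grid) {
  if (length(grid) < 2)
    stop_fctopo("cost grid must have length >= 2 for integration")
  if (is.null(dim(values_by_cost)))
    values_by_cost <- matrix(values_by_cost, ncol = 1)
  keys <- rownames(values_by_cost)
  if (is.null(keys))
    stop_fctopo("values_by_cost must have cost rownames")
  ord <- order(grid)
  grid <- grid[ord]
  idx <- match(as.character(grid), keys)
  if (anyNA(idx))
    stop_fctopo("missing values for cost(s): %s",
                paste(grid[is.na(idx)], collapse = ", "))
  v <- values_by_cost[idx, , drop = FALSE]
  apply(v, 2, function(y) pracma::trapz(grid, y))
}

#' Compute nodal metrics across a cost grid
#'
#' Thresholds a connectivity matrix at every cost of the grid and evaluates
#' the requested nodal metrics, optionally against a fixed community
#' partition for the module-based metrics.
#'
#' @param fc connectivity matrix from [build_fc()].
#' @param grid cost grid from [cost_grid()].
#' @param metrics subset of `c("degree", "efficiency", "within_module_z",
#'   "participation")`.
#' @param partition community labels per node; required for the module-based
#'   metrics.
#' @return named list of matrices (costs x nodes, rownames = costs), one per
#'   metric.
#' @export
metrics_over_costs <- function(fc, grid,
                               metrics = c("degree", "efficiency"),
                               partition = NULL) {
  metrics <- match.arg(metrics, c("degree", "efficiency",
                                  "within_module_z", "participation"),
                       several.ok = TRUE)
  needs_part <- intersect(metrics, c("within_module_z", "participation"))
  if (length(needs_part) && is.null(partition))
    stop_fctopo("metrics %s require a partition",
                paste(needs_part, collapse = ", "))
  n <- nrow(fc)
  out <- lapply(metrics, function(m)
    matrix(NA_real_, length(grid), n,
           dimnames = list(as.character(grid), colnames(fc))))
  names(out) <- metrics
  for (k in seq_along(grid)) {
    g <- threshold_at_cost(fc, grid[k])
    for (m in metrics) {
      out[[m]][k, ] <- switch(m,
        degree = degree_centrality(g),
        efficiency = nodal_efficiency(g),
        within_module_z = within_module_degree(g, partition),
        participation = participation_coefficient(g, partition))
    }
  }
  out
}

#' Cost-integrated nodal metric table for a cohort
#'
#' @param fc_list named list of connectivity matrices (names = subject ids).
#' @param grid cost grid.
#' @param metrics,partition see [metrics_over_costs()]. `partition` may be a
#'   single vector or a named list keyed by subject id (e.g. each subject
#'   scored against their own group's partition).
#' @return long data.frame: subject_id, node_id (0-based), metric, value.
#' @export
nodal_metric_table <- function(fc_list, grid,
                               metrics = c("degree", "efficiency"),
                               partition = NULL) {
  ids <- names(fc_list) %||% as.character(seq_along(fc_list))
  rows <- lapply(seq_along(fc_list), function(s) {
    part <- if (is.list(partition)) partition[[ids[s]]] else partition
    per_cost <- metrics_over_costs(fc_list[[s]], grid, metrics, part)
    do.call(rbind, lapply(names(per_cost), function(m) {
      auc <- integrate_over_costs(per_cost[[m]], grid)
      data.frame(subject_id = ids[s],
                 node_id = seq_along(auc) - 1L,
                 metric = m, value = as.numeric(auc),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}
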