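#' Cost grids for graph thresholding
#'
#' A cost is the fraction of retained edges over all possible edges
#' N(N-1)/2. The nodal-metric pipeline uses a coarse grid from 0.09 to 0.40
#' in steps of 0.01 (32 costs); community detection uses a fine grid with
#' step 0.001 (311 costs). Grid endpoints are generated arithmetically to
#' avoid floating-point drift in the threshold count.
#'
#' @param cost_min,cost_max grid endpoints, fractions in (0, 1].
#' @param step grid step.
#' @return numeric vector of strictly increasing costs.
#' @examples
#' length(cost_grid())            # 32
#' length(cost_grid(step = 0.001)) # 311
#' @export
cost_grid <- function(cost_min = 0.09, cost_max = 0.40, step = 0.01) {
  if (cost_min <= 0 || cost_max > 1 || cost_min >= cost_max || step <= 0)
    stop_fctopo("invalid cost grid: min %g, max %g, step %g",
                cost_min, cost_max, step)
  n <- floor((cost_max - cost_min) / step + 1e-9) + 1L
  round(cost_min + step * (seq_len(n) - 1L), 10)
}

#' Threshold a connectivity matrix at a given cost
#'
#' Retains the `floor(cost * N(N-1)/2)` largest-weight edges of a symmetric
#' nonnegative connectivity matrix, keeping their original weights
#' (weighted, non-binarized thresholding). Ties in weight are broken by
#' ascending (i, j) node-index order, which makes edge sets nested across
#' costs. If fewer positive edges exist than the cost requests, all positive
#' edges are kept and the result is flagged.
#'
#' @param fc symmetric nonnegative matrix with zero diagonal
#'   (see [build_fc()]).
#' @param cost fraction of possible edges to retain, in (0, 1].
#' @return object of class `thresholded_graph`: a list with `cost`, `weights`
#'   (retained-weight matrix), `binary` (0/1 adjacency), `n_edges`, and
#'   `flagged` (TRUE when the positive-edge supply ran out).
#' @examples
#' fc <- build_fc(matrix(rnorm(400), 20, 20) %*% diag(20) + rnorm(400))
#' g <- threshold_at_cost(fc, 0.2)
#' g$n_edges
#' @export
threshold_at_cost <- function(fc, cost) {
  check_square_symmetric(fc, "fc")
  if (cost <= 0 || cost > 1) stop_fctopo("cost must lie in (0, 1], got %g", cost)
  n <- nrow(fc)
  m_target <- floor(cost * n * (n - 1) / 2)
  iu <- which(upper.tri(fc), arr.ind = TRUE)
  w <- fc[iu]
  pos <- which(w > 0)
  # stable ranking: weight descending, then (i, j) ascending
  ord <- pos[order(-w[pos], iu[pos, 1L], iu[pos, 2L])]
  flagged <- FALSE
  if (length(ord) < m_target) {
    warning(sprintf(
      "cost %g requests %d edges but only %d positive edges exist; keeping all",
      cost, m_target, length(ord)), call. = FALSE)
    flagged <- TRUE
    m_target <- length(ord)
  }
  keep <- ord[seq_len(m_target)]
  weights <- matrix(0, n, n, dimnames = dimnames(fc))
  weights[iu[keep, , drop = FALSE]] <- w[keep]
  weights <- weights + t(weights)
  structure(
    list(cost = cost, weights = weights, binary = (weights > 0) + 0,
         n_edges = m_target, flagged = flagged),
    class = "thresholded_graph"
  )
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("thresholded_graph: %d nodes, %d edges at cost %.3f%s\n",
              nrow(x$weights), x$n_edges, x$cost,
              if (x$flagged) " (edge supply exhausted)" else ""))
  invisible(x)
}

as_igraph <- function(g, weighted = TRUE) {
  m <- if (inherits(g, "thresholded_graph")) {
    if (weighted) g$weights else g$binary
  } else g
  igraph::graph_from_adjacency_matrix(
    m, mode = "undirected", weighted = if (weighted) TRUE else NULL,
    diag = FALSE)
}
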