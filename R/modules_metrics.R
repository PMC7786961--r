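#' Within-module degree z-score
#'
#' For each node, the number of binary surviving edges to nodes of its own
#' module, z-scored within the module:
#' `z_i = (k_ni - mean_k_n) / sd_k_n`. Modules with zero intra-degree
#' spread (including singleton modules and perfect cliques) get z = 0.
#'
#' @param g a `thresholded_graph` (or 0/1 adjacency matrix).
#' @param part community labels per node (a `partition` or integer vector).
#' @param weighted use surviving edge weights instead of binary counts
#'   (sensitivity variant; default FALSE).
#' @return numeric vector of z-scores per node.
#' @export
within_module_degree <- function(g, part, weighted = FALSE) {
  a <- if (inherits(g, "thresholded_graph")) {
    if (weighted) g$weights else g$binary
  } else (g > 0) + 0
  labels <- if (inherits(part, "partition")) part$labels else part
  if (length(labels) != nrow(a))
    stop_fctopo("partition must cover all %d nodes", nrow(a))
  z <- numeric(nrow(a))
  for (cid in unique(labels)) {
    idx <- which(labels == cid)
    k_in <- rowSums(a[idx, idx, drop = FALSE])
    s <- stats::sd(k_in)
    z[idx] <- if (length(idx) < 2 || is.na(s) || s == 0) 0
              else (k_in - mean(k_in)) / s
  }
  z
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_n (k_ni / k_i)^2` over modules n, with binary degrees;
#' nodes with no surviving edges get P = 0. P is 0 when all of a node's
#' edges stay inside one module and approaches 1 as edges spread evenly over
#' many modules.
#'
#' @inheritParams within_module_degree
#' @return numeric vector in [0, 1) per node.
#' @export
participation_coefficient <- function(g, part, weighted = FALSE) {
  a <- if (inherits(g, "thresholded_graph")) {
    if (weighted) g$weights else g$binary
  } else (g > 0) + 0
  labels <- if (inherits(part, "partition")) part$labels else part
  if (length(labels) != nrow(a))
    stop_fctopo("partition must cover all %d nodes", nrow(a))
  k_tot <- rowSums(a)
  mods <- unique(labels)
  k_mod <- vapply(mods, function(cid)
    rowSums(a[, labels == cid, drop = FALSE]), numeric(nrow(a)))
  p <- 1 - rowSums((k_mod / pmax(k_tot, .Machine$double.eps))^2)
  p[k_tot == 0] <- 0
  p
}
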