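#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement under the permutation model:
#' identical partitions score 1 regardless of labeling, independent random
#' partitions score about 0.
#'
#' @param p1,p2 `partition` objects or label vectors over the same node set.
#' @return scalar ARI in [-1, 1].
#' @examples
#' adjusted_rand(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' @export
adjusted_rand <- function(p1, p2) {
  l1 <- if (inherits(p1, "partition")) p1$labels else p1
  l2 <- if (inherits(p2, "partition")) p2$labels else p2
  if (length(l1) != length(l2))
    stop_fctopo("partitions cover different node sets (%d vs %d)",
                length(l1), length(l2))
  n <- length(l1)
  tab <- table(l1, l2)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps * max(1, max_index))
    return(1)  # both partitions degenerate (and identical up to labels)
  (sum_ij - expected) / (max_index - expected)
}

#' ARI restricted to a node subset
#'
#' Both partitions are restricted to the subset (community labels re-indexed
#' within it) before the adjusted Rand index is computed, quantifying
#' agreement of the community assignment inside one sub-network.
#'
#' @param p1,p2 partitions over the full node set.
#' @param node_subset indices (1-based) of the nodes to keep; >= 2 nodes.
#' @return scalar ARI on the subset.
#' @export
restricted_ari <- function(p1, p2, node_subset) {
  if (length(node_subset) < 2)
    stop_fctopo("node subset must contain >= 2 nodes")
  l1 <- if (inherits(p1, "partition")) p1$labels else p1
  l2 <- if (inherits(p2, "partition")) p2$labels else p2
  adjusted_rand(canonical_labels(l1[node_subset]),
                canonical_labels(l2[node_subset]))
}

#' Subgroup-resampled partition similarity per group and scope
#'
#' For each group, `n_subgroups` subgroups of `subgroup_size` subjects are
#' drawn with replacement; each subgroup's representative partition is built
#' with [group_partition()] (repeated subjects counted with multiplicity in
#' the allegiance matrix) and compared to the reference partition by the
#' adjusted Rand index, at the whole-brain level and restricted to each
#' community-of-interest scope of the atlas. For the reference's own group
#' this measures sampling variability relative to the full-group structure.
#'
#' @param partitions_by_group named list; each element a list of
#'   subject-consensus partitions (or label vectors) for one group.
#' @param reference reference partition (typically the all-HC group-level
#'   structure).
#' @param atlas atlas from [make_atlas()]; its `community_of_interest` column
#'   defines the restricted scopes (`DN_CN`, `SVAN`, `SUBCORTICAL`).
#' @param n_subgroups subgroups per group (default 20).
#' @param subgroup_size subjects per subgroup, sampled with replacement
#'   (default 10).
#' @param gamma_group resolution for subgroup partitions (default 2).
#' @param seed integer seed.
#' @param scopes restricted scopes to evaluate (besides `whole_brain`).
#' @param ... passed to [group_partition()].
#' @return long data.frame: group, scope, subgroup, ari.
#' @export
resample_group_similarity <- function(partitions_by_group, reference, atlas,
                                      n_subgroups = 20, subgroup_size = 10,
                                      gamma_group = 2, seed = 1L,
                                      scopes = c("DN_CN", "SVAN",
                                                 "SUBCORTICAL"), ...) {
  ref_labels <- if (inherits(reference, "partition")) reference$labels
                else reference
  scope_sets <- c(list(whole_brain = seq_along(ref_labels)),
                  stats::setNames(lapply(scopes, scope_nodes, atlas = atlas),
                                  scopes))
  scope_sets <- scope_sets[vapply(scope_sets, length, 1L) >= 2]
  groups <- names(partitions_by_group)
  if (is.null(groups)) stop_fctopo("partitions_by_group must be named")
  seeds <- derive_seeds(seed, length(groups) * n_subgroups * 2L)
  k <- 0L
  rows <- list()
  for (gname in groups) {
    parts <- partitions_by_group[[gname]]
    if (!length(parts)) stop_fctopo("group %s has no subjects", gname)
    for (b in seq_len(n_subgroups)) {
      k <- k + 1L
      set.seed(seeds[2L * k - 1L])
      draw <- sample.int(length(parts), subgroup_size, replace = TRUE)
      gp <- group_partition(parts[draw], gamma = gamma_group,
                            seed = seeds[2L * k], ...)
      for (sc in names(scope_sets)) {
        ari <- if (sc == "whole_brain")
          adjusted_rand(gp$partition, ref_labels)
        else
          restricted_ari(gp$partition, ref_labels, scope_sets[[sc]])
        rows[[length(rows) + 1L]] <- data.frame(
          group = gname, scope = sc, subgroup = b, ari = ari,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = groups)
  out
}
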