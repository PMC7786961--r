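#' Seeded Louvain community detection with restarts
#'
#' Greedy modularity maximization (Newman-Girvan modularity with resolution
#' parameter gamma) on a weighted undirected graph. The greedy sweep is
#' randomized, so the best partition over `n_restarts` seeded restarts is
#' returned (highest modularity at the given gamma; ties go to the earliest
#' restart).
#'
#' @param g a `thresholded_graph`, a symmetric weight matrix (e.g. a
#'   co-classification or allegiance matrix with its diagonal ignored), or an
#'   igraph object.
#' @param gamma resolution parameter (> 0); larger values yield more, smaller
#'   communities.
#' @param seed integer seed.
#' @param n_restarts number of restarts (default 10).
#' @return object of class `partition`: list with `labels` (integer community
#'   id per node, canonical order of first appearance), `gamma`, `modularity`.
#' @export
louvain_partition <- function(g, gamma = 1, seed = 1L, n_restarts = 10) {
  if (gamma <= 0) stop_fctopo("gamma must be positive")
  ig <- if (inherits(g, "igraph")) g else as_igraph(g, weighted = TRUE)
  if (igraph::vcount(ig) == 0) stop_fctopo("empty graph")
  best <- NULL
  best_q <- -Inf
  seeds <- derive_seeds(seed, n_restarts)
  for (k in seq_len(n_restarts)) {
    set.seed(seeds[k])
    cl <- igraph::cluster_louvain(ig, resolution = gamma)
    mem <- igraph::membership(cl)
    q <- igraph::modularity(ig, mem, resolution = gamma,
                            weights = igraph::E(ig)$weight)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- mem
    }
  }
  structure(list(labels = canonical_labels(best), gamma = gamma,
                 modularity = best_q),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d nodes, %d communities (gamma %.2f, Q %.4f)\n",
              length(x$labels), length(unique(x$labels)), x$gamma,
              x$modularity))
  invisible(x)
}

#' Newman-Girvan modularity of a labeling
#'
#' @param w symmetric weight matrix (or `thresholded_graph`).
#' @param labels community id per node.
#' @param gamma resolution parameter.
#' @return scalar modularity Q.
#' @export
modularity_q <- function(w, labels, gamma = 1) {
  if (inherits(w, "thresholded_graph")) w <- w$weights
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  igraph::modularity(ig, canonical_labels(labels), resolution = gamma,
                     weights = igraph::E(ig)$weight)
}

#' Co-classification matrix of a set of partitions
#'
#' Entry (i, j) is the fraction of partitions assigning nodes i and j to the
#' same community. Invariant to community relabeling; diagonal is 1.
#'
#' @param partitions list of `partition` objects or label vectors over the
#'   same node set (counted with multiplicity).
#' @return list with `frequency` (N x N matrix in [0, 1]) and `n_partitions`.
#' @export
co_classification <- function(partitions) {
  labs <- lapply(partitions, function(p)
    if (inherits(p, "partition")) p$labels else p)
  n <- length(labs[[1]])
  if (any(vapply(labs, length, 1L) != n))
    stop_fctopo("all partitions must cover the same node set")
  freq <- matrix(0, n, n)
  for (l in labs) {
    # indicator outer product per community, summed
    for (cid in unique(l)) {
      idx <- which(l == cid)
      freq[idx, idx] <- freq[idx, idx] + 1
    }
  }
  freq <- freq / length(labs)
  diag(freq) <- 1
  list(frequency = freq, n_partitions = length(labs))
}

#' Consensus clustering of a co-classification matrix
#'
#' Iterative consensus: entries of the matrix below `tau` are zeroed, the
#' thresholded matrix is clustered `n_recluster` times with seeded Louvain at
#' resolution gamma, and if the runs disagree their co-classification matrix
#' replaces the input for the next iteration, until all runs agree or
#' `max_iter` is reached.
#'
#' @param mat co-classification/allegiance matrix (list with `frequency`, or
#'   plain matrix in [0, 1]).
#' @param gamma resolution for every re-clustering.
#' @param seed integer seed.
#' @param tau consensus threshold (default 0.5).
#' @param n_recluster clusterings per iteration (default 10).
#' @param max_iter iteration cap (default 20).
#' @param n_restarts restarts inside each Louvain call.
#' @return `partition` with extra fields `converged` and `n_iter`.
#' @export
consensus_cluster <- function(mat, gamma = 1, seed = 1L, tau = 0.5,
                              n_recluster = 10, max_iter = 20,
                              n_restarts = 10) {
  m <- if (is.list(mat)) mat$frequency else mat
  check_square_symmetric(m, "consensus matrix")
  seeds <- derive_seeds(seed, max_iter)
  part <- NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mt <- m
    mt[mt < tau] <- 0
    diag(mt) <- 0
    runs <- lapply(derive_seeds(seeds[it], n_recluster), function(s)
      louvain_partition(mt, gamma = gamma, seed = s, n_restarts = n_restarts))
    labs <- lapply(runs, `[[`, "labels")
    if (all(vapply(labs[-1], identical, TRUE, labs[[1]]))) {
      part <- runs[[1]]
      converged <- TRUE
      break
    }
    m <- co_classification(labs)$frequency
    part <- runs[[1]]
  }
  if (!converged)
    warning("consensus clustering did not converge; returning last partition",
            call. = FALSE)
  part$converged <- converged
  part$n_iter <- it
  part
}

#' Subject-level consensus community structure
#'
#' Stage one of the two-stage scheme: the subject's connectivity matrix is
#' thresholded at every cost of the fine grid, each thresholded weighted
#' graph is clustered with seeded Louvain at resolution gamma, the
#' co-classification matrix over all per-cost partitions is formed, and
#' consensus clustering of that matrix yields one final partition for the
#' subject.
#'
#' @param fc connectivity matrix from [build_fc()].
#' @param fine_grid cost grid (default 0.09-0.40 step 0.001, 311 costs).
#' @param gamma subject-level resolution (default 3).
#' @param seed integer seed.
#' @param n_restarts Louvain restarts per cost (default 10).
#' @param ... passed to [consensus_cluster()].
#' @return list with `partition` (consensus `partition`), `coclass`
#'   (co-classification over costs), `per_cost_labels` (matrix costs x nodes).
#' @export
subject_consensus <- function(fc, fine_grid = cost_grid(step = 0.001),
                              gamma = 3, seed = 1L, n_restarts = 10, ...) {
  seeds <- derive_seeds(seed, length(fine_grid) + 1L)
  labs <- vector("list", length(fine_grid))
  for (k in seq_along(fine_grid)) {
    g <- withCallingHandlers(
      threshold_at_cost(fc, fine_grid[k]),
      warning = function(w) invokeRestart("muffleWarning"))
    labs[[k]] <- louvain_partition(g, gamma = gamma, seed = seeds[k],
                                   n_restarts = n_restarts)$labels
  }
  cc <- co_classification(labs)
  part <- consensus_cluster(cc, gamma = gamma,
                            seed = seeds[length(fine_grid) + 1L], ...)
  list(partition = part,
       coclass = cc,
       per_cost_labels = do.call(rbind, labs))
}

#' Group-level consensus community structure
#'
#' Stage two: the allegiance matrix records, for every node pair, the
#' fraction of the group's subject-consensus partitions that co-assign the
#' pair (subjects counted with multiplicity, normalized to [0, 1]); consensus
#' clustering of the allegiance matrix at the group-level resolution yields
#' the representative group partition.
#'
#' @param subject_partitions list of subject `partition` objects or label
#'   vectors over the same node set (>= 2).
#' @param gamma group-level resolution (default 2).
#' @param seed integer seed.
#' @param ... passed to [consensus_cluster()].
#' @return list with `partition` and `allegiance` (as [co_classification()]).
#' @export
group_partition <- function(subject_partitions, gamma = 2, seed = 1L, ...) {
  if (length(subject_partitions) < 2)
    stop_fctopo("need >= 2 subject partitions")
  alg <- co_classification(subject_partitions)
  part <- consensus_cluster(alg, gamma = gamma, seed = seed, ...)
  list(partition = part, allegiance = alg)
}
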