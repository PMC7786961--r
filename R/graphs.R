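#' Small-worldness of a thresholded graph
#'
#' Computes sigma = (C / C_rand) / (L / L_rand) on the binarized graph,
#' where C is the mean local clustering coefficient (isolates counted as 0),
#' L is the characteristic path length on the largest connected component,
#' and the normalizers are means over `n_null` degree-preserving rewired
#' null graphs. Values above 1 indicate small-world organization.
#'
#' @param g a `thresholded_graph` (or 0/1 adjacency matrix).
#' @param n_null number of rewired null graphs (>= 1).
#' @param seed integer seed for the rewiring.
#' @return list with `sigma`, `C`, `L`, `C_rand`, `L_rand`, `flagged`
#'   (TRUE when a null had no triangles and the ratio was guarded).
#' @export
small_worldness <- function(g, n_null = 20, seed = 1L) {
  if (n_null < 1) stop_fctopo("configuration error: n_null must be >= 1")
  ig <- as_igraph(g, weighted = FALSE)
  cl_obs <- clustering_and_path(ig)
  set.seed(seed)
  nulls <- vapply(seq_len(n_null), function(k) {
    gr <- igraph::rewire(ig, igraph::keeping_degseq(
      niter = 20 * igraph::ecount(ig)))
    unlist(clustering_and_path(gr))
  }, numeric(2))
  C_rand <- mean(nulls[1, ])
  L_rand <- mean(nulls[2, ])
  flagged <- FALSE
  if (C_rand == 0 || L_rand == 0 || cl_obs$L == 0) {
    flagged <- TRUE
    sigma <- NA_real_
  } else {
    sigma <- (cl_obs$C / C_rand) / (cl_obs$L / L_rand)
  }
  list(sigma = sigma, C = cl_obs$C, L = cl_obs$L,
       C_rand = C_rand, L_rand = L_rand, flagged = flagged)
}

clustering_and_path <- function(ig) {
  C <- igraph::transitivity(ig, type = "localaverage", isolates = "zero")
  comp <- igraph::components(ig)
  lcc <- igraph::induced_subgraph(
    ig, which(comp$membership == which.max(comp$csize)))
  L <- igraph::mean_distance(lcc, directed = FALSE)
  list(C = C, L = L)
}

#' Validate a cost range against connectome criteria
#'
#' Evaluates, per subject and per cost, the three validity criteria used to
#' select a cost range for brain graphs: (a) small-worldness sigma > 1,
#' (b) the largest connected component covers at least `lcc_frac` of nodes,
#' and (c) mean binary degree 2m/N exceeds log(N) (natural log). Reports
#' subject-level pass/fail plus cohort pass fractions; no cost is rejected
#' automatically.
#'
#' @param fc_list list of connectivity matrices.
#' @param grid cost grid from [cost_grid()].
#' @param n_null rewired nulls per small-worldness evaluation.
#' @param lcc_frac required largest-component coverage (default 0.8).
#' @param seed integer seed.
#' @return list with `subjects` (long data.frame: subject, cost, sigma,
#'   sigma_ok, lcc_frac, lcc_ok, mean_degree, degree_ok) and `summary`
#'   (per-cost pass fractions).
#' @export
validate_cost_range <- function(fc_list, grid, n_null = 20, lcc_frac = 0.8,
                                seed = 1L) {
  if (!length(fc_list)) stop_fctopo("fc_list must be non-empty")
  seeds <- derive_seeds(seed, length(fc_list) * length(grid))
  k <- 0L
  rows <- list()
  for (s in seq_along(fc_list)) {
    for (cost in grid) {
      k <- k + 1L
      g <- threshold_at_cost(fc_list[[s]], cost)
      n <- nrow(g$binary)
      ig <- as_igraph(g, weighted = FALSE)
      comp <- igraph::components(ig)
      lcc <- max(comp$csize) / n
      mdeg <- 2 * g$n_edges / n
      sw <- small_worldness(g, n_null = n_null, seed = seeds[k])
      rows[[k]] <- data.frame(
        subject = s, cost = cost,
        sigma = sw$sigma, sigma_ok = isTRUE(sw$sigma > 1),
        lcc_frac = lcc, lcc_ok = lcc >= lcc_frac,
        mean_degree = mdeg, degree_ok = mdeg > log(n))
    }
  }
  subjects <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(subjects, subjects$cost), function(d)
    data.frame(cost = d$cost[1],
               frac_sigma_ok = mean(d$sigma_ok),
               frac_lcc_ok = mean(d$lcc_ok),
               frac_degree_ok = mean(d$degree_ok))))
  rownames(summary) <- NULL
  list(subjects = subjects, summary = summary)
}
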