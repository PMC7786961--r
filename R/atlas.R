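#' Build a node atlas with planted network modules
#'
#' Constructs a label table assigning every node of a connectome to an
#' intrinsic-network module and to a community of interest
#' (`DN_CN`, `SVAN`, `SUBCORTICAL`, `OTHER`). The default 141-node layout
#' mirrors a whole-brain parcellation with 111 cortical nodes spread over
#' higher-order and sensory networks plus 30 subcortical nodes; module sizes
#' scale proportionally for other node counts.
#'
#' Two granularities are available. The `"fine"` scheme splits the default,
#' control and salience/ventral-attention systems into A/B subsystems and the
#' subcortex into striatum/thalamus/medial-temporal blocks (13 modules),
#' matching the module counts that resolution parameters around 2-3 recover on
#' real connectomes. The `"coarse"` scheme keeps 7 whole systems and is meant
#' for small scaled-down simulations.
#'
#' @param n_nodes total number of nodes (>= number of modules x 2).
#' @param scheme `"fine"` (13 modules) or `"coarse"` (7 modules); by default
#'   fine for 100+ nodes, coarse below.
#' @return data.frame with columns `node_id` (0-based, contiguous), `label`,
#'   `network`, `community_of_interest`, and attribute `"partition"` giving the
#'   planted module index per node.
#' @examples
#' atlas <- make_atlas(141)
#' table(atlas$community_of_interest)
#' @export
make_atlas <- function(n_nodes = 141,
                       scheme = if (n_nodes >= 100) "fine" else "coarse") {
  scheme <- match.arg(scheme, c("fine", "coarse"))
  tmpl <- if (scheme == "fine") {
    data.frame(
      network = c("DN-A", "DN-B", "CN-A", "CN-B", "SVAN-A", "SVAN-B",
                  "DATTN", "SMN", "VIS", "LIMBIC",
                  "STRIATUM", "THALAMUS", "MTL"),
      size141 = c(12, 12, 12, 12, 9, 9, 12, 12, 12, 9, 12, 8, 10),
      coi = c("DN_CN", "DN_CN", "DN_CN", "DN_CN", "SVAN", "SVAN",
              "OTHER", "OTHER", "OTHER", "OTHER",
              "SUBCORTICAL", "SUBCORTICAL", "SUBCORTICAL"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      network = c("DN", "CN", "SVAN", "SMN", "VIS", "LIMBIC", "SUBCORT"),
      size141 = c(26, 25, 18, 15, 14, 13, 30),
      coi = c("DN_CN", "DN_CN", "SVAN", "OTHER", "OTHER", "OTHER",
              "SUBCORTICAL"),
      stringsAsFactors = FALSE
    )
  }
  m <- nrow(tmpl)
  if (n_nodes < 2L * m)
    stop_fctopo("n_nodes = %d too small for the %s scheme (%d modules)",
                n_nodes, scheme, m)
  # proportional allocation, largest-remainder rounding, >= 2 nodes per module
  raw <- tmpl$size141 / sum(tmpl$size141) * n_nodes
  sizes <- pmax(2L, floor(raw))
  rem <- n_nodes - sum(sizes)
  if (rem > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    idx <- rep_len(ord, rem)
    for (i in idx) sizes[i] <- sizes[i] + 1L
  } else if (rem < 0) {
    ord <- order(sizes, decreasing = TRUE)
    k <- 1L
    while (rem < 0) {
      i <- ord[(k - 1L) %% m + 1L]
      if (sizes[i] > 2L) { sizes[i] <- sizes[i] - 1L; rem <- rem + 1L }
      k <- k + 1L
    }
  }
  module <- rep(seq_len(m), times = sizes)
  atlas <- data.frame(
    node_id = seq_len(n_nodes) - 1L,
    label = paste0(tmpl$network[module], "_",
                   unlist(lapply(sizes, seq_len))),
    network = tmpl$network[module],
    community_of_interest = tmpl$coi[module],
    stringsAsFactors = FALSE
  )
  attr(atlas, "partition") <- module
  atlas
}

#' Planted module partition of an atlas
#'
#' @param atlas result of [make_atlas()].
#' @return integer vector, one module id per node.
#' @export
atlas_partition <- function(atlas) {
  p <- attr(atlas, "partition")
  if (is.null(p)) p <- canonical_labels(atlas$network)
  p
}

#' Node ids belonging to a community of interest
#'
#' @param atlas result of [make_atlas()].
#' @param scope one of `"DN_CN"`, `"SVAN"`, `"SUBCORTICAL"`, `"OTHER"`.
#' @return integer vector of row indices (1-based) into the atlas.
#' @export
scope_nodes <- function(atlas, scope) {
  scope <- match.arg(scope, c("DN_CN", "SVAN", "SUBCORTICAL", "OTHER"))
  which(atlas$community_of_interest == scope)
}
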