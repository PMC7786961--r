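#' Build a weighted functional-connectivity matrix
#'
#' Pearson correlation between every pair of ROI time courses, with the main
#' diagonal and all negative correlations set to zero, yielding a symmetric
#' nonnegative weighted (non-binarized) connectivity matrix.
#'
#' @param ts a `subject_ts` or a plain frames x nodes numeric matrix.
#' @return N x N numeric matrix (class `matrix`), symmetric, zero diagonal,
#'   entries in [0, 1].
#' @examples
#' x <- matrix(rnorm(300), 100, 3)
#' fc <- build_fc(x)
#' all(diag(fc) == 0)
#' @export
build_fc <- function(ts) {
  x <- if (inherits(ts, "subject_ts")) ts$data else ts
  if (!is.matrix(x)) stop_fctopo("time series must be a frames x nodes matrix")
  if (nrow(x) < 3)
    stop_fctopo("insufficient data: need >= 3 frames, got %d", nrow(x))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0] %||% which(sds == 0)
    stop_fctopo("zero-variance ROI(s): %s",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  fc <- stats::cor(x)
  fc[fc < 0] <- 0
  diag(fc) <- 0
  # enforce exact symmetry against floating-point asymmetry in cor()
  (fc + t(fc)) / 2
}

#' Integrated mean functional connectivity across the cost range
#'
#' For each cost in the grid, the mean weight of edges surviving
#' thresholding; the per-cost means are then aggregated over the cost axis by
#' the trapezoidal rule, giving one area-under-the-curve FC-strength summary
#' per subject. Used as a covariate to dissociate topology differences from
#' raw connectivity-strength differences.
#'
#' @param fc connectivity matrix from [build_fc()].
#' @param grid cost grid from [cost_grid()] (length >= 2).
#' @return scalar AUC of mean surviving-edge weight over cost.
#' @export
integrated_mean_fc <- function(fc, grid) {
  if (length(grid) < 2) stop_fctopo("cost grid must have length >= 2")
  means <- vapply(grid, function(cost) {
    g <- threshold_at_cost(fc, cost)
    w <- g$weights[upper.tri(g$weights)]
    w <- w[w > 0]
    if (length(w)) mean(w) else 0
  }, numeric(1))
  pracma::trapz(grid, means)
}
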