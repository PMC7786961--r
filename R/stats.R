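#' Covariate-adjusted group contrasts on nodal metrics
#'
#' Per node and metric, ordinary least squares of the cost-integrated metric
#' value on group membership plus nuisance covariates (by default education
#' years, scanner type, and frames retained after scrubbing). Every pairwise
#' group contrast gets a two-sided t-test; following the reporting
#' convention for exploratory nodal maps, p-values are uncorrected across
#' nodes (an FDR column is appended for convenience).
#'
#' @param metrics long table from [nodal_metric_table()] (subject_id,
#'   node_id, metric, value).
#' @param cohort cohort table (one row per subject) with a `group` factor
#'   whose first level is the reference, plus the covariate columns.
#' @param covariates character vector of cohort columns to adjust for.
#' @param extra_covariates optional additional cohort columns (e.g.
#'   `"integrated_fc"`).
#' @param gm_volume optional subjects x nodes matrix of gray-matter volumes
#'   (rownames = subject ids); the node-matched column is added as a
#'   covariate for each node's model.
#' @return data.frame: node_id, metric, contrast ("A-B" = A minus B),
#'   estimate, se, t, p_uncorrected, significant (p <= .05), p_fdr.
#' @export
nodal_group_glm <- function(metrics, cohort,
                            covariates = c("education", "scanner",
                                           "frames_retained"),
                            extra_covariates = NULL, gm_volume = NULL) {
  covs <- c(covariates, extra_covariates)
  missing_cols <- setdiff(c("group", covs), names(cohort))
  if (length(missing_cols))
    stop_fctopo("cohort lacks column(s): %s",
                paste(missing_cols, collapse = ", "))
  if (!is.factor(cohort$group)) cohort$group <- factor(cohort$group)
  if (nlevels(droplevels(cohort$group)) < 2)
    stop_fctopo("need >= 2 groups")
  rows <- list()
  for (m in unique(metrics$metric)) {
    dm <- metrics[metrics$metric == m, ]
    for (node in unique(dm$node_id)) {
      dn <- dm[dm$node_id == node, ]
      d <- merge(dn, cohort, by = "subject_id")
      if (!is.null(gm_volume))
        d$gm_volume_node <- gm_volume[d$subject_id, node + 1L]
      use_covs <- c(covs, if (!is.null(gm_volume)) "gm_volume_node")
      fml <- stats::reformulate(c("group", use_covs), response = "value")
      fit <- stats::lm(fml, data = d)
      if (anyNA(stats::coef(fit)))
        stop_fctopo("rank-deficient design; collinear column(s): %s",
                    paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                          collapse = ", "))
      rows[[length(rows) + 1L]] <- group_contrasts(fit, d$group, node, m)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::ave(out$p_uncorrected, out$metric, out$contrast,
                          FUN = function(p) stats::p.adjust(p, "fdr"))
  rownames(out) <- NULL
  out
}

# all pairwise group contrasts from a fitted lm with `group` factor
group_contrasts <- function(fit, group, node, metric) {
  lev <- levels(droplevels(group))
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  df <- stats::df.residual(fit)
  coef_name <- function(g) paste0("group", g)
  pairs <- utils::combn(lev, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    b <- pairs[1, k]  # earlier level; contrast reported as later - earlier
    a <- pairs[2, k]
    if (b == lev[1]) {
      est <- cf[coef_name(a)]
      se <- sqrt(vc[coef_name(a), coef_name(a)])
    } else {
      est <- cf[coef_name(a)] - cf[coef_name(b)]
      se <- sqrt(vc[coef_name(a), coef_name(a)] +
                   vc[coef_name(b), coef_name(b)] -
                   2 * vc[coef_name(a), coef_name(b)])
    }
    tval <- est / se
    p <- 2 * stats::pt(-abs(tval), df)
    data.frame(node_id = node, metric = metric,
               contrast = paste0(a, "-", b),
               estimate = unname(est), se = unname(se), t = unname(tval),
               p_uncorrected = unname(p),
               significant = !is.na(p) & p <= 0.05,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' ANOVA and Bonferroni-corrected post hoc tests on ARI distributions
#'
#' Per scope, a one-way ANOVA of the subgroup adjusted Rand indices across
#' groups, followed by pooled-variance two-tailed two-sample t-tests for all
#' group pairs with Bonferroni correction over the pairs within the scope.
#'
#' @param results long data.frame from [resample_group_similarity()] (group,
#'   scope, subgroup, ari).
#' @return list with `anova` (scope, df1, df2, F, p) and `posthoc` (scope,
#'   contrast, t, df, p, p_bonferroni, significant at .05).
#' @export
ari_anova <- function(results) {
  scopes <- unique(results$scope)
  an <- list(); ph <- list()
  for (sc in scopes) {
    d <- results[results$scope == sc, ]
    d$group <- droplevels(factor(d$group))
    if (nlevels(d$group) < 2 || any(table(d$group) < 2))
      stop_fctopo("scope %s needs >= 2 groups with >= 2 values each", sc)
    if (all(tapply(d$ari, d$group, stats::var) == 0))
      stop_fctopo("degenerate input: zero within-group variance in scope %s",
                  sc)
    av <- stats::anova(stats::lm(ari ~ group, data = d))
    an[[sc]] <- data.frame(scope = sc, df1 = av$Df[1], df2 = av$Df[2],
                           F = av$`F value`[1], p = av$`Pr(>F)`[1],
                           stringsAsFactors = FALSE)
    pairs <- utils::combn(levels(d$group), 2)
    n_pairs <- ncol(pairs)
    ph[[sc]] <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
      x <- d$ari[d$group == pairs[1, k]]
      y <- d$ari[d$group == pairs[2, k]]
      df <- length(x) + length(y) - 2L
      s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
      if (s2 > 0) {
        tval <- (mean(x) - mean(y)) /
          sqrt(s2 * (1 / length(x) + 1 / length(y)))
        p <- 2 * stats::pt(-abs(tval), df)
      } else {
        # both groups constant: identical means are indistinguishable,
        # different means are perfectly separated
        tval <- sign(mean(x) - mean(y)) * Inf
        p <- if (mean(x) == mean(y)) 1 else 0
        if (is.nan(tval)) tval <- 0
      }
      p_b <- min(1, p * n_pairs)
      data.frame(scope = sc,
                 contrast = paste0(pairs[1, k], "-", pairs[2, k]),
                 t = tval, df = df, p = p, p_bonferroni = p_b,
                 significant = p_b < 0.05, stringsAsFactors = FALSE)
    }))
  }
  list(anova = do.call(rbind, c(an, make.row.names = FALSE)),
       posthoc = do.call(rbind, c(ph, make.row.names = FALSE)))
}

#' Covariate-residualized Pearson correlation
#'
#' Both the connectivity metric and the behavior score are residualized on
#' the covariates (by default age, gender, education, scanner) by least
#' squares; Pearson's correlation is computed on the residuals with a
#' two-sided t-test on n - 2 - k degrees of freedom (k = covariate design
#' columns beyond the intercept), i.e. the partial-correlation test, so the
#' test stays calibrated at small n.
#'
#' @param metric_values numeric vector, one value per cohort row.
#' @param scores numeric vector of behavior/cognition scores, same length.
#' @param cohort cohort table supplying the covariate columns.
#' @param covariates cohort columns to regress out.
#' @return list with `r`, `p`, `df`, and the residual vectors.
#' @export
residual_correlation <- function(metric_values, scores, cohort,
                                 covariates = c("age", "gender",
                                                "education", "scanner")) {
  n <- nrow(cohort)
  if (length(metric_values) != n || length(scores) != n)
    stop_fctopo("metric and score vectors must match the cohort rows")
  if (n < length(covariates) + 3)
    stop_fctopo("need at least %d subjects for %d covariates",
                length(covariates) + 3, length(covariates))
  d <- cohort[, covariates, drop = FALSE]
  d$..x <- metric_values
  d$..y <- scores
  fit_x <- stats::lm(stats::reformulate(covariates, "..x"), data = d)
  rx <- stats::resid(fit_x)
  ry <- stats::resid(stats::lm(stats::reformulate(covariates, "..y"), data = d))
  tol_x <- 1e-10 * max(stats::sd(d$..x), 1)
  tol_y <- 1e-10 * max(stats::sd(d$..y), 1)
  if (stats::sd(rx) <= tol_x || stats::sd(ry) <= tol_y)
    stop_fctopo("undefined correlation: constant residuals")
  r <- stats::cor(rx, ry)
  k <- fit_x$rank - 1L
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, df = df, residual_x = rx, residual_y = ry)
}
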