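make_null_cohort <- function(n_per_group, groups = c("HC", "AD", "bvFTD")) {
  n <- n_per_group * length(groups)
  data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = factor(rep(groups, each = n_per_group), levels = groups),
    age = rnorm(n, 64, 5),
    gender = sample(c("M", "F"), n, replace = TRUE),
    education = rnorm(n, 11, 3),
    scanner = sample(c("TimTrio", "Prisma"), n, replace = TRUE),
    frames_retained = sample(120:235, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

metric_row <- function(cohort, values, metric = "degree", node = 0L) {
  data.frame(subject_id = cohort$subject_id, node_id = node,
             metric = metric, value = values, stringsAsFactors = FALSE)
}

test_that("GLM coefficients match a normal-equations oracle on a tiny table", {
  cohort <- data.frame(
    subject_id = paste0("s", 1:6),
    group = factor(c("HC", "HC", "HC", "AD", "AD", "AD"),
                   levels = c("HC", "AD")),
    education = c(10, 12, 14, 9, 11, 13),
    scanner = rep("A", 6),
    frames_retained = c(200, 210, 220, 190, 205, 215),
    stringsAsFactors = FALSE)
  vals <- c(1.0, 1.2, 1.1, 0.7, 0.8, 0.9)
  res <- nodal_group_glm(metric_row(cohort, vals), cohort,
                         covariates = c("education", "frames_retained"))
  X <- cbind(1, cohort$group == "AD", cohort$education,
             cohort$frames_retained)
  beta <- solve(t(X) %*% X, t(X) %*% vals)
  expect_equal(res$estimate[res$contrast == "AD-HC"], beta[2],
               tolerance = 1e-8)
})

test_that("covariate-free balanced two-group GLM reproduces the t-test", {
  set.seed(101)
  cohort <- make_null_cohort(12, c("HC", "AD"))
  vals <- rnorm(24) + 0.8 * (cohort$group == "AD")
  res <- nodal_group_glm(metric_row(cohort, vals), cohort,
                         covariates = character(0))
  tt <- t.test(vals[cohort$group == "AD"], vals[cohort$group == "HC"],
               var.equal = TRUE)
  expect_equal(res$t[res$contrast == "AD-HC"], unname(tt$statistic),
               tolerance = 1e-10)
  expect_equal(res$p_uncorrected[res$contrast == "AD-HC"], tt$p.value,
               tolerance = 1e-10)
})

test_that("all pairwise contrasts are reported with the re-referenced pair", {
  set.seed(102)
  cohort <- make_null_cohort(10)
  vals <- rnorm(30)
  res <- nodal_group_glm(metric_row(cohort, vals), cohort)
  expect_setequal(res$contrast, c("AD-HC", "bvFTD-HC", "bvFTD-AD"))
  # the AD-bvFTD contrast equals refitting with AD as reference
  cohort2 <- cohort
  cohort2$group <- relevel(cohort2$group, "AD")
  res2 <- nodal_group_glm(metric_row(cohort2, vals), cohort2)
  expect_equal(res$estimate[res$contrast == "bvFTD-AD"],
               res2$estimate[res2$contrast == "bvFTD-AD"], tolerance = 1e-10)
  expect_equal(res$t[res$contrast == "bvFTD-AD"],
               res2$t[res2$contrast == "bvFTD-AD"], tolerance = 1e-10)
})

test_that("collinear designs fail with the offending column named", {
  set.seed(103)
  cohort <- make_null_cohort(8, c("HC", "AD"))
  cohort$shadow <- cohort$education  # exact copy
  expect_error(
    nodal_group_glm(metric_row(cohort, rnorm(16)), cohort,
                    covariates = c("education", "shadow")),
    "collinear.*shadow")
})

test_that("type-I error of the nodal GLM is near nominal under the null", {
  set.seed(104)
  # several independent null nodes per simulated cohort sharpen the rate
  # estimate without changing the per-test nominal level
  rej <- unlist(replicate(200, {
    cohort <- make_null_cohort(15, c("HC", "AD"))
    metrics <- do.call(rbind, lapply(0:4, function(nd)
      metric_row(cohort, rnorm(30), node = nd)))
    res <- nodal_group_glm(metrics, cohort)
    res$p_uncorrected[res$contrast == "AD-HC"] <= 0.05
  }, simplify = FALSE))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("a planted 1-SD group deficit is detected with the correct sign", {
  set.seed(105)
  hits <- mean(replicate(100, {
    cohort <- make_null_cohort(20, c("HC", "AD"))
    vals <- rnorm(40) - 1.0 * (cohort$group == "AD")
    res <- nodal_group_glm(metric_row(cohort, vals, "within_module_z"),
                           cohort)
    row <- res[res$contrast == "AD-HC", ]
    row$estimate < 0 && row$p_uncorrected <= 0.05
  }))
  expect_gte(hits, 0.8)
})

test_that("null GLM p-values are uniform (KS)", {
  set.seed(106)
  ps <- replicate(500, {
    cohort <- make_null_cohort(10, c("HC", "AD"))
    vals <- rnorm(20)
    res <- nodal_group_glm(metric_row(cohort, vals), cohort,
                           covariates = "education")
    res$p_uncorrected[res$contrast == "AD-HC"]
  })
  expect_gt(ks.test(ps, punif)$p.value, 0.01)
})

test_that("ARI ANOVA matches the hand-computed mean-square ratio", {
  toy <- data.frame(
    group = factor(rep(c("A", "B", "C"), each = 4)),
    scope = "whole_brain", subgroup = rep(1:4, 3),
    ari = c(0.9, 0.8, 0.85, 0.95, 0.6, 0.55, 0.65, 0.6, 0.3, 0.35, 0.4, 0.25))
  res <- ari_anova(toy)
  grand <- mean(toy$ari)
  ms_b <- sum(4 * (tapply(toy$ari, toy$group, mean) - grand)^2) / 2
  ms_w <- sum((toy$ari - ave(toy$ari, toy$group))^2) / 9
  expect_equal(res$anova$F, ms_b / ms_w, tolerance = 1e-10)
  expect_equal(res$anova$df1, 2)
  expect_equal(res$anova$df2, 9)
  expect_equal(nrow(res$posthoc), 3)
  # only contrasts involving the clearly shifted group C survive Bonferroni
  expect_true(all(res$posthoc$significant[grepl("C", res$posthoc$contrast)]))
})

test_that("ARI ANOVA rejects at the nominal rate under a common null", {
  set.seed(107)
  rej <- mean(replicate(200, {
    d <- data.frame(group = factor(rep(c("A", "B", "C"), each = 10)),
                    scope = "whole_brain", subgroup = rep(1:10, 3),
                    ari = rnorm(30, 0.7, 0.1))
    ari_anova(d)$anova$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  expect_error(
    ari_anova(data.frame(group = factor(rep(c("A", "B"), each = 3)),
                         scope = "s", subgroup = rep(1:3, 2),
                         ari = rep(0.5, 6))),
    "degenerate")
})

test_that("residual correlation is exact for linear dependence and matches
           the partial-correlation identity", {
  set.seed(108)
  cohort <- make_null_cohort(15)
  x <- rnorm(45)
  res <- residual_correlation(x, 2 * x + 1, cohort)
  expect_equal(res$r, 1, tolerance = 1e-10)

  # partial-correlation identity with one numeric covariate
  z <- rnorm(45)
  x2 <- rnorm(45) + z
  y2 <- rnorm(45) + 0.5 * z
  cohort$z <- z
  res2 <- residual_correlation(x2, y2, cohort, covariates = "z")
  r_xy <- cor(x2, y2); r_xz <- cor(x2, z); r_yz <- cor(y2, z)
  partial <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  expect_equal(res2$r, partial, tolerance = 1e-10)
})

test_that("residual correlation is invariant to affine covariate rescaling", {
  set.seed(109)
  cohort <- make_null_cohort(12)
  x <- rnorm(36); y <- rnorm(36)
  a <- residual_correlation(x, y, cohort,
                            covariates = c("age", "education"))
  cohort$age <- 10 * cohort$age - 300
  cohort$education <- cohort$education / 7 + 2
  b <- residual_correlation(x, y, cohort,
                            covariates = c("age", "education"))
  expect_equal(a$r, b$r, tolerance = 1e-10)
  expect_error(residual_correlation(x, rep(1, 36), cohort), "constant")
})

test_that("null residual correlations are centered with nominal rejection", {
  set.seed(110)
  out <- replicate(500, {
    cohort <- make_null_cohort(10)
    r <- residual_correlation(rnorm(30), rnorm(30), cohort)
    c(r$r, r$p)
  })
  expect_lt(abs(mean(out[1, ])), 0.03)
  rej <- mean(out[2, ] < 0.05)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})
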