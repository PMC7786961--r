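test_that("adjusted Rand index handles identity, relabeling, and extremes", {
  p <- c(1, 1, 2, 2, 3)
  expect_equal(adjusted_rand(p, p), 1)
  expect_equal(adjusted_rand(p, c(7, 7, 5, 5, 9)), 1)  # label invariance
  # all singletons vs one community on 4 nodes
  expect_equal(adjusted_rand(1:4, rep(1, 4)), 0)
  expect_error(adjusted_rand(1:4, 1:5), "node set")
})

test_that("ARI matches the mclust oracle on random partition pairs", {
  skip_if_not_installed("mclust")
  set.seed(81)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    p1 <- sample(1:4, n, replace = TRUE)
    p2 <- sample(1:4, n, replace = TRUE)
    expect_equal(adjusted_rand(p1, p2), mclust::adjustedRandIndex(p1, p2),
                 tolerance = 1e-10)
    expect_equal(adjusted_rand(p1, p2), adjusted_rand(p2, p1))
  }
})

test_that("ARI of independent random partitions is centered at zero", {
  set.seed(91)
  vals <- replicate(500, {
    adjusted_rand(sample(1:3, 30, replace = TRUE),
                  sample(1:3, 30, replace = TRUE))
  })
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("restricted ARI equals manual sub-partition extraction", {
  p1 <- c(1, 1, 2, 2, 3, 3, 4, 4)
  p2 <- c(1, 1, 2, 2, 4, 4, 3, 5)  # agrees on nodes 1-4 only
  expect_equal(restricted_ari(p1, p2, 1:4), 1)
  sub <- 3:8
  manual <- adjusted_rand(match(p1[sub], unique(p1[sub])),
                          match(p2[sub], unique(p2[sub])))
  expect_equal(restricted_ari(p1, p2, sub), manual)
  expect_error(restricted_ari(p1, p2, 4), ">= 2")
})

test_that("subgroup resampling emits the configured arity, deterministically", {
  set.seed(7)
  parts <- replicate(6, sample(1:3, 20, replace = TRUE), simplify = FALSE)
  ref <- parts[[1]]
  atlas <- make_atlas(20)
  sim <- resample_group_similarity(
    list(A = parts[1:3], B = parts[4:6]), ref, atlas,
    n_subgroups = 5, subgroup_size = 4, seed = 11)
  counts <- table(sim$group, sim$scope)
  expect_true(all(counts == 5))
  expect_true(all(sim$ari >= -1 & sim$ari <= 1))
  sim2 <- resample_group_similarity(
    list(A = parts[1:3], B = parts[4:6]), ref, atlas,
    n_subgroups = 5, subgroup_size = 4, seed = 11)
  expect_identical(sim, sim2)
  expect_error(resample_group_similarity(list(A = list()), ref, atlas),
               "no subjects")
})

test_that("groups identical to the reference score ARI 1 everywhere", {
  atlas <- make_atlas(20)
  ref <- atlas_partition(atlas)
  parts <- replicate(4, ref, simplify = FALSE)
  sim <- resample_group_similarity(list(HC = parts), ref, atlas,
                                   n_subgroups = 3, subgroup_size = 3,
                                   seed = 5)
  expect_true(all(sim$ari == 1))
})

test_that("planted SVAN fragmentation lowers SVAN-scope similarity", {
  atlas <- make_atlas(30)
  specs <- list(
    HC = group_spec(8),
    bvFTD = default_group_specs(atlas, n_bvftd = 8)$bvFTD)
  specs$bvFTD$n_subjects <- 8L
  deltas <- vapply(1:4, function(rep) {
    cfg <- simulation_config(n_nodes = 30, atlas = atlas, n_frames = 100,
                             group_specs = specs, seed = 200 + rep)
    coh <- generate_cohort(cfg)
    fcs <- lapply(coh$timeseries, build_fc)
    parts <- lapply(seq_along(fcs), function(i)
      subject_consensus(fcs[[i]], fine_grid = cost_grid(0.09, 0.40, 0.05),
                        gamma = 3, seed = 300 + i,
                        n_restarts = 4)$partition)
    by_group <- split(parts, coh$cohort$group)
    ref <- group_partition(by_group$HC, gamma = 2, seed = 17)$partition
    sim <- resample_group_similarity(by_group, ref, atlas, n_subgroups = 8,
                                     subgroup_size = 6, seed = 400 + rep,
                                     scopes = "SVAN")
    agg <- tapply(sim$ari[sim$scope == "SVAN"],
                  droplevels(sim$group[sim$scope == "SVAN"]), mean)
    agg[["HC"]] - agg[["bvFTD"]]
  }, numeric(1))
  # perfect separation makes the deltas constant; fall back to a sign check
  if (sd(deltas) == 0) {
    expect_true(all(deltas > 0))
  } else {
    expect_lt(t.test(deltas, alternative = "greater")$p.value, 0.05)
  }
})
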