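test_that("cohort bookkeeping matches the configuration", {
  cfg <- simulation_config(
    n_nodes = 30, atlas = make_atlas(30), n_frames = 40,
    group_specs = list(HC = group_spec(3), AD = group_spec(3)), seed = 2)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$cohort), 6)
  expect_equal(as.vector(table(coh$cohort$group)), c(3, 3))
  expect_length(coh$timeseries, 6)
  expect_equal(dim(coh$timeseries[[1]]$data), c(40, 30))
  expect_equal(length(coh$timeseries[[1]]$fd), 40)
  expect_false(anyNA(coh$timeseries[[4]]$data))
  expect_equal(dim(coh$gm_volume), c(6, 30))
})

test_that("identical seeds give bit-identical cohorts", {
  cfg <- simulation_config(
    n_nodes = 20, atlas = make_atlas(20), n_frames = 30,
    group_specs = list(HC = group_spec(2), bvFTD = group_spec(2)), seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$gm_volume, b$gm_volume)
})

test_that("partition size mismatch is a configuration error", {
  expect_error(
    simulation_config(n_nodes = 20, atlas = make_atlas(20),
                      planted_partition = rep(1:2, 5),
                      group_specs = list(HC = group_spec(2))),
    "configuration error")
})

test_that("group_spec rejects inconsistent correlation parameters", {
  expect_error(group_spec(3, rho_within = 0.3, rho_between = 0.5),
               "rho_between")
  expect_error(group_spec(3, rho_within = 0.4, lesion_delta = 0.6),
               "lesion_delta")
})

test_that("within-module correlation exceeds between-module correlation", {
  atlas <- make_atlas(30)
  part <- atlas_partition(atlas)
  cfg <- simulation_config(n_nodes = 30, atlas = atlas, n_frames = 120,
                           group_specs = list(HC = group_spec(22)), seed = 31)
  coh <- generate_cohort(cfg)
  same <- outer(part, part, "==") & upper.tri(diag(30))
  diff <- outer(part, part, "!=") & upper.tri(diag(30))
  deltas <- vapply(coh$timeseries, function(ts) {
    cm <- cor(ts$data)
    mean(cm[same]) - mean(cm[diff])
  }, numeric(1))
  expect_lt(t.test(deltas, alternative = "greater")$p.value, 0.01)
  expect_true(all(deltas > 0))
})

test_that("raising lesion_delta strictly lowers FC inside lesioned modules", {
  atlas <- make_atlas(30)
  part <- atlas_partition(atlas)
  svan <- unique(part[atlas$community_of_interest == "SVAN"])
  les_nodes <- which(part %in% svan)
  mask <- upper.tri(diag(30)) & outer(part, part, "==") &
    outer(seq_len(30) %in% les_nodes, seq_len(30) %in% les_nodes, "&")
  mean_fc <- vapply(c(0, 0.3, 0.6), function(delta) {
    cfg <- simulation_config(
      n_nodes = 30, atlas = atlas, n_frames = 120,
      group_specs = list(G = group_spec(10, lesioned_modules = svan,
                                        lesion_delta = delta)),
      seed = 77)
    coh <- generate_cohort(cfg)
    mean(vapply(coh$timeseries,
                function(ts) mean(cor(ts$data)[mask]), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_fc) < 0))
})

test_that("merged module pairs show elevated mutual correlation", {
  atlas <- make_atlas(30)
  part <- atlas_partition(atlas)
  cfg <- simulation_config(
    n_nodes = 30, atlas = atlas, n_frames = 200,
    group_specs = list(G = group_spec(10, merge_pairs = list(c(1, 2)),
                                      merge_rho = 0.5)),
    seed = 13)
  coh <- generate_cohort(cfg)
  cross12 <- outer(part == 1, part == 2, "&")
  cross13 <- outer(part == 1, part == 3, "&")
  m <- sapply(coh$timeseries, function(ts) {
    cm <- cor(ts$data)
    c(mean(cm[cross12]), mean(cm[cross13]))
  })
  expect_gt(mean(m[1, ]), 0.4)   # merged pair near merge_rho
  expect_lt(mean(m[2, ]), 0.15)  # untouched pair near rho_between
})

test_that("motion traces respect spike probability extremes and scaling", {
  quiet <- generate_motion_trace(200, spike_prob = 0, seed = 4)
  expect_true(all(quiet$fd < 0.5) && all(quiet$dvars < 0.5))
  wild <- generate_motion_trace(200, spike_prob = 1, seed = 4)
  expect_true(all(wild$fd > 0.5) && all(wild$dvars > 0.5))
  expect_error(generate_motion_trace(10, spike_scale = -1),
               "configuration error")
  expect_identical(generate_motion_trace(50, 0.2, seed = 8),
                   generate_motion_trace(50, 0.2, seed = 8))
})

test_that("spike counts follow the binomial expectation", {
  counts <- vapply(1:200, function(s) {
    mt <- generate_motion_trace(1000, spike_prob = 0.1, seed = s)
    sum(mt$fd > 0.5)
  }, numeric(1))
  se <- sqrt(0.1 * 0.9 * 1000)  # binomial sd of one trace
  expect_lt(abs(mean(counts) - 100), 3 * se / sqrt(200))
})

test_that("coupled behavior score recovers the planted slope direction", {
  atlas <- make_atlas(30)
  cfg <- simulation_config(
    n_nodes = 30, atlas = atlas, n_frames = 100,
    group_specs = list(HC = group_spec(25)),
    behavior_coupling = list(target_metric = "mean_fc", slope = 50,
                             noise_sd = 0.1),
    seed = 21)
  coh <- generate_cohort(cfg)
  fc_means <- vapply(coh$timeseries, function(ts) {
    cm <- cor(ts$data)
    mean(pmax(cm[upper.tri(cm)], 0))
  }, numeric(1))
  expect_gt(cor(fc_means, coh$cohort$coupled_score), 0.8)
})
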