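#' Group specification for the synthetic cohort
#'
#' Describes one diagnostic group of the simulated cohort: its size, the
#' latent-factor correlation structure of its ROI signals, and its planted
#' topological lesions. Node signals follow a factor model
#' `x = a * z_module + b * s_merge + c * g_global + noise_sd * e`, with
#' coefficients chosen so that the expected correlation is `rho_within`
#' inside an intact module, `rho_within - lesion_delta` inside a lesioned
#' module, `merge_rho` between (and within, when the lesion depth reaches it)
#' modules listed in `merge_pairs`, and `rho_between` elsewhere.
#'
#' @param n_subjects number of subjects in the group.
#' @param rho_within expected node-pair correlation inside an intact module.
#' @param rho_between background correlation between modules.
#' @param lesioned_modules integer module ids whose within-module correlation
#'   is reduced by `lesion_delta`.
#' @param lesion_delta correlation decrement applied to lesioned modules.
#' @param merge_pairs list of length-2 integer vectors: module pairs whose
#'   mutual correlation is raised to `merge_rho` (pairs are pooled into
#'   connected components sharing one latent signal).
#' @param merge_rho elevated correlation between merged modules.
#' @return list of class `group_spec`.
#' @export
group_spec <- function(n_subjects, rho_within = 0.9, rho_between = 0.05,
                       lesioned_modules = integer(0), lesion_delta = 0,
                       merge_pairs = list(), merge_rho = 0.45) {
  if (!(rho_between >= 0 && rho_between < rho_within && rho_within <= 1))
    stop_fctopo("need 0 <= rho_between < rho_within <= 1 (got %g, %g)",
                rho_between, rho_within)
  if (lesion_delta < 0 || rho_within - lesion_delta < 0)
    stop_fctopo("lesion_delta %g must satisfy 0 <= rho_within - lesion_delta",
                lesion_delta)
  if (length(merge_pairs) && merge_rho < rho_between)
    stop_fctopo("merge_rho must be >= rho_between")
  structure(list(n_subjects = as.integer(n_subjects), rho_within = rho_within,
                 rho_between = rho_between,
                 lesioned_modules = as.integer(lesioned_modules),
                 lesion_delta = lesion_delta, merge_pairs = merge_pairs,
                 merge_rho = merge_rho),
            class = "group_spec")
}

# module ids carrying a given community-of-interest label
modules_of_coi <- function(atlas, coi) {
  part <- atlas_partition(atlas)
  unique(part[atlas$community_of_interest == coi])
}

#' Default three-group specification (HC / AD-like / bvFTD-like)
#'
#' Encodes the study conditions the pipeline is exercised under: a healthy
#' control group with intact planted structure; an AD-like group whose
#' default and control modules lose within-module coherence and merge into
#' one less distinctive block; and a bvFTD-like group with fragmented
#' salience/ventral-attention and subcortical modules plus elevated
#' salience-subcortical coupling. Group sizes default to the 47/50/14 split
#' of the motivating cohort.
#'
#' @param atlas result of [make_atlas()].
#' @param n_hc,n_ad,n_bvftd group sizes.
#' @param lesion_delta,merge_rho lesion severity parameters shared by both
#'   patient groups.
#' @return named list of [group_spec()] objects (`HC`, `AD`, `bvFTD`).
#' @export
default_group_specs <- function(atlas, n_hc = 47, n_ad = 50, n_bvftd = 14,
                                lesion_delta = 0.45, merge_rho = 0.45) {
  dncn <- modules_of_coi(atlas, "DN_CN")
  svan <- modules_of_coi(atlas, "SVAN")
  subc <- modules_of_coi(atlas, "SUBCORTICAL")
  pair_up <- function(ids) {
    if (length(ids) < 2) return(list())
    cmb <- utils::combn(ids, 2)
    lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
  }
  list(
    HC = group_spec(n_hc),
    AD = group_spec(n_ad, lesioned_modules = dncn,
                    lesion_delta = lesion_delta,
                    merge_pairs = pair_up(dncn), merge_rho = merge_rho),
    bvFTD = group_spec(n_bvftd, lesioned_modules = c(svan, subc),
                       lesion_delta = lesion_delta,
                       merge_pairs = c(pair_up(svan),
                                       pair_up(c(svan[1], subc[1]))),
                       merge_rho = merge_rho)
  )
}

#' Simulation configuration for a synthetic cohort
#'
#' @param n_nodes number of ROIs.
#' @param atlas node atlas; defaults to [make_atlas()] at `n_nodes`.
#' @param planted_partition module id per node; defaults to the atlas modules.
#' @param group_specs named list of [group_spec()]; defaults to
#'   [default_group_specs()].
#' @param n_frames frames per subject (default 235: an 8-minute acquisition
#'   at TR 2 s minus 5 dropped volumes).
#' @param tr_seconds repetition time in seconds.
#' @param noise_sd standard deviation of the i.i.d. node noise; `NULL` picks
#'   `sqrt(1 - rho_within)` per group so intact-module signals have unit
#'   variance and empirical correlations match the nominal rho values.
#' @param behavior_coupling list with `target_metric` (`"mean_fc"` or
#'   `"lesioned_fc"`), `slope`, and `noise_sd`: the cohort's `coupled_score`
#'   column is `slope * metric + noise`, giving correlation analyses a known
#'   ground truth. Between-subject spread of mean FC is small (about 0.02 at
#'   default sizes), so the default slope 50 / noise 0.5 plants a strong but
#'   noisy association.
#' @param motion list with `spike_prob` and `spike_scale` passed to
#'   [generate_motion_trace()].
#' @param simulate_gm logical: also draw node-wise gray-matter volumes?
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(n_nodes = 141, atlas = make_atlas(n_nodes),
                              planted_partition = atlas_partition(atlas),
                              group_specs = default_group_specs(atlas),
                              n_frames = 235, tr_seconds = 2,
                              noise_sd = NULL,
                              behavior_coupling = list(
                                target_metric = "mean_fc",
                                slope = 50, noise_sd = 0.5),
                              motion = list(spike_prob = 0.05,
                                            spike_scale = 0.5),
                              simulate_gm = TRUE, seed = 1L) {
  if (length(planted_partition) != n_nodes)
    stop_fctopo("configuration error: planted_partition has %d nodes, expected %d",
                length(planted_partition), n_nodes)
  if (n_frames < 2) stop_fctopo("n_frames must be >= 2")
  if (is.null(names(group_specs)) || any(names(group_specs) == ""))
    stop_fctopo("group_specs must be a named list")
  structure(list(n_nodes = as.integer(n_nodes), atlas = atlas,
                 planted_partition = as.integer(planted_partition),
                 group_specs = group_specs, n_frames = as.integer(n_frames),
                 tr_seconds = tr_seconds, noise_sd = noise_sd,
                 behavior_coupling = behavior_coupling, motion = motion,
                 simulate_gm = isTRUE(simulate_gm), seed = as.integer(seed)),
            class = "sim_config")
}

# merge components: pool merge_pairs into connected components of module ids;
# returns integer component id per module (NA when not merged)
merge_components <- function(n_modules, merge_pairs) {
  comp <- rep(NA_integer_, n_modules)
  if (!length(merge_pairs)) return(comp)
  g <- igraph::graph_from_edgelist(
    do.call(rbind, lapply(merge_pairs, as.integer)), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_modules - igraph::vcount(g)))
  mem <- igraph::components(g)$membership
  touched <- sort(unique(unlist(merge_pairs)))
  comp[touched] <- canonical_labels(mem[touched])
  comp
}

# per-node factor loadings for one group
node_loadings <- function(spec, partition) {
  n_modules <- max(partition)
  comp <- merge_components(n_modules, spec$merge_pairs)
  rho_eff <- rep(spec$rho_within, n_modules)
  rho_eff[spec$lesioned_modules] <- spec$rho_within - spec$lesion_delta
  a <- b <- numeric(n_modules)
  for (m in seq_len(n_modules)) {
    if (!is.na(comp[m])) {
      b[m] <- sqrt(spec$merge_rho - spec$rho_between)
      a[m] <- sqrt(max(rho_eff[m] - spec$merge_rho, 0))
    } else {
      a[m] <- sqrt(max(rho_eff[m] - spec$rho_between, 0))
    }
  }
  list(a = a[partition], b = b[partition], comp = comp[partition],
       c = sqrt(spec$rho_between), n_comp = max(c(0L, comp), na.rm = TRUE))
}

simulate_subject_data <- function(spec, partition, n_frames, noise_sd) {
  ld <- node_loadings(spec, partition)
  n_nodes <- length(partition)
  n_modules <- max(partition)
  Z <- matrix(stats::rnorm(n_frames * n_modules), n_frames, n_modules)
  G <- stats::rnorm(n_frames)
  S <- if (ld$n_comp > 0)
    matrix(stats::rnorm(n_frames * ld$n_comp), n_frames, ld$n_comp)
  else NULL
  sd_e <- noise_sd %||% sqrt(1 - spec$rho_within)
  X <- Z[, partition, drop = FALSE] *
    matrix(ld$a, n_frames, n_nodes, byrow = TRUE) +
    outer(G, rep(ld$c, n_nodes))
  if (!is.null(S)) {
    has <- !is.na(ld$comp)
    X[, has] <- X[, has] + S[, ld$comp[has], drop = FALSE] *
      matrix(ld$b[has], n_frames, sum(has), byrow = TRUE)
  }
  X + matrix(stats::rnorm(n_frames * n_nodes, sd = sd_e), n_frames, n_nodes)
}

# demographic templates per group role (healthy / AD-like / bvFTD-like),
# matched to the motivating cohort's demographics table
demo_template <- function(group_name) {
  tab <- list(
    HC = list(age = c(63.20, 5.00), edu = c(13.47, 3.57), p_female = 25 / 47,
              scores = rbind(episodic = c(0.34, 0.61), executive = c(0.74, 0.34),
                             attention = c(0.38, 0.96), language = c(0.53, 0.62),
                             visuospatial = c(0.75, 0.79)),
              npi = c(0.45, 1.34)),
    AD = list(age = c(65.45, 5.87), edu = c(9.04, 3.84), p_female = 27 / 50,
              scores = rbind(episodic = c(-3.80, 1.51), executive = c(-1.48, 1.87),
                             attention = c(-0.28, 1.03), language = c(-0.78, 1.46),
                             visuospatial = c(-0.83, 0.98)),
              npi = c(2.76, 2.80)),
    bvFTD = list(age = c(62.05, 5.47), edu = c(8.79, 2.30), p_female = 11 / 14,
                 scores = rbind(episodic = c(-2.54, 1.58), executive = c(-2.10, 2.23),
                                attention = c(-0.63, 1.06), language = c(-1.65, 1.51),
                                visuospatial = c(-1.14, 0.89)),
                 npi = c(9.10, 7.90))
  )
  tab[[group_name]] %||% tab$HC
}

#' Generate per-frame motion summaries
#'
#' Draws a framewise-displacement (mm) and DVARS (percent signal change)
#' trace with quiet baseline frames strictly below the conventional 0.5
#' censoring thresholds and occasional motion spikes exceeding both.
#'
#' @param n_frames number of frames (>= 1).
#' @param spike_prob per-frame spike probability in [0, 1].
#' @param spike_scale spike magnitude scale in mm (must be non-negative).
#' @param seed integer seed.
#' @return list with numeric vectors `fd` and `dvars` of length `n_frames`.
#' @export
generate_motion_trace <- function(n_frames, spike_prob = 0.05,
                                  spike_scale = 0.5, seed = 1L) {
  if (n_frames < 1) stop_fctopo("n_frames must be >= 1")
  if (spike_prob < 0 || spike_prob > 1)
    stop_fctopo("spike_prob must lie in [0, 1]")
  if (spike_scale < 0)
    stop_fctopo("configuration error: spike_scale must be non-negative")
  set.seed(seed)
  fd <- stats::runif(n_frames, 0.03, 0.30)
  dvars <- stats::runif(n_frames, 0.05, 0.35)
  spikes <- which(stats::runif(n_frames) < spike_prob)
  if (length(spikes)) {
    amp <- max(spike_scale, 1e-3)
    fd[spikes] <- 0.5 + amp * stats::runif(length(spikes), 0.05, 1)
    dvars[spikes] <- 0.5 + amp * stats::runif(length(spikes), 0.05, 1)
  }
  list(fd = fd, dvars = dvars)
}

#' Generate a synthetic cohort of ROI time series
#'
#' Simulates every subject of the configured cohort from the latent factor
#' model described in [group_spec()], attaches motion traces, and assembles
#' a cohort table with demographics, cognitive domain z-scores, NPI totals,
#' and a behavior score coupled to a known connectivity metric. Identical
#' seeds yield bit-identical output.
#'
#' @param config a [simulation_config()].
#' @return list with `timeseries` (list of `subject_ts` objects: `subject_id`,
#'   `data` frames x nodes, `tr_seconds`, `fd`, `dvars`), `cohort`
#'   (data.frame), `partition` (planted module labels), `atlas`, and
#'   `gm_volume` (subjects x nodes matrix or NULL).
#' @examples
#' cfg <- simulation_config(n_nodes = 30, n_frames = 60,
#'   group_specs = list(HC = group_spec(3), AD = group_spec(3)), seed = 7)
#' cohort <- generate_cohort(cfg)
#' table(cohort$cohort$group)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  part <- config$planted_partition
  groups <- names(config$group_specs)
  n_total <- sum(vapply(config$group_specs, `[[`, 1L, "n_subjects"))
  seeds <- derive_seeds(config$seed, 3L * n_total + 1L)
  ts_list <- vector("list", n_total)
  rows <- vector("list", n_total)
  gm <- if (config$simulate_gm)
    matrix(NA_real_, n_total, config$n_nodes) else NULL
  idx <- 0L
  for (gname in groups) {
    spec <- config$group_specs[[gname]]
    tmpl <- demo_template(gname)
    for (s in seq_len(spec$n_subjects)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%03d", gname, s)
      set.seed(seeds[idx])
      X <- simulate_subject_data(spec, part, config$n_frames, config$noise_sd)
      colnames(X) <- config$atlas$label
      mt <- generate_motion_trace(config$n_frames,
                                  config$motion$spike_prob,
                                  config$motion$spike_scale,
                                  seed = seeds[n_total + idx])
      ts <- structure(list(subject_id = sid, data = X,
                           tr_seconds = config$tr_seconds,
                           fd = mt$fd, dvars = mt$dvars),
                      class = "subject_ts")
      ts_list[[idx]] <- ts
      set.seed(seeds[2L * n_total + idx])
      # behavior target: realized FC summary of this subject's data
      cm <- stats::cor(X)
      target <- switch(config$behavior_coupling$target_metric %||% "mean_fc",
        mean_fc = mean(pmax(cm[upper.tri(cm)], 0)),
        lesioned_fc = {
          les <- if (length(spec$lesioned_modules))
            which(part %in% spec$lesioned_modules) else seq_len(config$n_nodes)
          sub <- cm[les, les]
          mean(pmax(sub[upper.tri(sub)], 0))
        },
        stop_fctopo("unknown behavior target metric '%s'",
                    config$behavior_coupling$target_metric))
      coupled <- config$behavior_coupling$slope * target +
        stats::rnorm(1, 0, config$behavior_coupling$noise_sd)
      dom <- stats::rnorm(5, tmpl$scores[, 1], tmpl$scores[, 2])
      frames_kept <- sum(!(mt$fd > 0.5 | mt$dvars > 0.5))
      rows[[idx]] <- data.frame(
        subject_id = sid, group = gname,
        age = stats::rnorm(1, tmpl$age[1], tmpl$age[2]),
        gender = if (stats::runif(1) < tmpl$p_female) "F" else "M",
        education = max(0, stats::rnorm(1, tmpl$edu[1], tmpl$edu[2])),
        scanner = if (stats::runif(1) < 39 / 111) "TimTrio" else "Prisma",
        frames_retained = frames_kept,
        episodic = dom[1], executive = dom[2], attention = dom[3],
        language = dom[4], visuospatial = dom[5],
        npi_total = max(0, stats::rnorm(1, tmpl$npi[1], tmpl$npi[2])),
        coupled_score = coupled,
        integrated_fc = NA_real_,
        stringsAsFactors = FALSE)
      if (!is.null(gm)) {
        lesioned_nodes <- part %in% spec$lesioned_modules
        gm[idx, ] <- stats::rnorm(config$n_nodes,
                                  mean = 6 - 0.8 * lesioned_nodes, sd = 0.5)
      }
    }
  }
  cohort <- do.call(rbind, rows)
  cohort$group <- factor(cohort$group, levels = groups)
  if (!is.null(gm)) rownames(gm) <- cohort$subject_id
  list(timeseries = ts_list, cohort = cohort, partition = part,
       atlas = config$atlas, gm_volume = gm)
}
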