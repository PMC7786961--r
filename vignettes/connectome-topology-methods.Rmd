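---
title: "Methods: whole-brain connectome topology across dementia syndromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-brain connectome topology across dementia syndromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fctopo)
```

## What the pipeline computes

`fctopo` implements a whole-brain functional-connectome topology analysis for
contrasting dementia syndromes (Alzheimer's disease, behavioral-variant
frontotemporal dementia) against healthy controls. Starting from per-subject
ROI-mean BOLD time series, it runs:

1. **Motion scrubbing** — frames with framewise displacement > 0.5 mm or
   DVARS > 0.5% are censored (strict inequality), and subjects keep their
   place in the cohort only if at least 4 minutes of data survive.
2. **Connectome construction** — Pearson correlation between all ROI pairs;
   the diagonal and all negative correlations are zeroed, giving a symmetric
   nonnegative weighted matrix. No Fisher transform is applied: raw r values
   are thresholded directly.
3. **Cost thresholding** — at cost `c`, the `floor(c * N(N-1)/2)`
   largest-weight edges are retained with their original weights. Ties break
   by ascending node-index order, which makes edge sets nested across costs
   and the whole pipeline deterministic. Validity of a cost range is
   assessed by three criteria per subject: small-worldness > 1,
   largest-component coverage of at least 80% of nodes, and mean degree
   above log(N) (natural log).
4. **Integration metrics** — weighted degree centrality `D_i = sum_j w_ij`
   and nodal efficiency `E_i = mean_j 1/L_ij` with edge lengths `1/w`
   (unreachable pairs contribute 0), evaluated on the coarse grid
   0.09–0.40 in 0.01 steps and integrated over cost by the trapezoidal
   rule into one composite per node.
5. **Two-stage consensus communities** — per subject, seeded Louvain
   partitions at every cost of the fine grid (0.09–0.40 in 0.001 steps,
   311 thresholds), a co-classification matrix over those partitions, and
   iterative consensus clustering of that matrix; per group, an allegiance
   matrix over the subjects' consensus partitions and a second consensus.
   Resolutions default to gamma = 3 (subject stage) and gamma = 2 (group
   stage) and apply to every clustering, including re-clusterings of
   co-classification and allegiance matrices.
6. **Module distinctiveness** — within-module degree z-scores and
   participation coefficients against a fixed group-level partition, with
   binary intra-module degrees, integrated over the coarse grid.
7. **Partition similarity** — the adjusted Rand index, whole-brain and
   restricted to communities of interest (combined default + control
   "DN-CN", salience/ventral attention "SVAN", subcortical), with 20
   subgroups of 10 subjects resampled with replacement per group and each
   subgroup's partition compared against the all-control reference.
8. **Statistics** — per-node OLS contrasts of group on each metric with
   education, scanner and retained-frame covariates (p <= .05 uncorrected,
   with an FDR column for convenience); one-way ANOVA plus Bonferroni-
   corrected pooled-variance post hoc t-tests on the ARI distributions; and
   Pearson correlations between metrics and behavior scores after
   residualizing both on age, gender, education and scanner.

## The synthetic cohort

No public dataset accompanies this design, so the package ships a generator
whose defaults encode the study conditions: 47 controls, 50 AD-like and 14
bvFTD-like subjects; 235 frames at TR 2 s (an 8-minute acquisition minus
five dropped volumes); a 141-node atlas (111 cortical nodes over 13
fine-grained network modules, 30 subcortical nodes in striatal, thalamic and
medial-temporal blocks).

Node signals follow a latent factor model: each module has a latent time
course, all nodes share a weak global signal, and

```
x_node = a * z_module + b * s_merge + c * g_global + noise
```

with loadings chosen so intact-module node pairs correlate at
`rho_within = 0.9`, between-module pairs at `rho_between = 0.05`, and unit
marginal variance at the default noise level. Lesions subtract
`lesion_delta = 0.45` from a module's internal coherence (fragmentation);
merge pairs give two modules one shared latent at coupling
`merge_rho = 0.45` (loss of distinctiveness). The AD-like group merges and
weakens the default and control modules; the bvFTD-like group fragments the
salience and subcortical modules and couples salience to striatum. Motion
traces have quiet baselines strictly under the censoring thresholds plus
Bernoulli spikes exceeding both; demographics, domain z-scores and NPI
totals are drawn from group-specific normal distributions matching a
realistic memory-clinic cohort.

A behavior column (`coupled_score`) equals `slope x (subject's mean positive
FC) + noise` with slope 50 and noise SD 0.5. The slope looks large because
the between-subject spread of mean FC is only about 0.02 at these sizes;
these values plant a strong but noisy association (r around 0.85 in the
demo cohort) so correlation recovery has a known ground truth.

What the generator does **not** emulate: hemodynamics, spatial smoothness,
scanner drift and physiological noise, realistic score distributions or
missingness, and any coupling between motion and signal. Passing tests
therefore demonstrate that the algorithms recover structure *their model
plants*, not that the pipeline is robust to every artifact of real fMRI.

## Numerical and design choices

* **Edge count** uses `floor`, never `round`, so a cost never overshoots
  its nominal edge fraction; with the deterministic tie rule, thresholded
  edge sets are nested in cost. A matrix whose positive-edge supply runs
  out is kept with all positive edges and flagged. Note one degenerate
  corner: a matrix with *exactly tied* block weights (all within-block
  entries equal) interacts with the lexicographic tie rule so that low
  costs retain only the lexicographically first block; empirical FC
  matrices carry no exact ties, and the consensus tests use empirically
  realized block structure.
* **Small-worldness** is computed on the binarized graph with
  degree-preserving rewired nulls (20 by default, seeded); the
  characteristic path length uses the largest connected component. A null
  ensemble without triangles flags the result rather than dividing by zero.
* **Efficiency** uses edge length `1/w`, the standard choice for weighted
  brain graphs; disconnected pairs contribute zero rather than being
  dropped.
* **Consensus clustering** zeroes co-classification entries below
  `tau = 0.5`, re-clusters 10 times per iteration, and stops when all runs
  agree (cap 20 iterations, flagged on non-convergence). tau and the run
  count are configurable because the literature this scheme follows states
  them loosely; gamma applies at every stage.
* **Louvain** is greedy and order-dependent, so every call takes a seed and
  the best of 10 restarts by modularity at the requested resolution is
  returned; ties go to the earliest restart, making results reproducible
  bit for bit.
* **Module metrics** use binary intra-module degree (a weighted variant sits
  behind a flag); each group is scored against its own group-level
  partition by default, with a shared-reference mode for sensitivity
  analyses.
* **Restricted-ARI scopes** come from the atlas's community-of-interest
  column, the deterministic realization of mapping the reference partition
  onto the labeled networks.
* **ARI degeneracy**: when both partitions are trivial (all-singletons or
  one community) the index is defined as 1; one-community versus
  all-singletons yields 0 by the standard formula.
* **Post hoc t-tests** on ARI distributions use pooled variance. Synthetic
  lesions can separate groups perfectly, leaving zero variance in a pair:
  identical constant groups get p = 1, different constant groups p = 0, and
  a scope where *every* group is constant raises a degenerate-input error.
* **Residualized correlations** report the plain Pearson r of the
  covariate residuals but compute the p-value on n - 2 - k degrees of
  freedom (k = covariate design columns), the partial-correlation test;
  the naive residual test is anticonservative at these sample sizes.
* **Cost-integrated composites** store the raw trapezoidal AUC; divide by
  the grid width (0.31 for the default range) to rescale to a mean level.

## Problem sizes

The bundled analysis drivers and tests run scaled-down configurations chosen
to keep a full rerun in the minutes range on one CPU: the demo cohort uses
15/15/10 subjects with fine-grid step 0.005; planted-partition recovery runs
141 nodes x 20 subjects x 3 seeds at step 0.01; lesion-direction recovery
runs ten 30-node replicates at step 0.05 with 10 subgroups of 6; the
statistical calibrations use 200 replicate cohorts (five independent null
nodes each for the GLM, four scopes each for the ANOVA). Every size is a
parameter, and the full-scale settings (311 thresholds, 20 x 10 resampling,
47/50/14 subjects) are the package defaults.

## Known limitations

Louvain with restarts is still a heuristic: on weak or fragmented structure
(e.g. the AD-like merged blob) subject partitions are unstable and the
consensus can retain many singleton communities — which is precisely the
fragmentation phenotype the similarity statistics quantify, but it means
absolute community counts should not be over-interpreted. The generator's
block-correlation world contains no hubs, no distance effects and no
negative-correlation structure, so participation coefficients are milder
than in real connectomes. DVARS is consumed as given, never recomputed from
voxel data, and censoring happens after (not before) any temporal filtering
applied upstream.
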