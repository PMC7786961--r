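# Shared settings for the numbered analysis drivers.
#
# The demo cohort is scaled down from the full study conditions (47/50/14
# subjects, fine grid step 0.001) to 15/15/10 subjects and step 0.005 so the
# whole workflow reruns in a few minutes; all group-specific lesion settings
# are the package defaults. Edit here to scale up.

library(fctopo)

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

DEMO_SEED <- 20260922L
N_NODES <- 141
ATLAS <- make_atlas(N_NODES)
GROUP_SIZES <- c(HC = 15, AD = 15, bvFTD = 10)
COARSE_GRID <- cost_grid(0.09, 0.40, 0.01)   # nodal metrics
FINE_GRID <- cost_grid(0.09, 0.40, 0.005)    # community detection (demo)
GAMMA_SUBJECT <- 3
GAMMA_GROUP <- 2

demo_config <- function() {
  simulation_config(
    n_nodes = N_NODES, atlas = ATLAS,
    group_specs = default_group_specs(ATLAS,
                                      n_hc = GROUP_SIZES[["HC"]],
                                      n_ad = GROUP_SIZES[["AD"]],
                                      n_bvftd = GROUP_SIZES[["bvFTD"]]),
    n_frames = 235, tr_seconds = 2, seed = DEMO_SEED)
}

res_path <- function(...) file.path(RESULTS_DIR, ...)
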