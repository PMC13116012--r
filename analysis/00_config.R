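# Shared configuration for the analysis workflow (sourced by 01-05).
#
# Desk-scale emulation of the word-reading study: an eight-subject cohort
# with four left-hemisphere regions, 34 word-aligned trials per subject, and
# known planted structure so every downstream stage has ground truth to
# find: an early category effect in dlPFC (BA 9), a late category effect in
# SMG (BA 40), and a trial-wise coupling from the dlPFC effect window to
# the SMG effect window.

library(prespeech)

GLOBAL_SEED <- 20260924L
RESULTS_DIR <- "results"
DATA_DIR <- file.path(RESULTS_DIR, "data")
ENV_DIR <- file.path(RESULTS_DIR, "envelope")

study_synth_config <- function() {
  synth_config(
    n_subjects = 8,
    areas = data.frame(brodmann_area = c("9", "20", "40", "37"),
                       hemisphere = "L", stringsAsFactors = FALSE),
    channels_per_area = 6,
    epoch_ms = c(-400, 700),      # covers baseline (-300..0) and 0..550 ms
    ied_rate = 0.02,
    effects = list(
      planted_effect("9", "L", c(100, 200), 1.5),
      planted_effect("40", "L", c(350, 450), 1.5)),
    couplings = list(
      planted_coupling("9", "L", 3, "40", "L", 6, 0.35)),
    seed = prespeech:::stage_seed(GLOBAL_SEED, "synth"))
}

study_stats_config <- function() {
  # reduced desk-scale permutation counts (full analysis: 2000 / 1000)
  stats_config(n_label_perms = 500, n_time_perms = 200,
               seed = prespeech:::stage_seed(GLOBAL_SEED, "stats"))
}

study_cluster_config <- function() {
  cluster_config(n_perms = 500,
                 seed = prespeech:::stage_seed(GLOBAL_SEED, "coupling"))
}

study_selection_config <- function() {
  selection_config(seed = prespeech:::stage_seed(GLOBAL_SEED, "split"))
}

# Features + channel selection recomputed from the envelope container; all
# stages after 02 start from here.
load_features_and_selection <- function() {
  env <- read_dataset(ENV_DIR)
  feats <- window_features(env)
  scfg <- study_selection_config()
  sp <- split_trials(env$trials, scfg)
  sel <- select_channels(feats, sp$selection_ids, scfg)
  list(env = env, feats = feats, split = sp, selection = sel)
}
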