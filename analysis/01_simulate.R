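#!/usr/bin/env Rscript
# Stage 1: simulate the cohort.
#
# Generates the synthetic six-subject dataset with planted ground truth
# (early dlPFC effect, late SMG effect, dlPFC->SMG coupling) and writes the
# dataset container plus the channel metadata TSV.

source("analysis/00_config.R")

cfg <- study_synth_config()
ds <- generate_dataset(cfg)
write_dataset(ds, DATA_DIR)

cat(sprintf("subjects: %d, channels: %d, trials/subject: %d, samples: %d @ %g Hz\n",
            length(unique(ds$channels$subject_id)), nrow(ds$channels),
            sum(ds$trials$subject_id == ds$trials$subject_id[1]),
            dim(ds$signals)[3], ds$sample_rate))
cat(sprintf("category split: %d body / %d nonbody words\n",
            sum(ds$trials$category == "body") / length(unique(ds$trials$subject_id)),
            sum(ds$trials$category == "nonbody") / length(unique(ds$trials$subject_id))))
cat(sprintf("speech onsets: mean %.0f ms, min %.0f ms\n",
            mean(ds$trials$speech_onset_ms), min(ds$trials$speech_onset_ms)))
cat("planted truth:", length(ds$truth$effects), "effects,",
    length(ds$truth$couplings), "couplings\n")
cat("container written to", DATA_DIR, "\n")
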