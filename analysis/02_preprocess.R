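#!/usr/bin/env Rscript
# Stage 2: preprocess the raw signals.
#
# Common average reference (within subject) -> notch at 60/120/180 Hz ->
# impedance-based channel exclusion -> interictal-discharge trial rejection
# -> 70-170 Hz envelope -> baseline z-scoring against -300..0 ms. Writes
# the envelope container.

source("analysis/00_config.R")

ds <- read_dataset(DATA_DIR)
env <- preprocess(ds, preprocess_config())
write_dataset(env, ENV_DIR)

cat(sprintf("channels: %d kept, %d excluded (impedance > 10 kOhm or bad)\n",
            nrow(env$channels), length(env$excluded_channels)))
cat(sprintf("trials rejected for discharges: %d of %d\n",
            sum(env$trials$rejected), nrow(env$trials)))
rng <- range(env$envelope)
cat(sprintf("envelope z-range: [%.2f, %.2f]\n", rng[1], rng[2]))
cat("envelope container written to", ENV_DIR, "\n")
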