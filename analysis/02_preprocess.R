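#!/usr/bin/env Rscript
# Trim the first 5 s of every trial, standardise to 40 s (2,000 samples at
# 50 Hz), centre, and low-pass filter (zero-phase Butterworth, 10 Hz).

library(dyadsync)

ex <- readRDS("results/experiment.rds")
pre <- lapply(ex$trials, preprocess_dyad, discard = 5, keep = 40, cutoff = 10)
saveRDS(pre, "results/preprocessed.rds")
write_motion_csv(pre, "results/motion_preprocessed.csv",
                 stage = "preprocessed")

n <- length(pre[[1]]$participant_arm$samples)
cat(sprintf("Preprocessed %d trials: %d samples per channel (40 s at 50 Hz),\n",
            length(pre), n))
cat("zero-phase Butterworth low-pass at 10 Hz, channels centred.\n")
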