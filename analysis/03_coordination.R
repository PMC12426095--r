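#!/usr/bin/env Rscript
# Coordination estimation. Arms: Hilbert relative phase between the
# participant and avatar arm channels, folded to [0, 180] degrees, rho =
# mean resultant length (doubled-angle convention), Fisher-transformed.
# Heads: cross-recurrence at radius 12 with embedding parameters estimated
# from the avatar head series (AMI first minimum; FNN first minimum), pooled
# across trials.

library(dyadsync)

pre <- readRDS("results/preprocessed.rds")

phase_results <- lapply(pre, phase_coordination, mode = "doubled")

est <- estimate_embedding(lapply(pre, function(tr) tr$avatar_head), rate = 50)
cat(sprintf("Embedding from avatar head series: delay %d samples, dimension %d%s\n",
            est$delay, est$dimension,
            if (est$delay_no_minimum || est$dimension_no_minimum)
              " (no clear minimum: flagged)" else ""))

crqa_results <- lapply(pre, crqa_trial, delay = est$delay,
                       dimension = est$dimension, radius = 12)

saveRDS(list(phase = phase_results, crqa = crqa_results,
             embedding = est[c("delay", "dimension")]),
        "results/coordination.rds")

rho <- vapply(phase_results, `[[`, numeric(1), "rho")
rec <- vapply(crqa_results, `[[`, numeric(1), "percent_recurrence")
cat(sprintf("Arm rho: mean %.3f (range %.3f-%.3f)\n",
            mean(rho), min(rho), max(rho)))
cat(sprintf("Head %%REC: mean %.2f%% (range %.2f-%.2f)\n",
            mean(rec), min(rec), max(rec)))
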