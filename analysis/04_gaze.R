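#!/usr/bin/env Rscript
# Gaze reduction: align each stream with the 40-s motion analysis window and
# summarise percent dwell time on the three areas of interest.

library(dyadsync)

ex <- readRDS("results/experiment.rds")
summaries <- lapply(ex$gaze, function(g) summarize_gaze(trim_gaze(g)))
saveRDS(summaries, "results/gaze_summaries.rds")

pa <- vapply(summaries, `[[`, numeric(1), "pct_avatar")
pn <- vapply(summaries, `[[`, numeric(1), "pct_near")
pr <- vapply(summaries, `[[`, numeric(1), "pct_room")
usable <- vapply(summaries, `[[`, logical(1), "usable")
cat(sprintf("Gaze dwell means: avatar %.1f%%, near %.1f%%, room %.1f%% (%d/%d usable)\n",
            mean(pa), mean(pn), mean(pr), sum(usable), length(usable)))
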