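#!/usr/bin/env Rscript
# Generate the synthetic 2x2 experiment: 20 participants per avatar-gaze
# group, two 45-s trials each (self- vs other-focus, counterbalanced order),
# arm channels from coupled phase oscillators, head channels from
# band-limited sway with condition-dependent coupling, and AOI gaze streams.
# Writes the raw data dialects under results/.

library(dyadsync)

seed <- 20260927L
design <- experiment_design(n_per_group = 20, seed = seed)
ex <- generate_experiment(design)

dir.create("results", showWarnings = FALSE)
write_design_csv(ex$design_table, "results/design.csv")
write_motion_csv(ex$trials, "results/motion_raw.csv")
write_gaze_csv(ex$gaze, "results/gaze.csv")
saveRDS(ex, "results/experiment.rds")   # convenience cache for later stages

cat(sprintf("Simulated %d participants, %d trials at %g Hz, %g s each.\n",
            length(unique(ex$design_table$participant_id)),
            nrow(ex$design_table), design$sampling_rate,
            design$trial_duration))
cat("Arm coupling by cell:",
    paste(names(design$arm_coupling), design$arm_coupling, sep = "=",
          collapse = ", "), "\n")
cat("Head coupling by cell:",
    paste(names(design$head_coupling), design$head_coupling, sep = "=",
          collapse = ", "), "\n")
cat("Wrote results/design.csv, results/motion_raw.csv, results/gaze.csv\n")
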