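#!/usr/bin/env Rscript

# Stage 1: simulate the synthetic two-group resting-state cohort.
#
# The cohort emulates the study conditions the downstream analyses assume:
# two groups, 240 volumes at TR = 2 s, six recurring brain states, a higher
# state switching rate in patients (0.08 vs 0.06 transitions per step),
# patient occupancy shifts (state 1 up, states 3 and 6 down) and planted
# amplitude/coherence deficits in the first fifth of parcels. Here it runs at
# desk scale (20/20 subjects, 20 parcels) so the full workflow reruns in
# minutes; the "paper" preset in pipeline_config() pins the full sizes.

suppressPackageStartupMessages(library(flexstates))

seed <- 42L
cfg <- sim_config(n_patients = 20L, n_controls = 20L, n_parcels = 20L,
                  n_volumes = 240L, tr_seconds = 2, n_states = 6L,
                  seed = seed)
cohort <- simulate_cohort(cfg)

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort")
saveRDS(cohort, "results/cohort.rds")

sr <- cohort$truth$sr
pat <- cohort$manifest$group == "patient"
cat(sprintf("simulated %d patients + %d controls, %d parcels, %d volumes\n",
            cfg$n_patients, cfg$n_controls, cfg$n_parcels, cfg$n_volumes))
cat(sprintf("true switching rate: patients %.3f, controls %.3f\n",
            mean(sr[pat]), mean(sr[!pat])))
cat("cohort written to results/cohort/ (TSV + JSON) and results/cohort.rds\n")
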