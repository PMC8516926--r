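#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic resting-state cohort.
#
# Twelve subjects at the study conditions: TR = 0.586 s, 400 cortical
# parcels, 1000 time points (~10 min), phasic bursts at 0.25/min per type
# with amplitude 3 s.d., an anterior-to-posterior travelling wave at
# 0.13 m/s, and post-event displacement-variance scaling (x2 after LC-type
# events, x0.5 after BNM-type events).  The cohort and its ground truth are
# written under scratch/ for the later stages.

library(arousalwaves)

cfg <- sim_config(n_subjects = 12, n_time = 1000, n_parcels = 400, seed = 20260921L)
g <- generate_cohort(cfg, out_dir = "scratch/cohort")

te <- truth_events(g$truth)
message("cohort written to scratch/cohort (manifest: ", g$manifest, ")")
message("ground-truth events by type:")
print(table(te$type))
message("events per subject and type: ",
        round(nrow(te) / 3 / cfg$n_subjects, 2))
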