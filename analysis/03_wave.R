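#!/usr/bin/env Rscript
# Stage 3 — event-locked travelling wave.
#
# Cross-correlates tau_LC-BNM with each parcel over the 21-TR windows
# around detected LC-relative bursts (lags 0-10 TR), extracts per-parcel
# time-to-peak, and estimates the propagation velocity from a robust
# regression of latency on the anterior-posterior MNI coordinate.

library(arousalwaves)

cohort <- load_cohort("scratch/cohort/manifest.yaml")
sig <- condition_cohort(cohort)
ev <- read_events("results/events")

wf <- wave_analysis(cohort, sig, ev, type = "LC-BNM")
write_results(wf, "results/wave")
print(wf)
message(sprintf("latency range %.2f-%.2f s across the cortex",
                min(wf$time_to_peak_s), max(wf$time_to_peak_s)))
message("per-parcel latencies written to results/wave/wave_fit.tsv")
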