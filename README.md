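# arousalwaves

Phasic bursts in the subcortical arousal system — the noradrenergic locus
coeruleus (LC) and the cholinergic basal nucleus of Meynert (BNM) — have
been proposed to reshape whole-cortex BOLD dynamics in opposite ways: LC
bursts integrating cortical networks and *flattening* the brain-state
energy landscape, BNM bursts segregating networks and *deepening* it.
`arousalwaves` is an R implementation of the full analysis pipeline behind
that question, for researchers working with parcellated resting-state
fMRI and subcortical ROI time series. It ships a synthetic-cohort
generator with exact ground truth, so every estimator in the chain is
verifiable end-to-end without any data download.

## The models at the core

* **Phasic burst detection.** On the conditioned contrast
  τ<sub>LC−BNM</sub> = z(τ<sub>LC</sub>) − z(τ<sub>BNM</sub>) (nuisance
  residualisation → 0.01–0.15 Hz zero-phase band-pass → z-score), an
  event is a time point whose second derivative is ≥ 2 s.d. above its
  mean, with the series itself rising ≥ 2 s.d. above its mean within the
  following 10 TRs, at least 20 TRs from the run edges.
* **Travelling wave.** Per-parcel time-to-peak of the event-locked
  cross-correlation between the contrast and each parcel (lags 0–10 TR,
  sub-TR refinement), then a robust (Theil–Sen) regression of latency on
  the anterior–posterior coordinate; velocity = 1/|slope|.
* **Time-resolved topology.** Multiplication of temporal derivatives
  (w = 20 TR) → signed modularity
  Q = (1/v⁺)Σ(w⁺ − γe⁺)δ − (1/(v⁺+v⁻))Σ(w⁻ − γe⁻)δ with Louvain
  restarts and consensus clustering → participation coefficient
  PC<sub>i</sub> = 1 − Σ<sub>s</sub>(κ<sub>is</sub>/κ<sub>i</sub>)² on
  positive weights as the integration measure.
* **Energy landscape.** MSD<sub>t,t₀</sub> = ⟨|x<sub>t₀+t</sub> −
  x<sub>t₀</sub>|²⟩<sub>parcels</sub> from each burst onset, a per-lag
  Gaussian KDE (bandwidth 4, MSD grid 0–50, lags 1–15 TR), and
  E = ln(1/P) with T = Z = 1. Landscape contrasts against
  block-resampled baselines, and a non-negative decomposition
  E<sub>LC+BNM</sub> ≈ αE<sub>LC</sub> + βE<sub>BNM</sub>.
* **Inference.** Block-resampled nulls (random non-event time points that
  preserve autocorrelation), percentile CIs, one-sided permutation tests,
  and FIR event-locked responses (±5 TR) for button-press designs.

## A worked example

```r
library(arousalwaves)

cfg <- sim_config(n_subjects = 4, n_parcels = 100, n_time = 800, seed = 7)
g <- generate_cohort(cfg)
print(g$cohort)
#> cohort_store: 4 subjects, 100 parcels, 800 time points, TR = 0.586 s

sig    <- condition_cohort(g$cohort)
events <- detect_cohort_events(sig)
print(events)
#> phasic_events: 21 events across 4 subjects (thresholds 2/2 s.d.)
#> BNM-LC LC-BNM LC+BNM
#>      7      6      8

wave <- wave_analysis(g$cohort, sig, events)
print(wave)
#> wave_fit: velocity 0.137 m/s, direction anterior->posterior, R^2 = 0.72

nulls      <- sample_null_timepoints(events, n = 500, max_lag = 15, seed = 2)
landscapes <- build_landscapes(g$cohort, events, nulls)
contrast   <- landscape_contrast(landscapes$E_LC, landscapes$E_A,
                                 flagged = "common_floor")
mean(contrast$delta_e[contrast$msd_grid >= 20], na.rm = TRUE)
#> -1.00
```

The generator planted a 0.13 m/s anterior-to-posterior wave and the fit
recovers 0.137 m/s from the detected bursts. The detected event counts
(~1.5–2 per subject and type over ~8 minutes) reflect the configured burst
rate. The negative landscape contrast (−1.00 over MSD 20–50, lags
10–15 TR) is the flattening signature: large displacements are about
e<sup>1</sup> ≈ 2.7 times more probable after an LC-relative burst than at
baseline in this simulation, because the generator doubles post-event
displacement variance after LC events. `landscape_contrast(landscapes$E_BNM,
landscapes$E_A, ...)` gives the opposite (deepening) sign.

## The analysis workflow

The `analysis/` directory holds the numbered drivers of the full study
workflow, each a thin narrative script over the package functions:

| script | stage |
| --- | --- |
| `01_simulate.R` | generate the 12-subject synthetic cohort (writes `scratch/cohort/`) |
| `02_condition_detect.R` | conditioning, burst detection, threshold sweep |
| `03_wave.R` | event-locked latencies and wave velocity |
| `04_network.R` | MTD, consensus modularity, PC, lagged τ–PC coupling, γ sweep |
| `05_landscape.R` | energy landscapes, contrasts, joint decomposition |
| `06_meditation.R` | FIR event-locked analysis of a button-press design (TR 1.5 s) |

Run them in order with `Rscript analysis/01_simulate.R` etc.; tables land
under `results/`.

## Package layout

* `R/` — generator, conditioning, detection, wave, network, landscape,
  null-model and event-locked modules.
* `tests/testthat/` — unit, property and acceptance suites; all expected
  values come from closed forms or brute-force oracles.
* `vignettes/arousal-energy-landscape.Rmd` — the methods vignette: models,
  parameter choices, generator design and limitations.
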