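---
title: "Phasic arousal, travelling waves and the BOLD energy landscape: methods"
author: "arousalwaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasic arousal, travelling waves and the BOLD energy landscape: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

The ascending arousal system modulates cortical computation through two
complementary neuromodulatory hubs: the noradrenergic locus coeruleus (LC),
whose diffuse projections are thought to increase multiplicative gain and
*integrate* cortical networks, and the cholinergic basal nucleus of Meynert
(BNM), whose targeted projections are thought to sharpen response gain and
*segregate* them. `arousalwaves` implements an analysis pipeline that asks,
on parcellated resting-state BOLD data, whether phasic bursts of LC or BNM
activity are followed by (i) a cortical travelling wave, (ii) a transient
rise in network integration, and (iii) a reshaping of a low-dimensional
"energy landscape" of brain-state displacement — a flattening after LC
bursts (unlikely state transitions become easier) and a deepening after
BNM bursts (the current state becomes stickier).

Every stage can be exercised without any data download because the package
ships a synthetic-cohort generator whose ground truth (burst times, wave
velocity, module structure, integration windows, displacement-variance
shifts) is known exactly.

# Pipeline stages and their models

## Signal conditioning

Subcortical ROI series are residualised by ordinary least squares against
nuisance channels (a fourth-ventricle series and a pontine control),
band-pass filtered to 0.01–0.15 Hz with a 4th-order Butterworth filter
applied forward and backward (zero phase, so event timing is preserved for
all lag analyses), and z-scored. The conditioned LC and BNM series
$\tau_{LC}$ and $\tau_{BNM}$ are combined into the contrast
$\tau_{LC-BNM} = \tau_{LC} - \tau_{BNM}$ (with
$\tau_{BNM-LC} = -\tau_{LC-BNM}$ exactly) and the sum $\tau_{LC+BNM}$.
Z-scoring before differencing makes the contrast unit-free; the detection
thresholds below are in s.d. units, so detection is scale-invariant.
The filter is applied to a demeaned, reflection-padded copy of the series
so that filter transients do not leak into the run edges.

## Phasic burst detection

A time point $t_0$ is a phasic event when three criteria hold:

1. the second derivative (central difference, endpoints invalid) of the
   series is at least `accel_sd` (default 2) s.d. above its mean;
2. the series itself rises to at least `sustain_sd` (default 2) s.d. above
   its mean somewhere within the following `sustain_window` (default 10)
   TRs — an existence condition on the post-burst peak, since requiring
   every sample to exceed 2 s.d. would detect essentially nothing;
3. $t_0$ lies at least `boundary` (default 20) TRs from either run edge.

Within a run of consecutive qualifying samples only the acceleration
maximum is kept, so one burst yields one event. The three event types are
detected on $\tau_{LC-BNM}$, $\tau_{BNM-LC}$ and $\tau_{LC+BNM}$
respectively, each using that series' own mean and s.d. (the sum-signal
reading of the joint type; a coincidence-based definition would require an
arbitrary coincidence window, and the sum parallels how the contrasts are
defined).

Because the detector marks acceleration maxima of an HRF-shaped response,
a detection lags the underlying neural onset by the acceleration-peak
offset of the band-passed HRF kernel (2 TR at TR = 0.586 s). Recovery
scoring against ground truth therefore shifts true onsets by this
kernel-determined offset and matches within ±2 TR.

## Travelling wave

For each parcel the arousal contrast is cross-correlated with the parcel
series over the 21-TR analysis windows centred on each detected event,
at lags 0…10 TR. The time-to-peak is the lag maximising this pooled
correlation, refined to sub-TR resolution by parabolic interpolation of
the three correlation values around the peak; the correlation is evaluated
one lag beyond each edge of the range so that peaks at lag 0 can still be
interpolated. Without this guard, every parcel whose true latency is below
half a TR is floored at exactly zero, which compresses the latency range
and biases the velocity upward by ~15%.

Velocity comes from a Theil–Sen regression of latency (s) on the
anterior–posterior MNI coordinate (mm): the median pairwise slope is
robust to off-wave parcels, and the velocity is $1/|\mathrm{slope}|$
converted to m/s. The slope sign gives the propagation direction
(anterior→posterior positive). Fits with $|\mathrm{slope}|$ below
$10^{-4}$ s/mm (an apparent speed above 10 m/s) are flagged undefined
rather than reported. Euclidean regression along the y axis is the
implemented convention; geodesic distances are not used.

## Time-resolved connectivity and topology

Coupling uses multiplication of temporal derivatives (MTD): first
differences of each parcel series, normalised by each parcel's derivative
s.d. (without this normalisation the "identical series couple at 1"
property fails and coupling becomes scale-dependent), multiplied pairwise
and averaged in a sliding window of `w = 20` TR.

Community structure per window maximises signed modularity
$$Q = \frac{1}{v^+}\sum_{ij}\left(w^+_{ij} - \gamma e^+_{ij}\right)\delta_{M_iM_j}
 - \frac{1}{v^+ + v^-}\sum_{ij}\left(w^-_{ij} - \gamma e^-_{ij}\right)\delta_{M_iM_j},$$
with $e_{ij} = s_i s_j / v$ the strength-product null computed separately
on the positive and negative layers and $\gamma$ the resolution parameter
scaling both null terms (the conventional placement; the sweep over
$\gamma \in [0.5, 2.5]$ requires it). A Louvain heuristic is restarted
`runs` times with distinct sub-seeds; the co-assignment matrix across runs
is thresholded at 0.5 and reclustered until all runs agree, which is the
consensus partition. The implementation is verified against a brute-force
double-sum oracle on random signed graphs to $10^{-12}$.

Integration is quantified by the participation coefficient
$PC_i = 1 - \sum_s (\kappa_{is}/\kappa_i)^2$ on positive weights only;
nodes with zero positive strength get 0. Windowed PC is mapped to the TR
grid by nearest-window-centre assignment for the lag analyses; the null
band for the lagged $\tau$–PC correlation comes from circular rotations of
the contrast, which preserve its autocorrelation.

## The MSD energy landscape

Displacement from a reference point $t_0$ is
$\mathrm{MSD}_{t,t_0} = \langle |x_{t_0+t} - x_{t_0}|^2 \rangle_r$ (mean
over parcels), computed for lags 1…15 TR from every event of a condition,
pooled across subjects. The probability surface $P(\mathrm{MSD}, t)$ is a
per-lag Gaussian kernel density with bandwidth $h = 4$ MSD units on a
0–50 grid (step 0.5; the KDE at $h = 4$ changes by under $10^{-3}$ at step
0.25, so the grid is not a tuning knob), and the energy is
$E = \ln(1/P)$ with the statistical-physics convention $T = Z = 1$.
The kernel is a properly normalised Gaussian: the conventional
"kernel over 4" notation with $K(u) = e^{-u^2/2}/(2\sqrt{\pi})$ integrates
to $\sqrt{2}/2$, not 1; since $E$ is defined only up to the additive
constant absorbed by $Z$, normalising the kernel changes nothing
scientific and makes per-lag densities integrate to 1 (verified to
$10^{-6}$ by quadrature).

Cells with $P$ at or below a floor of $1/(100\,n\,h)$ are capped and
flagged. Contrasts between landscapes average $E_{\text{event}} -
E_{\text{baseline}}$ over lags 10–15 per MSD bin, excluding flagged cells;
a `common_floor` mode instead recomputes both energies from $P$ with one
shared floor so that deep-tail cells compare as ties — necessary for the
deepening contrast, where the event condition concentrates all its mass at
low MSD and would otherwise have no usable high-MSD cells. The baseline
condition uses block-resampled non-event time points (below). Subjects'
cortical matrices are z-scored per parcel and multiplied by a BOLD scale
of 3 before displacement is measured, placing baseline MSD at long lags in
the teens so that the 0–50 grid and $h = 4$ bandwidth resolve both the
baseline well and its doubling or halving.

The joint landscape is decomposed as
$E_{LC+BNM} \approx \alpha E_{LC} + \beta E_{BNM}$ by non-negative least
squares over all cells finite and unflagged in all three landscapes
(energies, not probabilities; an optional sum-to-one rescaling is provided
but not imposed during the fit).

## Null models

Null reference points are uniform draws over per-subject indices that
respect the boundary margin and lie at least 10 TR (half the 21-TR
analysis window — the minimal reading of "not substantially overlapping")
from every detected event; draws never cross subject boundaries, and
statistics are always evaluated on contiguous windows around the drawn
points, which preserves temporal autocorrelation. Null distributions
re-evaluate the statistic on pseudo-event sets of the observed size; the
95% band is the 2.5th–97.5th percentile. One-sided permutation tests use
add-one smoothing, $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(n+1)$.

## Event-locked (awareness) analysis

For button-press designs the pipeline fits a finite-impulse-response
model: OLS of each signal (arousal contrast, TR-to-TR MSD, mean PC) on
lagged press indicators over −5…+5 TR plus an intercept. For isolated
events the coefficients equal the event-locked average minus the off-event
baseline (asserted to $10^{-10}$ in tests). Per-subject responses are
averaged with between-subject SEM, and each lag is compared with a null
band from pseudo-press FIR fits. The TR for this pathway comes from the
cohort manifest (1.5 s in the emulated design), never hard-coded.

# The synthetic generator: what it emulates, and what it does not

Defaults are the study conditions: TR 0.586 s, 400 parcels on a lattice
spanning MNI extents (y spanning 140 mm, hemispheres split at x = 0),
1000 time points (~10 min), bursts at 0.25/min per event type (about 2.5
LC-relative events per run), burst amplitude 3 s.d., an
anterior→posterior wave at 0.13 m/s whose per-parcel onset delay is
distance along the propagation axis divided by velocity, four cortical
modules with within-module correlation 0.6 and between-module correlation
0.05 rising to 0.3 for the 10 TR following LC-type events, and post-event
displacement variance scaled by 2 (LC) or 0.5 (BNM) over the 15-lag
landscape window. Events are Poisson draws thinned to a minimum 21-TR
separation so analysis windows never overlap.

Three generator choices deserve explanation:

* **Noise spectrum.** In-band noise is synthesised in the frequency domain
  (exact band limits, no filter transients) with power $\propto 1/f^2$,
  mirroring the strong low-frequency dominance of resting BOLD. A flat
  in-band spectrum is unrealistic in a specific way that matters here: it
  puts so much power near 0.15 Hz that the second derivative of noise
  swamps the acceleration of an HRF-shaped burst, and no realistic burst
  amplitude is detectable by an acceleration criterion.
* **Channel correlation.** The LC and BNM noise floors share 70% of their
  variance (`channel_corr = 0.7`): the nuclei are densely interconnected
  and share global and vascular fluctuations. This also controls the
  noise variance of the contrast, $2(1-\rho)$; with independent channels a
  3 s.d. single-channel burst is only ~2.1 s.d. in the contrast and sits
  exactly at the detection threshold by construction.
* **Haemodynamic delays.** Injected bursts are scaled by the inverse of
  the band-pass peak attenuation, so "amplitude in s.d. units" refers to
  the conditioned series the detector actually sees; and the post-event
  integration (coupling) window is delayed by the HRF peak lag, because
  the generator's coupling shapes BOLD correlations directly and the BOLD
  expression of a neural gain change is haemodynamically delayed — this
  is what makes measured integration *follow* the arousal contrast.

The generator does **not** emulate: head motion or scrubbing artefacts,
spatially structured vascular confounds, inter-subject anatomical
variability, geodesic cortical geometry (the wave propagates along a
Euclidean axis over a lattice), hemispheric asymmetries of integration
(both hemispheres are statistically identical, so the hemispheric
permutation test has a true null on synthetic data), or any relation
between the joint-landscape $\alpha/\beta$ and empirical values (joint
events scale displacement variance by 1, so the decomposition on
generator output reflects the generator, not the deposited cohort).
Passing the simulation suite therefore shows that the estimators recover
what was planted under realistic noise, not that real data behave this
way.

# Problem sizes and verification strategy

The test suite's simulation checks use sizes chosen to separate estimator
error from sampling noise while remaining quick: the parameter-recovery
cohort is 12 subjects × 1000 TR × 400 parcels; wave-velocity recovery at
0.05/0.13/0.30 m/s uses the median over five cohorts seeded 1…5, because
a single 12-subject cohort carries ±8% sampling error at the slowest
velocity — comparable to the 10% recovery tolerance being verified;
detector sensitivity and precision are pooled over the same cohorts
(≈250 planted bursts). Directional landscape checks run 20 seeded
replicates of a 3-subject, 60-parcel cohort at 2 bursts/min (≈100 events
per condition and replicate) and require the planted sign in every
replicate. Null-model calibration covers 200 replicates of an 8-event
design with 999 resamples each, with planted events at least 21 TR apart
as real detections are; empirical 95% coverage must fall in [0.92, 0.98].
Windowed community detection in tests uses 50–200 Louvain restarts;
scientific runs on real-sized problems should use the conventional 500.

# Known limitations

* The time-to-peak estimator retains a small compressive bias at very slow
  wave speeds (latency range ≫ the 10-lag horizon); velocity estimates at
  0.05 m/s are accurate to ~8% rather than the ~3% seen at 0.13–0.3 m/s.
* Consensus clustering reclusters the co-assignment matrix with a fixed
  0.5 threshold; pathological coupling matrices with genuinely ambiguous
  structure may alternate between partitions across the consensus
  iterations (capped at 20).
* The energy landscape is defined through displacement magnitude only;
  two trajectories with identical MSD are indistinguishable, and basin or
  transition-path structure is out of scope.
* `mtd()` materialises the full coupling tensor and refuses above 2 GB;
  `network_timecourse()` streams windows instead and is the intended
  interface at full parcel resolution.
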