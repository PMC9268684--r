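---
title: "Phenotyping dentate gyrus units: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping dentate gyrus units: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgephys)
```

This vignette documents the models and procedures the package
implements, the parameters that matter, and the reasoning behind the
choices that were genuinely open. It is the package's own account; the
numerical claims it makes are exactly those the test suite and
`scripts/acceptance.R` compute.

## 1. The phenotyping model

Extracellular units recorded in the dentate gyrus (DG) are assigned
putative cell types from three waveform/spike-train features, applied
in sequence:

1. **Trough-to-peak latency.** Extracellular spikes are negative-going;
   the latency runs from the global minimum (trough) to the first
   positive-going local maximum after it. Units at or below **0.4 ms**
   are narrow-waveform, putative fast-spiking PV basket cells.
2. **Burst index (BI).** From the inter-spike-interval (ISI)
   distribution, the ratio of frequency in the 0–10 ms window to that
   in the 200–300 ms window. Units **above 1.8** are putative
   excitatory (bursting) cells.
3. **AHP derivative metric.** The afterhyperpolarization expressed as
   the maximum |dV/dt| of the mean waveform after the spike's positive
   peak, in μV/ms. Using the derivative rather than an amplitude makes
   the measure insensitive to the unit's unknown distance from the
   electrode. Its distribution over excitatory DG units is bimodal;
   the valley near **70 μV/ms** separates putative mossy cells (small
   AHP) from putative granule cells (large AHP).

Everything else is `wide_interneuron`; units whose waveform cannot be
measured are `unclassifiable`, a first-class outcome that is counted,
never dropped.

### Decision rules at the boundaries

The published thresholds name open intervals on one side only, so the
boundaries need explicit conventions. This package uses:

* latency exactly 0.4 ms → **narrow** (PV);
* BI exactly 1.8 → **not** excitatory ("higher than 1.8");
* AHP exactly at the threshold → **granule** (configurable);
* a unit that is simultaneously narrow *and* bursting → **PV** under
  the default `precedence = "latency_first"`. The alternative
  `"bi_first"` is implemented and tested, because published unit counts
  alone cannot disambiguate how such units were resolved; we default to
  the physiological reading (fast-spiking interneurons can show short
  ISIs without being excitatory).

### Burst-index normalization

A ratio of "frequency distributions" over windows of unequal width
(10 ms vs 100 ms) is ambiguous: it may or may not normalize by the
width. The default here divides each window count by its width, making
BI a dimensionless ratio of per-ms frequencies directly comparable to
the 1.8 boundary; `normalize = "raw"` gives the raw count ratio. Two
conventions cover the zero windows: an empty 0–10 ms window gives
BI = 0 outright, and a nonempty early window with an empty 200–300 ms
window gives BI = +Inf with an `infinite_bi` flag — this keeps the
classifier total without inventing pseudo-counts. Trains with fewer
than two spikes get BI = 0 with a `few_spikes` flag.

### AHP window

Only the threshold value (70 μV/ms) is conventionally fixed; the exact
extremum and window are an interpretation. The default,
`post_peak_max`, takes the maximum |dV/dt| in the open window from the
post-trough peak to the end of the waveform; `post_peak_min`
(magnitude of the most negative derivative) and `full_tail_max`
(window starting at the trough) are provided as alternatives. The
discrete maximum is refined with a 3-point parabolic fit, which removes
most of the sampling bias at 20 kHz (see §4).

## 2. Group statistics

Per cell class, firing rates across experimental groups are analyzed
with the gated workflow standard in this literature:

* **Normality gate:** D'Agostino–Pearson omnibus K² per group
  (implemented from the 1990 formulas — transformed skewness plus
  transformed kurtosis, χ² with 2 df; the test suite pins it to frozen
  reference values from an independent implementation). The gate
  passes only if every group has p ≥ α.
* **Parametric branch:** one-way ANOVA, then all pairwise t
  comparisons with the pooled within-group variance, Bonferroni
  adjusted (raw p × number of pairs, capped at 1).
* **Nonparametric branch:** Kruskal–Wallis with tie correction, then
  Dunn's pairwise z tests on mean ranks (tie-corrected pooled
  variance), Bonferroni adjusted. Groups too small for the normality
  test (n < 8) route directly here.

Two-way designs use **type-II sums of squares** via nested base-R
linear-model fits (each main effect adjusted for the other; identical
to sequential sums of squares when balanced, a robust default when
not — the suite cross-checks both claims, the unbalanced case against
`car::Anova`). Repeated-measures designs are approximated by adding
the subject as an additive blocking factor; sphericity corrections are
out of scope and deliberately not claimed. The post hoc family is all
pairwise comparisons by default; α is fixed at 0.05 throughout.

The unit of analysis is the **neuron**, matching how per-group n is
reported in this literature; the animal identifier is carried through
the tables but not modeled (no mixed effects — a known limitation, see
§6).

## 3. What the synthetic generators emulate

The generators exist so that every downstream stage is testable with
known ground truth; their defaults are the study conditions under
which the acceptance checks run.

**Waveforms** are sums of three Gaussian lobes: a deep trough
(default −150 μV), a positive repolarization peak, and a shallow, slow
AHP undershoot (15% of the peak). The family was chosen for
smoothness: every extremum is C-infinity, so parabolic sub-sample
interpolation has only O(Δt²) bias and the stated recovery tolerances
are achievable at 20 kHz. The lobe centers and peak amplitude are
calibrated numerically at generation time (fixed-point iteration on a
2 μs grid) until the *continuous* template's trough-to-peak latency
and post-peak max |dV/dt| equal the requested ground truth to ~1e-5;
infeasible requests (e.g. an AHP slope target that would demand a peak
rivaling the trough, or a very small slope for a very narrow spike)
fail loudly as parameter errors rather than silently degrading. A
strictly zero AHP slope is unattainable in this family while keeping a
genuine positive peak, so the generator requires a positive target;
the features module's flat-tail-gives-zero behavior is tested on a
hand-built waveform instead.

**Spike trains** come in three modes: homogeneous Poisson, bursty
(Poisson burst onsets, geometric within-burst counts with mean 3,
intra-burst ISIs jittered ±20% around 4 ms), and jittered-regular
(lattice at 1/rate, Gaussian jitter defaulting to 1% of the period).
A 1 ms absolute refractory period is enforced by thinning (deleting
violators), which preserves the nominal rate to first order; the exact
kept-process mean, duration/(t_ref + 1/rate), is used as the oracle in
the tests. One property worth knowing: a Poisson train's exponential
ISI density concentrates enough mass below 10 ms that its burst index
exceeds 1.8 at quite ordinary rates — which is precisely why the
burst index discriminates bursting excitatory cells only against
*regular-firing* interneurons. The default cohort therefore gives its
interneuron classes jittered-regular trains (BI = 0) and its
excitatory classes bursty trains.

**Cohorts** default to 4 groups (non-defeated ND, resilient Res,
susceptible Sus, ketamine-treated Sus+Ket) × 5 animals × 2 units per
class per animal — 10 units per class per group, 160 units total, with
per-group unit counts an order of magnitude below a full study but
enough for exact label recovery. Class parameters put each class well
clear of one decision boundary and on the correct side of the others
(PV: 0.25 ms latency; wide interneuron: 0.6 ms, regular; mossy:
bursty, AHP 40; granule: bursty, AHP 100). Group rate multipliers
encode the defeat-phenotype effect directions: PV elevated (×1.5) only
in Sus; granule reduced (×0.5) in Sus and restored under ketamine;
mossy and wide unchanged across ND/Res/Sus, mossy elevated under
ketamine. Firing-rate heterogeneity is log-normal with unit-level
sdlog 0.4 plus an animal-level sdlog 0.1. The unit-level spread was
chosen a priori so that group differences of the reported magnitude
are statistically detectable at the per-group unit counts this
literature reports (~30–60 neurons) — i.e. the cohort reproduces the
discriminability that published group comparisons demonstrate, rather
than the full (larger) between-neuron variance of raw recordings,
which at these n would bury any fixed multiplier.

**Behavior.** Phase-1 interaction-zone times are truncated normal
(60 ± 15 s of a 150 s phase); phase 2 equals phase 1 times a
log-normal ratio whose *mean* is the group effect (so the expected SI
ratio equals the effect exactly — the property the degenerate-effect
test checks). Defaults: ND effect 1.05, defeated effect 0.85 with
sdlog 0.4, which yields a susceptible majority with a substantial
resilient minority. Sucrose preference increases with SI ratio
(anhedonia co-occurring with social avoidance) plus noise, truncated
to [1, 99]%.

**Intracellular sweeps** are square current steps (default 500 ms —
the step duration is not conventionally fixed, so it is configurable —
from a −70 mV baseline, 100 pA increments) with piecewise-linear
action potentials placed evenly at the threshold-linear rate
max(0, slope × (I − rheobase)). The AP shape is parameterized by
threshold (−45 mV), amplitude (80 mV), threshold-referenced
half-amplitude width (1 ms; with the fall rate at half the rise rate
the half-width is exact by similar triangles), and AHP depth (10 mV).

What the generators do **not** emulate: raw continuous voltage,
spike-sorting errors and unit contamination, probe geometry and
per-channel waveform variation, non-stationary firing, correlated
units, LFP. Passing tests therefore certify the *analysis* given
clean sorted units, not robustness to sorting artifacts.

## 4. Numerical choices

* **Sampling.** 20 kHz waveforms (0.05 ms/sample), 50 kHz intracellular
  sweeps. Units are fixed: μV and ms inside waveforms, mV for sweeps,
  seconds for spike times.
* **Extremum location.** The latency uses the global minimum and the
  first subsequent local maximum whose height above the trough is at
  least 5% of the post-trough range — identical to the literal first
  local maximum on clean templates, robust to single-sample ripple on
  noisy ones. 3-point parabolic interpolation (clamped to ±half a
  sample) refines both extrema; it is on by default and brings the
  worst-case latency error on the generator grid from half a sample to
  under 0.02 ms.
* **Derivatives** are central differences scaled to per-ms units,
  one-sided at the boundaries. The AHP metric refines its discrete
  maximum parabolically; without that refinement the combination of
  sampling offset and finite-difference smoothing can bias the metric
  by several percent at 20 kHz for narrow spikes.
* **Inverted polarity** (global maximum before global minimum) is
  auto-flipped with a warning, configurable off.
* **Bimodality detection** uses a kernel density estimate
  (Sheather–Jones bandwidth, falling back to the default rule if SJ
  fails), keeps modes of at least 5% relative height, and demands the
  valley between the two highest modes be at most 80% of the lower
  mode's height; otherwise a no-bimodality error sends the caller back
  to the fixed threshold of 70 μV/ms.
* **Degenerate inputs** raise classed conditions
  (`dg_degenerate_waveform`, `dg_small_sample`, `dg_no_bimodality`,
  `dg_no_ap`, ...) so pipelines can route rather than die; inside
  `extract_features()` a degenerate waveform becomes an NA-feature
  record flagged for the classifier.
* **Determinism.** Every generator is a pure function of its
  parameters and a seed; seeds are passed down explicitly and the
  caller's RNG state is restored. Two pipeline runs with the same
  configuration and seed are byte-identical, including p-values.
* **Serialization.** Times and waveforms are written with six decimal
  places, other numerics with 12 significant digits; manifests carry no
  timestamps so that reruns are reproducible byte for byte.

## 5. The SI-ratio boundary

Definitions of the resilient phenotype differ between "greater than 1"
and "greater than or equal to 1" even within single reports. This
package adopts **SI ratio ≥ 1 → resilient** (the boundary case is
resilient), because the susceptible definition ("under 1") is the
stable one; the choice only affects animals whose ratio is exactly 1.
Animals with zero phase-1 time have an undefined ratio and are
excluded with an `excluded` phenotype rather than mapped to infinity —
an undefined behavior should not assign a phenotype.

## 6. Problem sizes and limitations

The test suite and acceptance script run at sizes chosen to make the
statistical checks sharp while staying desk-sized: 2000 null
replicates for type-I calibration of each omnibus branch (standard
error ~0.5%), 200 cohort seeds at 35 units per group for the
effect-detection and permutation checks, 100 random trains for the
burst-index oracle, 20 seeds for bimodal-threshold recovery, and the
160-unit default cohort for end-to-end label recovery.

Known limitations, deliberate:

* no mixed-effects modeling of the animal hierarchy (neuron is the
  unit of analysis; animal ids are reported);
* repeated-measures ANOVA as subject-blocked two-way ANOVA, without
  sphericity corrections;
* no probabilistic cell typing (mixture models or clustering) — the
  package reproduces threshold rules, and `mclust` appears only as an
  independent cross-check in the tests;
* the pipeline starts at sorted units: no spike detection or sorting,
  no raw-format (NWB/Intan/Neuralynx) readers;
* generator class parameters are tuned to the decision boundaries,
  not fitted to real dentate statistics — no public sorted-unit
  dataset accompanies the in vivo recordings this workflow targets,
  so the cohort module is a synthetic stand-in by construction.
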