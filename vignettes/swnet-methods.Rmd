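---
title: "Methods: beta-band lagged-coherence networks and the small-world index"
author: "swnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta-band lagged-coherence networks and the small-world index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swnet)
```

## What the package computes

swnet implements a resting-state EEG functional-connectivity analysis for
sensorimotor cortical networks in stroke survivors with and without trait
fatigue, together with a synthetic-cohort generator that makes every stage
testable without access to clinical recordings.

The chain is:

1. **Preprocessing** of continuous multichannel EEG: anti-aliased
   downsampling to 250 Hz, zero-phase FIR band-pass 0.1–47 Hz, automated
   bad-channel detection, segmentation into 2-s epochs, amplitude-based
   epoch rejection at ±2 SD, channel interpolation, common-average
   re-referencing.
2. **Connectivity**: band-averaged lagged linear coherence between
   region-of-interest (ROI) current-density series, assembled into one
   weighted adjacency matrix per network — motor (Brodmann areas 4, 6, 8, 9,
   24, 32) and sensory (areas 1, 2, 3, 5, 7, 40, 43) in each hemisphere — in
   the beta band (13–30 Hz).
3. **Graph metrics**: weighted clustering coefficient `C_brain` and
   characteristic path length `L_brain`, normalized by the means over 100
   surrogate random networks, yielding `Cw = C_brain/C_random`,
   `Lw = L_brain/L_random` and the small-world index `Sw = Cw/Lw`.
4. **Group statistics**: FSS-7 > 4 fatigue grouping, 3×IQR extreme-outlier
   exclusion, Shapiro–Wilk and Levene checks, a three-way mixed ANOVA
   (fatigue × sex between subjects; network × hemisphere within), Bonferroni
   post-hoc t-tests, and nonparametric demographic tests.

Source reconstruction (the linear inverse mapping from scalp potentials to
cortical current density) is deliberately out of scope: the pipeline ingests
ROI-level time series and delegates inverse modelling to external tooling.

## The connectivity estimator

For each 2-s epoch, ROI series are demeaned, Hann-tapered and Fourier
transformed; cross-spectra are averaged across epochs (Welch-style,
0.5 Hz resolution). For ROIs $i, j$ at frequency $f$ the lagged linear
coherence is

$$\mathrm{LagR}(f) \;=\;
  \frac{\mathrm{Im}\,S_{ij}(f)^2}
       {S_{ii}(f)\,S_{jj}(f) - \mathrm{Re}\,S_{ij}(f)^2},$$

averaged arithmetically over the bins whose centre frequency falls in
[13, 30] Hz (inclusive). Because any instantaneous (zero-lag) mixture of
sources contributes only to the real part of the cross-spectrum, this
estimator is insensitive to volume conduction; the test suite verifies that
adding a strong common zero-lag component to two independent sources moves
ordinary coherence substantially while the median change in band-averaged
LagR stays below 0.05. Identical signals give exactly zero (the degenerate
denominator is reported with a warning). Values are clipped to [0, 1].

Two conventions were genuinely open and are documented here: LagR is
averaged *per bin* (a band-collapsed variant would pool cross-spectra before
forming the ratio), and the taper is Hann (recorded in the `cross_spectra`
object).

## Graph metrics and the surrogate null

Clustering uses the Onnela geometric-mean form on weights normalized by the
matrix maximum; nodes of degree < 2 contribute 0. Path lengths use
reciprocal weights (1/w) with all-pairs shortest paths (Floyd–Warshall);
a disconnected graph is an error, never a silent average over infinities.
Multiplying all weights by $k>0$ leaves `C_brain` and `Sw` invariant and
scales `L_brain` by $1/k$ (asserted in the tests).

Surrogate networks preserve the node count, the binary degree sequence
(Maslov–Sneppen edge swaps) and the exact multiset of edge weights, randomly
reassigned to the rewired edges. On a *complete* topology no
degree-preserving swap exists, so surrogates reduce to weight permutations —
this is the typical regime for dense coherence matrices, and it is also why
a complete equal-weight graph yields `Cw = Lw = Sw = 1` to machine
precision. A `weight_shuffle` mode skips rewiring explicitly. The ensemble
statistic is the arithmetic mean over 100 surrogates; everything is
deterministic given the seed. A compiled kernel handles the
fixed-topology permutation ensemble; sparse rewiring runs in R with a
connectivity check and up to five retries before falling back to weight
shuffling.

### How Sw responds to coupling structure — an estimator-dependent mapping

A point that matters for interpreting simulations: under this
weight-multiset-preserving null on *dense* coherence matrices, concentrating
strong weights into clustered triads **lowers** Sw. The clustering ratio
`Cw` does rise, but concentrating strong edges lengthens the brain graph's
shortest paths relative to surrogates that spread the same weights evenly,
and the `Lw` penalty empirically dominates for every concentration pattern
we examined (single triads, double triads, cliques). Sw > 1 arises for
sparse topologies where rewiring genuinely destroys triangles (e.g. two
strong triangles weakly bridged, or weighted ring lattices), not for dense
matrices with concentrated weights. The synthetic cohort's planted group
effect is chosen accordingly (below).

## The synthetic cohort

Each ROI signal is band-limited Gaussian noise (a windowed-sinc FIR applied
with zero phase; for synthesis the filter gain is applied circularly in the
frequency domain, which is free of edge transients), plus lagged
contributions from coupled ROIs, independent white noise, and optionally a
shared zero-lag component for volume-conduction tests. Defaults mirror the
reference recording conditions: 26 ROIs (13 Brodmann areas × 2 hemispheres), 250 Hz
ROI-level rate (the post-downsampling rate), 420 s per subject, beta-band
oscillations, 29 subjects (16 low / 13 high fatigue; 13/3 and 5/8
male/female), FSS-7 from truncated normals centred near the group medians
(2.1 on [1, 4]; 5.6 on (4, 7]) so scores are always consistent with the
FSS-7 > 4 grouping. Covariates (age, grip strength, nine-hole-peg-test,
HADS, stroke descriptors) are independent draws shaped like the cohort
table; no covariate correlations are modelled.

The planted group effect is a crossover in how *concentrated* the
within-network lagged coupling is: one strong triad (gain 0.65, 20 ms lag)
per network per hemisphere versus diffuse weak coupling (gain 0.25). Because
concentration lowers Sw under the surrogate null (previous section), the
high-fatigue profile carries the concentrated *motor* and diffuse *sensory*
coupling, and the low-fatigue profile the mirror image. Downstream this
reproduces the target observable — higher sensory and lower motor
small-worldness in the high-fatigue group — with a network × fatigue
crossover interaction. The gains were calibrated once against the power and
type-I-error checks in the acceptance suite and then frozen; they are not
tuning knobs.

What the generator does *not* emulate: 1/f background spectra, ocular and
muscle artifacts (a blink/spike injector exists solely to exercise epoch
rejection), inter-subject anatomical variability, and any realistic forward
model (scalp projections use a random full-rank mixing matrix). Passing
tests therefore demonstrate correctness of the estimators and calibration of
the inference under the stated generative model, not performance on real
EEG.

## Preprocessing decisions

* **Bad channels** (commonly reported only as automated detection, with no
  named criterion): robust
  z-score of log-variance across channels (median/MAD, |z| > 3) plus a
  flatline check. Deterministic and documented; all-flagged input is an
  error.
* **Epoch rejection**: the across-channel mean signal $m(t)$ is computed
  over the recording with grand mean $\mu$ and standard deviation $\sigma$.
  The default rule removes an epoch when its *mean* of $m$ deviates from
  $\mu$ by more than $2\sigma$. The sample-wise reading — reject when any
  sample of $m$ in the epoch exceeds the threshold — is available as
  `variant = "samplewise"`, but cannot be the default: for any stationary
  Gaussian-like signal roughly 5% of samples exceed 2 SD, so nearly every
  2-s epoch contains one and essentially all clean data would be discarded.
  The epoch-mean rule retains ≥ 95% of artifact-free synthetic epochs while
  still catching high-amplitude sustained transients (a 10-SD epoch-long
  step shifts the epoch mean far beyond the threshold).
* **Rejection statistics** are computed after bad-channel removal (the
  order the stage list implies).
* **ICA** ocular cleanup is a pluggable no-op: component selection is a
  manual, visual step on real data and cannot be specified; the slot accepts
  a user function.
* **Interpolation**: Perrin-type spherical splines (order m = 4, 20
  Legendre terms, regularization 1e-5) on an idealized spherical 10-20
  montage; inverse-distance weighting is a dependency-free alternative.
* **FIR design**: windowed-sinc, Hamming; taps chosen for a ≈0.5 Hz
  transition at the band edges, applied forward–backward (zero phase), so
  stopband attenuation is far beyond 40 dB and passband ripple well under
  1 dB. Downsampling low-passes at 80% of the target Nyquist before
  decimation and is exactly DC-preserving.

## Statistics

The three-way mixed ANOVA is computed by the exact contrast decomposition
for 2×2 within designs: per subject, the cell mean, network difference,
hemisphere difference and their interaction are analysed in four Type-III
(sum-to-zero) linear models on the between factors. For two-level within
factors this reproduces the classical mixed-model F tests exactly —
verified against an independent balanced cell-means sums-of-squares oracle
to 1e-10 — and sphericity holds trivially (Greenhouse–Geisser ε = 1, so
adjusted and unadjusted p coincide; both are reported). Effect sizes are
generalized η² (effect SS over effect SS plus all error strata). Subjects
missing any cell are dropped listwise; each fatigue × sex cell must retain
at least 2 subjects.

"Extreme outliers" use the 3×IQR fence convention per network × hemisphere
cell. Post-hoc families are kept separate: 4 group contrasts (one per
network × hemisphere) and 8 sex-stratified contrasts, each
Bonferroni-adjusted within its own family (`min(1, p·m)`), so the family
size is never silently inflated. Demographics use Spearman correlations
(continuous), Wilcoxon rank-sum with effect size $r = |Z|/\sqrt{n}$ from
the normal approximation (two-level categorical; the p-value itself is
exact where ties permit), and Kruskal–Wallis with
$\eta^2 = (H - k + 1)/(n - k)$ for vascular territory, skipped when any
territory has fewer than 2 subjects. All tests are two-sided at α = 0.05.

## Problem sizes and calibration checks

The acceptance suite runs, among others: 100 random fully connected 7-node
networks × 100 surrogates (ensemble-mean Sw within [0.9, 1.1]); 200
independent signal pairs at 160 epochs (null LagR < 0.1 in ≥ 95%); and a
full pipeline calibration at 60 s per subject — 200 null cohorts (planted
effect removed) for the type-I error of the network × fatigue interaction
(expected within [0.02, 0.10] at α = 0.05) and 100 cohorts with the frozen
default effect for power (≥ 80%) and for the sign pattern of the group
differences. The 60-s recording length for the calibration runs and the
reduced surrogate counts in some unit tests are the package's chosen
simulation sizes; all stage defaults remain at their reference values
(420 s, 100 surrogates).

## Known limitations

* The inverse problem is not modelled; real scalp data require external ROI
  extraction before entering the connectivity stage.
* The generator's planted effect demonstrates calibration and power under
  one generative model; effect magnitudes in real cohorts are unknown.
* The mapping "more clustered coupling → higher Sw" does **not** hold for
  dense coherence matrices under weight-preserving surrogates (see above);
  comparisons of Sw across estimator or null-model conventions should be
  made with care.
* BrainVision I/O covers the binary multiplexed IEEE-float32 subset; EDF is
  not implemented.
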