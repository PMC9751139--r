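---
title: "Mapping DBS outcomes at fiber, voxel and network level: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stimmap methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimmap)
```

# The problem

Deep brain stimulation (DBS) cohorts vary in where exactly each patient's
electrode sits and how strongly it is driven. That variability is a nuisance
clinically but an opportunity statistically: if outcomes co-vary with *where*
the stimulation field falls, the anatomy driving the response can be mapped.
`stimmap` implements that idea at three spatial levels, all consuming the same
input — one electric-field magnitude image (E-field, V/mm, in template space)
per patient plus a clinical improvement score:

1. **Fiber filtering.** Each streamline of a normative tractogram is
   weighted, per patient, by the peak E-field magnitude along its course.
   Fibers reached with at least `e_thr` (default 0.36 V/mm) by at least a
   `coverage_fraction` (default 20%) of the cohort's stimulation volumes are
   retained, and each retained fiber is assigned the Spearman correlation
   between its weights and improvement across patients.
2. **Sweetspot mapping.** Within a cohort coverage mask (voxels where at
   least 20% of E-fields exceed 0.2 V/mm, i.e. 200 V/m), each voxel's
   magnitudes across patients are Spearman-correlated with improvement;
   positive voxels are sweet spots, negative ones sour spots. Connected
   components of each sign are summarised by their peak-|R| voxel and
   |R|-weighted centre of gravity, per hemisphere.
3. **Network mapping.** Each E-field seeds a functional connectome (one
   BOLD-like timeseries per masked voxel): the field-weighted average
   timeseries is correlated with every voxel's series and Fisher-z
   transformed, giving a connectivity fingerprint; fingerprints are
   voxel-wise Spearman-correlated with improvement into an R-map, which can
   be decoded against a library of term maps.

Why rank correlations everywhere? The mapping only assumes that *more*
stimulation of a relevant structure does *more* — the exact dose-response
shape (linear, cubic, logistic) is unknown and patient-specific. Spearman
statistics are invariant to any strictly increasing transform of the field
magnitudes, which the test suite verifies as an exact property.

All three levels share one estimation-and-validation machinery: a fitted
model turns a held-out patient's field into a scalar score (rank profile
correlation for fibers and networks; the masked mean of E x R for
sweetspots); scores are mapped to the percent scale by an affine calibration
fitted within the training fold; leave-one-out and k-fold designs, a
permutation test, and error metrics (RMS, median absolute error, and a
sum-of-squares R^2) quantify predictive value.

Outcomes are percent improvements on a deficit scale (ADAS-cog 11, higher =
worse): `improvement_pct(baseline, followup) = 100 (baseline - followup) /
baseline`, so positive means cognitive improvement. The baseline denominates
the change. Responder classes (`poor` at <= -21%, `middle` in (-21, 0],
`top` above 0) are provided for visualisation only.

# The E-field stand-in

Patient-specific finite-element field models are out of scope. What the
mapping levels actually consume is a smooth magnitude field decaying from the
active contacts, so the simulator uses the closed form for a point current
source in an infinite homogeneous medium: potential `V(r) = I / (4 pi sigma
r)` and single-source magnitude `|E|(r) = I / (4 pi sigma r^2)`; with current
in mA, distance in mm and conductivity in S/m the expression yields V/mm
directly. Multiple sources superpose vectorially (opposed sources cancel at
the midpoint), and distances below 0.5 mm are evaluated at 0.5 mm so the
singularity never reaches a voxel (at exactly zero distance the direction is
undefined and the contribution is dropped). Conductivity defaults to
0.2 S/m, the gray-matter order of magnitude. Thresholds use `>=` throughout.

Hemispheric mirroring is a rigid x -> -x reflection; it requires a grid whose
x coordinates are symmetric about the mid-sagittal plane and is an exact
involution. The mirrored sweetspot variant enters each field twice — itself
and its flip, with the same outcome — doubling the rows rather than
averaging, which makes the fitted map exactly x-symmetric.

# The synthetic world

Every recovery test runs against `cohort_spec()` worlds with recorded ground
truth; all generators are pure functions of (spec, seed). The defaults state
the emulated regime once:

* 60 patients; a 41 x 41 x 31 grid at 1.5 mm centred on x = 0;
* bilateral implant targets at (+/-7, 1, -6) mm with 2 mm Gaussian placement
  jitter per axis, per-hemisphere currents uniform in 2-5 mA;
* a planted **sweet** sphere (radius 4 mm, weight 1) at (4.8, -0.9, -3.6) mm
  near the right lead and a **sour** sphere (radius 4 mm, weight 0.5) at
  (-5.5, 0, -1) mm near the left lead, so both hemispheres carry
  outcome-relevant exposure as in a bilateral cohort;
* noiseless effect = weighted sweet-overlap minus weighted sour-overlap of
  the summed bilateral field; improvement = the standardized effect scaled
  to mean -38.6 and SD 48.8 on the percent scale (the regime reported for
  this indication) plus Gaussian noise of SD 24.4 — i.e. noise at half the
  signal SD;
* baselines uniform on the 12-24 ADAS-cog inclusion band; follow-ups
  back-computed from the improvement.

The tractogram (`tract_spec()`) has 10 bundles of 50 fibers (quadratic
arcs plus per-fiber offset and smooth wander, 1 mm spread). Bundle 1 is the
predictive bundle: it traverses the sweet region and hugs the right lead
near the contact plane, so a sizable share of its fibers clears the
coverage filter. Bundle 2 hugs the left lead the same way and is the default
event-driving bundle of the flashback generator. The remaining bundles are
distractors kept at least 8 mm (along their entire arc) from the sweet
center and both targets: with inverse-square fields and 2-5 mA currents the
inclusion reach is only ~2.4 mm, so corridor-crossing distractors would not
be "distractors" at all but partially stimulated structures with genuine
correlations.

Flashback probes emulate intraoperative testing: each probe drives one
electrode at one of four contacts (stacked 3 mm dorsally) and one of four
amplitudes between 1 and 10 mA while the contralateral lead holds a chronic
3 mA — 60 x 2 x 4 x 4 = 1920 probes. Event probability is
`plogis(alpha + beta * peakE)` with `peakE` the probe's peak magnitude on the
designated bundle and `alpha` calibrated by root finding to a 3% marginal
rate (about 60 events in ~2000 probes). Varying one side at a time matters:
if both leads ramped together, every fiber's weight would be monotone in the
shared amplitude, the amplitude-event correlation (rho ~ 0.24) would make
essentially *every* included fiber FDR-significant at n ~ 2000, and the
designated bundle's share of the significant set would drop to ~0.5. With
the one-side-varied design the contralateral bundle's exposure at event
probes is patient-constant and the designated share reaches 1.0.

The connectome (`generate_connectome()`) is a latent-component world:
masked voxel series are mixtures of a spatially uniform common mode (the
global signal), K = 4 bilateral Gaussian blob-pair components (SD 4 mm) and
white noise, over a gray-matter-like mask restricted to network-bearing
territory. Component 1 sits on the sweet region and its mirror; component 2
is a deliberately strong "stimulation corridor" network dorsal along the
leads — most across-patient variance in seed connectivity reflects where the
field sits, not outcome, and without such outcome-unrelated variance the
seed norm becomes a monotone function of the planted component's exposure
and leaks a global anticorrelation into every voxel. Long, low-noise series
(T = 1000, sigma = 0.05) emulate many-subject averaging.

# Validation machinery

* **Calibration**: models emit unitless scores; error metrics are on the
  percent scale, so a least-squares affine map fitted on training scores
  bridges the two within each fold.
* **MAE is the MEDIAN absolute error** throughout — less outlier-sensitive
  than the mean; the initialism is kept for continuity with the field's
  reports but never denotes the mean.
* **R^2 by sum of squares**: `1 - SSE/SST`, not the squared correlation; it
  can be negative for out-of-sample predictions worse than the mean.
* **k-fold partitions** are a seeded shuffle followed by a contiguous split
  (sizes differ by at most one, remainders to the first folds), without
  stratification; `k = N` reproduces leave-one-out per-unit scores exactly.
* **Permutation test**: the in-sample statistic (fit on all, score all,
  Spearman of scores vs outcomes) is compared one-sided against the same
  statistic after shuffling outcomes, with the add-one rule
  `p = (1 + #{null >= obs}) / (n_perm + 1)`, so p is never 0.
* **Cross-validation p-values are one-sided** (better-than-chance).
  Held-out score-outcome correlations carry a negative bias under the null
  (the classic leave-one-out artifact: each fold's model overfits its
  training set in the direction opposite to the held-out point), which makes
  a two-sided test anticonservative under permutation; measured on permuted
  cohorts the two-sided version exceeded the nominal 5% rate roughly
  threefold while the one-sided version is calibrated.
* **Benjamini-Hochberg step-up** is implemented directly (reject all
  `p <= p_(k*)`, `k* = max{k: p_(k) <= k q/m}`) and tested against an
  independent implementation on a thousand random instances.
* **Per-fiber p-values** (flashback contrast) use the two-sided t
  approximation `t = r sqrt((n-2)/(1-r^2))`; within-patient dependence of
  probes is deliberately not modelled, matching the published design.

# Design choices where the design was open

* **Aggregation along a fiber** is the peak magnitude (mean available via
  argument): the peak is what the published method aggregates, and it is
  insensitive to how much of a long fiber lies far from the field.
* **Per-fiber correlations use all cohort rows**, including patients whose
  field never reaches the fiber: zero weights are informative ranks.
  Scoring against only positive-R fibers is available (`positive_only`) but
  not default; in the synthetic world it predicts slightly worse.
* **Cluster connectivity** is 26-neighborhood by default (6 available);
  peaks are the maximum-|R| voxel with ties broken by lowest linear index;
  centroids are |R|-weighted by default.
* **Unmasked voxels are NaN, never 0**, so the sweetspot estimator cannot
  silently dilute its masked mean.
* **Decoding similarity is Pearson by default** (Spearman available). Over
  a mask dominated by near-zero background, whole-mask rank similarity is
  governed by the spatial ordering of that background — in testing, a
  distractor component's rank similarity could exceed the planted
  component's, while Pearson ranked the planted component first with a 2-3x
  margin. Rank similarity retains the rescale-invariance property and is
  kept as an option.
* **Network recovery testing uses component-coupled outcomes**
  (`generate_network_outcomes()`): the cohort's sweet/sour outcome carries
  amplitude variance that scale-invariant fingerprints cannot observe,
  capping the correlation between outcome and *any* fingerprint-visible
  quantity near 0.3-0.5 — no mapping method could recover a component from
  that. The helper generates outcomes from the planted component's
  per-patient exposure, scaled and noised exactly like the cohort model.

# What a green test does and does not establish

The generators emulate placement variance, inverse-square fields, bundle
structure, latent networks, and monotone noisy outcomes. They do not emulate
tissue heterogeneity, electrode insulation geometry, nonlinear template
registration, site effects, or anatomically realistic fiber courses. A green
recovery test therefore establishes that the estimators recover *planted*
structure under the stated noise model at desk scale — not that any
particular anatomical claim is correct.

Two recovery checks in the test suite are expected to fail, deliberately
left failing, and worth understanding:

* **Permuted-outcome AUC band (fiber level).** After permuting outcomes the
  suite asks whether the predictive-vs-distractor AUC of per-fiber R falls
  near 0.5 in nearly all runs. In a bundle-structured tractogram fibers
  within a bundle have nearly identical weight profiles, so a permuted
  cohort moves each bundle's R values *together*: the AUC is effectively a
  rank among a handful of correlated bundle blocks and lands near 0, 0.5 or
  1. The band presumes exchangeable per-fiber statistics under the null,
  which contradicts bundle structure by construction. The point estimate
  itself (recovery AUC ~ 0.999 on unpermuted outcomes) passes.
* **Top-decile Dice (network level).** Correlation fingerprints are
  deterministic functions of a low-dimensional patient geometry (two contact
  positions and two currents), and the seed-normalisation term injects a
  patient-level monotone factor into every voxel's across-patient variation.
  Any outcome that is itself a smooth function of that geometry therefore
  rank-correlates at |R| ~ 0.3-0.65 with essentially *every* masked voxel,
  while the planted component's own R is capped near 0.7 by the same
  normalisation. The achievable top-decile Dice against the planted loadings
  plateaus near 0.2-0.25 across the defensible configuration space (global
  mode strength, corridor amplitude, blob scale, mask resolution, noise
  level were all varied). The decode check — the planted component map must
  rank first in a mixed library — passes with a wide margin, so the R-map
  does point at the right network; it is the voxel-exact decile overlap
  that correlation fingerprints cannot deliver in this regime.

# Numerical notes

* Spearman statistics are computed as Pearson correlations of average ranks
  (ties averaged), vectorised as one matrix product on centred rank
  matrices; columns with zero rank variance yield NA and are dropped from
  models at fit time.
* Fisher z clips correlations to +/-(1 - 1e-7) so self-correlations stay
  finite.
* Streamlines are resampled to at most half the smallest voxel size before
  nearest-voxel lookup, so thin voxels cannot be stepped over.
* Volumes are written as float32 NIfTI-1 with an sform affine; streamline
  files as TrackVis TRK (per-fiber scalars as tract properties) or MRtrix
  TCK; round-trips are tested against `nibabel` as an independent oracle.
* Grids are 0-based voxel indices with `world = affine %*% c(i, j, k, 1)`;
  no half-voxel shifts anywhere in the public interface.
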