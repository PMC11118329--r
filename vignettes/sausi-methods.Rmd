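---
title: "Quantifying social aversion from dyadic pose tracking: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying social aversion from dyadic pose tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sausi)
```

## The assay and the measurement problem

The package quantifies social aversion in a selective-access assay: an
experimental mouse lives on one side of a two-chamber arena, a docile
conspecific on the other, and a tunnel lets the experimental animal choose
whether, when and how to engage. A session has a solo baseline (180 s by
default) followed by a dyadic test phase (600 s). Two data streams describe
the session: a manually scored event log of a closed behavioral vocabulary
(`behaviorRegistry()`), and eight-node keypoint trajectories for both
animals at 30 fps.

Everything downstream answers one question in two independent ways: can the
animal's housing history (group-housed, GH, versus socially isolated, SI) be
read out from its social behavior?

## The supervised arm: ethogram metrics and the aversion index

`scoreSession()` reduces a session to one row of metrics: sniffing time by
subtype and their sum, conspecific sniff bouts, social freezing time, social
reactivity (reactions per conspecific sniff bout, as a percentage), tunnel
hesitancy (cumulative sheltering before the first social-chamber entry,
reversing, latency to enter), prosocial initiations, social chamber
preference, and the non-social controls (grooming, non-social freezing,
aggression, jumps, baseline thigmotaxis).

Conventions that matter:

* **Time.** Spans are half-open `[t0, t1)`; intervals are clipped to the
  span for durations, and a point event exactly at a span's end is not
  counted. This prevents double counting at phase boundaries.
* **Zones.** Chamber membership is decided by the trunk node inside a
  chamber polygon. Full-body entry criteria ("all four paws") cannot be
  evaluated from an eight-node skeleton that has no paws; the trunk is the
  most stable single-node surrogate, and this divergence is deliberate and
  documented here.
* **Undefined ratios.** Reactivity with zero conspecific sniff bouts, and
  entry latency for an animal that never entered, are *flagged* (`NA`), not
  guessed and not errors. Flagged values are skipped by the z-scoring and
  dropped (column-wise) from decoding features.
* **Thigmotaxis.** Fraction of baseline frames with the trunk within 2 cm of
  the home-chamber wall. The threshold is a package default; no standard
  value exists for this arena.

`aversionAnalysis()` turns the metric table into the composite index: each
composite behavior is z-scored over the pooled cohort with the sample
(n − 1) sd, motivation-direction behaviors (prosocial initiations, chamber
preference) are multiplied by −1, and the per-subject mean of the
sign-aligned z-scores is the social-aversion index. Design choices that were
genuinely open:

* **Reference population.** Pooling both groups keeps the index symmetric
  and needs no choice of a "control" group; standardizing against one group
  is available via `zscoreTable(reference=)`.
* **Sign alignment.** Without negating the motivation metrics the average
  would mix "more aversion" and "more approach" directions and cease to be
  an aversion index; the flip is an interpretation, exposed in
  `defaultCategoryMap()` and fully configurable.
* **Degenerate behaviors.** A behavior no animal in the cohort expressed
  (zero variance) carries no information; `aversionAnalysis()` drops it with
  a warning, while the lower-level `zscoreTable()` treats it as an error so
  silent degeneracy cannot propagate.

Group comparisons use two-tailed independent-samples Student t tests with
pooled variance (`groupTTest()`), the conventional default for this assay
family; Welch's correction is a switch.

## The decoder

`fitLogisticDecoder()` is a multivariable binary logistic regression fitted
by Newton iteration on the ridge-penalized negative log-likelihood with an
unpenalized intercept, features standardized internally. It reports
*training* accuracy (the fraction of the fitting data classified correctly
at the 0.5 threshold) — deliberately not cross-validated generalization,
which is a different quantity — and standardized coefficients whose
magnitudes rank feature importance.

The default penalty is λ = 1. Two considerations fix it: it must be small
against any realistic subject count so the fit is essentially maximum
likelihood (λ/n ≈ 0.03 for a 36-subject cohort), and it must be large
enough that the coefficient direction is unique when the classes are
linearly separable — at near-zero penalty the separating direction of a
separable cohort is arbitrary and "most important feature" would be
meaningless. The penalty is recorded in every `DecoderReport`.

Note that training accuracy is not monotone in λ in general (the guaranteed
monotonicities are in the fitted deviance and the coefficient norm), and on
small cohorts with many features training accuracy is far above chance even
for uninformative labels; chance-level calibration is therefore checked with
permuted labels at large n, where the overfitting bias vanishes.

## The unsupervised arm: posture angles to watershed regions

`mapCohort()` runs the mapping pipeline: gap interpolation, angle features,
PCA, 2-D embedding, kernel-density watershed, occupancy, and occupancy
decoding.

* **Interpolation** (`interpolateTracks`) fills invalid runs up to 1 s per
  node linearly; longer gaps stay invalid and their frames are excluded.
  Each filled cell is remembered, and every embedded frame carries the
  fraction of its source coordinates that were filled.
* **Angle features** are the interior angles at the head (nose–head–trunk
  and ear spread), the trunk (spine bend) and both hips, for each animal,
  plus the signed inter-animal heading difference: eleven features,
  rotation- and translation-invariant by construction. Temporal derivatives
  are available behind a flag but off by default: the description this
  design follows speaks only of angles, and the derivative-and-wavelet
  elaboration of other pipelines is intentionally not the default.
  Features are z-normalized over the pooled cohort frames. Frames are
  subsampled at stride 3 (an effective 10 Hz), which oversamples postural
  dynamics several-fold while keeping cohort-scale matrices small.
* **Embedding** is a pluggable contract (2-D output, deterministic under a
  fixed seed, neighborhood-preserving). The default backend is the
  variance-maximizing linear projection to two dimensions with a fixed sign
  convention — exactly reproducible and fast at cohort scale; UMAP via uwot
  (single-threaded, seeded) is the `backend = "umap"` alternative when a
  nonlinear map is wanted.
* **Watershed.** The embedding density is estimated by a binned Gaussian
  KDE on a 200 × 200 grid padded 5% (Scott's rule per axis times a factor
  of 2 — the factor calibrates region granularity to the order of ten
  regions on default synthetic cohorts). Every cell is assigned to the
  density mode reached by steepest ascent over the 8-neighborhood, ties
  toward the lower linear index; this is equivalent to watershed on the
  negated density from local-maximum markers, with boundary cells joining
  the steeper-ascent region. Regions below 0.2% of occupied cells merge
  into the neighbor with the densest shared boundary. Regions are numbered
  by descending peak density, a stable data-derived order (the original
  numbering scheme this mirrors is unstated). Cells beyond the truncated
  kernel's reach have exactly zero density and form the background.
* **Exclusion.** Regions whose member frames are on average majority-built
  from interpolated coordinates are flagged (`artifactRegions`), mirroring
  the exclusion of map regions that represent outlier or missing tracked
  points, and are removed from the region t tests and the occupancy
  decoder.

Per-subject occupancy fractions over the regions then feed per-region
two-tailed t tests and the same logistic decoder.

## The threat-imminence profile

`distanceBinProfile()` aligns behavior to nose-to-nose distance: test-phase
frames with a valid distance are assigned to 2-cm bins (0 to the arena
diagonal by default); start-stop behaviors get active-frame fractions per
bin, point events get rates per bin-second, and empty bins are flagged NA
rather than zero. Frames where either nose is untracked are excluded, not
imputed — the distance simply does not exist there. `sessionRaster()`
serializes the session's intervals, points and distance trace losslessly
for raster plots.

## What the synthetic cohort emulates — and what it does not

`simulateSession()` is a continuous-time generative model of the dyad, not a
video synthesizer. A semi-Markov behavioral program drives both animals:
baseline wandering with wall preference, grooming and non-social freezing;
a hesitancy script (home dwell, tunnel sheltering bouts with reversing,
first entry); then competing exponential clocks for sniffing (with a
subtype mix), prosocial initiations, conspecific sniff bouts — each
resolving into social freezing, a reactivity dart, or nothing — aggression,
jumps and home visits. Body centers move along piecewise-linear
goal-directed segments; skeleton nodes sit on fixed-length limbs around a
smoothed heading with state-dependent posture parameters (head yaw, spine
bend, hip spread, plus state-specific oscillation), so posture angles carry
the behavioral state and the unsupervised arm has real structure to find.
Gaussian jitter (sd 0.15 cm), missing points (1% of cells) and optional
identity swaps model tracking noise.

The GH preset and the SI multipliers (social-freeze probability ×10,
reactivity ×3, mean first-shelter bout ×4, reversing ×3, initiation rate
×0.5, aggression ×5, chamber preference unchanged) are package defaults
chosen once to reproduce the *direction* of every group contrast at
realistic magnitudes. No published effect sizes exist for these quantities
— the source reports significance patterns, not rates — so these numbers
must never be cited as empirical values. Consequently, passing tests show
that the pipeline recovers structure that is present and stays calibrated
when it is absent (identical-parameter null cohorts); they do not certify
accuracy numbers on real videos. Real data differ in ways the generator
deliberately omits: correlated tracking failures, occlusion during close
contact, postural idiosyncrasy across animals, and drifting behavioral
rates within a session.

Every simulated session returns a `GroundTruth` whose summaries are
recomputed from the realized frames and events by the generator's own
rectangle-based code, so the ethogram metrics can be checked against them
exactly, and the whole generator is bit-reproducible from
`(config, condition, seed)` with per-session seeds derived from a master
seed by a splittable counter.

## Numerical choices and degenerate inputs

* Zone membership uses even-odd ray casting; chamber polygons are disjoint,
  so ambiguity lives only on measure-zero boundaries.
* The Newton solver halves its step until the penalized objective
  decreases, converges on a gradient-norm tolerance of 1e-8, and reports a
  convergence error (with the gradient norm) rather than a silent partial
  fit.
* Zero-variance decoder features are dropped and recorded; a zero pooled
  sd in the t test returns a degenerate flag instead of an infinite
  statistic.
* Watershed ties (equal-density steepest neighbors, equal peak densities)
  break toward the lower linear index, making the segmentation fully
  deterministic.
* Problem sizes in the test suite: the study-scale checks use n = 18 per
  group and 20 master seeds — the cohort sizes the assay was reported
  with — while structural unit tests use short sessions (30 s + 90 s),
  which exercise identical code paths.

## Known limitations

* The default embedding is linear; fine postural submodes that only a
  nonlinear map would separate can share a watershed region. The UMAP
  backend exists for that case at higher cost.
* Manual scores are taken as ground truth; the package does not detect
  behaviors from keypoints.
* The composite index weights all behaviors equally after z-scoring;
  category sub-means are reported so alternative weightings can be built.
* Training accuracy is the reported decoder statistic by design; it should
  not be read as out-of-sample performance.
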