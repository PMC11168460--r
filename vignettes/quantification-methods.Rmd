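---
title: "Quantification methods for bead pull-down and condensate assays"
author: "pulldownQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for bead pull-down and condensate assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulldownQuant)
```

## The assays and what is quantified

Autophagy receptors such as p62/SQSTM1, NBR1 and TAX1BP1 recognize
ubiquitylated cargo. Two fluorescence-microscopy assays read this out in
vitro:

* **Microscopy-based pull down.** Agarose beads (50–100 µm) carry a
  fluorescently tagged bait on their surface; binding of a labeled prey is
  seen as a bright rim in the prey channel. The binding signal for one bead
  is quantified from radial line profiles: rays from the bead center out
  past the rim, each scored by the difference between its maximum and
  minimum gray value. A bright rim gives a large min–max difference; an
  empty bead gives only the noise range.
* **Condensate formation.** Receptors and cargo form micron-scale
  condensates (puncta). The readouts are the number of condensates per
  image over time, and the fraction of reference-channel condensates that
  also carry signal in a probe channel (the colocalization score), plus
  FRAP mobile fractions for exchange dynamics.

The package implements both quantification chains, the hierarchical
statistics that sit on top of the bead assay, the targeted-MS
normalization rules used for ubiquitylation-site intensities, and a
synthetic-scene generator that provides ground truth for every stage.

## Bead pipeline

**Detection.** The reference detector thresholds the bead (bait) channel at
the image median plus `k` robust SDs (MAD-based, `k = 5`), fills holes
(bead cores are dark), labels connected components, and discards
components below `minArea = 100` px or with a fill fraction below
`minFill = 0.6` against the circle through their farthest pixel. The fill
cutoff deterministically rejects merged doublets: two touching equal disks
have fill ≈ 0.5, a single disk ≈ 1. External segmentation models (for
example a cellpose-style AI backend) plug in as a function behind the same
label-mask contract; the package deliberately ships no trained model.

**Circle fit.** Center = centroid of labeled pixels; radius =
`sqrt(area/pi)`. This is parameter-free, deterministic and exact for disks;
boundary least squares would add nothing for convex bead masks. Fitted
radii below `minRadius = 3` px flag the bead rather than erroring.

**Profiles.** `nLines = 8` rays at equally spaced angles starting at 0 rad,
sampled every `step = 1` px by bilinear interpolation, from the center to
`(1 + extensionFrac) * radius` with `extensionFrac = 0.2`, so every ray
crosses the rim into local background. The original plugin states only "a
predefined number" of lines extending "beyond the border"; all three
values are configuration keys. Samples leaving the image exclude the
profile (`out-of-bounds`); a profile whose sampled points touch a pixel of
another bead's label is excluded (`adjacent-bead`), using the combined
mask of all detected beads. Coordinates are 0-based, x along columns,
pixel centers at integers, angles counterclockwise from +x.

**Scoring and summaries.** Each retained profile scores
`max(samples) - min(samples)`. A bead's "points of measurement" are taken
to be these per-profile scores (not the raw pixel samples) — the plots in
this kind of assay show one value per bead derived from per-line
quantification; the per-pixel reading remains available from the profile
objects. Per bead, the mean and sample SD (n−1; a single profile gives SD
0 by convention) are recorded, and beads whose SD is **equal to or
greater than** half their mean are excluded — the boundary case SD =
mean/2 fails, and mean 0 with SD 0 fails by the same rule. The QC filter
is idempotent and its exclusion report (bead, mean, SD, ratio, reason)
replaces the original plugin's interactive inspection step.

## Condensate pipeline

**Rolling-ball background.** Background is the grayscale opening of the
image with a non-flat hemispherical ("ball") structuring element of the
given radius, subtracted and clipped at 0. Edges use nearest-pixel
replication, so constant images map exactly to zero and features narrower
than the ball survive essentially unchanged. Radii of 1–2 px match the
diffraction-limited spot scale used in the assay's own processing.

**Counting.** Threshold (Otsu, fixed value, or robust background + k·SD),
connected components, discard area < `minArea = 4` px — large enough to
reject single-pixel noise while keeping 1–2 px features that survive the
small rolling-ball radii. An all-zero or constant image yields an empty
set, not an error.

**Colocalization.** A reference spot is positive when its mean probe
intensity inside the spot **mask** (mask overlap, not centroid distance)
exceeds the probe background mean by more than `k = 3` background SDs,
with background taken over pixels outside all spot masks. The assay
literature reports only the bounds of this score (">95 %", "<20 %"),
never its threshold; `k` is a configuration key and is echoed into every
output. With no reference spots the fraction is reported as 0 with a
flag, never an exception.

## FRAP

Traces are normalized to their own anchors,
`N(t) = (I(t) − I_bleach)/(I_pre − I_bleach)` with `I_pre` the pre-bleach
mean, so N reads as the recovered fraction of bleached signal. The mobile
fraction is the mean of the last `tailFrames = 5` normalized values,
clamped to [0, 1]. A tail mean was preferred over curve fitting because
the assay's readout is qualitative (mobile vs immobile) and the tail mean
needs no kinetic model; with the default cadence (1 frame/s for 30 s) and
a recovery rate ≥ 0.5 s⁻¹ its truncation bias is below 0.01. A
single-exponential Levenberg–Marquardt fit (`fitFrapRecovery`) is provided
as the secondary, model-based estimator. No acquisition-bleaching
correction is applied since the protocol defines no reference region.

## Inference

Bead responses are nested: beads in wells, wells in experiment
replicates. The model is
`mean_score ~ condition + (1 | replicate) + (1 | replicate:well)`,
fitted by REML. Well labels repeat across replicates on real plates, so
wells are disambiguated as `replicate:well`; a well carrying two
conditions is rejected as mislabeled. Fixed-effect contrasts (reference
level = first condition in the table) are tested with Wald t statistics
using Satterthwaite denominator degrees of freedom; with as few as three
replicates the plain normal reference is anticonservative, and the
estimated-marginal-means route used in practice for such data also relies
on t references. A plain Wald-z option exists (`pMethod = "wald"`), and
the p-value method is recorded in the result. Singular fits are flagged,
not hidden; with all variance components at zero the estimate reduces to
OLS. "Nested ANOVA" on such designs is this same model, so no separate
engine is provided. Student t tests are pooled-variance and two-tailed,
with zero-variance degeneracies resolved explicitly; two-way ANOVA uses
Type II sums of squares, falling back to explicit nested-model RSS
differences when the saturated fit has zero residual variance (noise-free
simulations), where F is reported as 0 or unbounded rather than NaN.

## Targeted-MS normalization

Modified (GG-remnant) peptide intensities are divided, within each
sample, by the sum of **exactly five** unmodified reference peptides from
the same protein; a missing or zero reference aborts rather than
renormalizing over a subset, because silently shrinking the reference set
biases every paired ratio. Paired log2 ratios (wild-type DUB over its
catalytically dead mutant) are computed per peptide — two peptides
covering the same site stay separate rows, doubling the data points for
that site, and site-level aggregation is an explicit separate step. Gel
sections are never mixed: site intensities divide only by their own
section's protein intensity. The reference-peptide identities are a
required input with no default. All normalized quantities are invariant
to per-sample multiplicative factors, and the ratio is antisymmetric
under swapping numerator and denominator.

## Synthetic scenes and what they do (not) show

The generator renders what each stage measures, with per-object ground
truth:

* **Bead scenes** — hard-edged annuli (rim over core) on noisy
  background. No point-spread blur by default, so programmed intensities
  are recoverable exactly: with a rim plateau wider than 2·√2 px, some
  integer sample distance has all four bilinear neighbors on the rim and a
  noise-free profile scores exactly the rim value. Default geometry is
  radius 16 px with a 6 px rim — a scaled-down but proportionate stand-in
  for 50–100 µm beads whose rim spreads over several pixels through the
  optics; the true pixel scale of the original acquisitions is not
  published, so geometry is configurable, not inferred. Optional Gaussian
  blur is available.
* **Condensate series** — symmetric 2-D Gaussians truncated at 4σ, the
  standard diffraction-limited emitter model, placed without overlap
  (rejection sampling; exceeding capacity errors with the capacity named);
  probe-channel twins appear with probability `colocFraction`.
* **FRAP traces** — single-exponential recovery with programmable mobile
  fraction; **bead tables** — Gaussian random intercepts for replicate and
  well plus residual noise around condition means; **PRM tables** — paired
  lognormal intensities with per-sample global factors that the reference
  normalization must cancel.

Noise is additive Gaussian clipped at zero — simple, with testable
moments. Real images add Poisson photon statistics, camera gain, optical
aberrations, uneven illumination, debris and out-of-focus light, and real
beads are not perfect annuli. Passing tests therefore demonstrate the
correctness of the measurement machinery (geometry, arithmetic,
exclusion logic, statistical calibration under the stated model), not
segmentation robustness on real micrographs — for that, an external
segmentation backend can replace the reference detector behind the same
mask contract.

A single top-level seed drives each generator, with sub-draws consumed in
documented order, so identical specifications reproduce bitwise-identical
outputs; pipelines re-run from their resolved configuration reproduce
their CSVs byte for byte.

## Validation problem sizes

The shipped validation uses sizes chosen to exercise each property while
keeping the whole suite quick on a laptop: 20 seeded scoring scenes
against a brute-force ray oracle (tolerance 1e-9); 100 beads (50 coated,
50 empty, noise SD 5 on a 100 gray-value rim) for separation;
colocalization at programmed fractions 0–1 with 200 spots per level;
mixed-model calibration on 500 null tables and 200 effect tables at the
default design of 3 replicates × 4 wells per condition × 30 beads (fixed
effect 50, replicate and well SDs 10, residual SD 20 — dispersion typical
of per-bead scores in this assay). `scripts/acceptance.R` recomputes the
same quantities from scratch for any seed.

## Known limitations

* The reference detector is tuned to the synthetic noise model; real
  acquisitions should use a trained segmentation backend.
* Rolling-ball radii much larger than ~10 px become slow (the
  implementation is O(area · radius²)); the assay's own radii are 1–2 px.
* 3-D stacks, photobleaching during acquisition and camera gain models
  are out of scope; positions are handled as independent 2-D scenes.
* Exact p-value agreement with other mixed-model software is not a goal:
  estimates and variance components agree, but denominator-df conventions
  differ between packages.
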