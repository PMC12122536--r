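---
title: "Methods: compartment-like striatal parcellation and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment-like striatal parcellation and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striocompart)
```

## The scientific problem

The striatum is built from two interdigitated tissue compartments. The
striosome (~15% of striatal volume) is mu-opioid-receptor rich,
limbic-connected, and forms island-like branches; the matrix (~85%) is
calbindin-rich, sensorimotor-connected, and spatially contiguous. The
compartments cannot be distinguished in living humans by contrast alone, but
they *can* be inferred from differential structural connectivity: decades of
tract-tracing work established cortical and subcortical regions whose
projections strongly favor one compartment. `striocompart` implements the
full analysis chain built on that idea:

1. **Parcellation** — given per-voxel streamline counts toward five
   striosome-favoring and five matrix-favoring "bait" regions (produced
   upstream by probabilistic tractography in classification-targets mode),
   compute the per-voxel bias `P = S / (S + M)` and select equal-volume,
   most-biased striosome-like and matrix-like seed masks per subject and
   hemisphere.
2. **Anatomical validation** — abundance, cluster segregation, centroid
   offsets, and 2-mm coronal-plane volume profiles, compared against the
   histologic signatures of the compartments.
3. **Negative controls** — random location jitter of the seed masks (same
   neighborhood, different voxels) and bundle-core Dice overlap.
4. **Resting-state functional connectivity** — mean seed time course,
   voxel-wise Pearson correlation with every non-striatal voxel, Fisher z
   transform, and paired group contrasts (striosome- vs matrix-seeded) with
   age and sex covariates and cluster-level family-wise-error control by
   sign-flip permutation.
5. **N-1 somatotopy** — leave-one-out parcellations quantify each bait
   region's contribution to compartment bias; winner-take-all segmentation
   and refinement yield 50-100-voxel somatotopic zones whose compartment
   bias is tested by ANOVA.
6. **Reporting** — laterality percentages, significant volumes, fold
   ratios, and Dice overlap between contrast maps.

Because the HCP-scale inputs (tractography on 674 subjects) are not
reproducible at desk scale, the package ships a first-class synthetic-data
module that plants known ground truth with the statistical structure the
analysis assumes, so every downstream stage is testable by recovery.

## The synthetic cohort

### Striatum geometry

`generate_striatum()` places caudate and putamen per hemisphere as
ellipsoids on a centred RAS grid (default 40 x 50 x 40 voxels at 1.25 mm,
the diffusion-grid resolution) and plants striosome islands inside the
matrix.

A packing argument shaped the island model. Islands that must not touch
under 26-connectivity need centre separations of at least `2r + 2` voxels
(Chebyshev), i.e. one island per `(2r + 2)^3` cell; a radius-2 ball holds
33 voxels, so the density ceiling is about `33 / 216` — ~15%, the striosome
fraction itself. At the
histologic abundance, island *density* therefore cannot encode the
rostro-ventro-medial enrichment the compartment shows in tissue: any
spatial region is already at the packing ceiling. The generator instead
carries the gradient chiefly in island *size*: each island's radius is
drawn as `1 + Binomial(island_radius - 1, plogis(g * (q - 0.5)))`, where
`q` is the within-nucleus rank (0-1) of the combined
rostral + ventral + medial location score and `g = gradient_strength`
(default 5). Island centres are proposed with weight `exp(g * q)` and kept
at a Chebyshev separation of the two radii + 2, which guarantees disjoint
islands; the last island is trimmed deterministically to land exactly on
the target fraction. This is also biologically faithful — striosomes are
larger and denser rostrally.

Key parameters (all in `striatum_spec()`):

* `striosome_fraction` (default 0.15) — the histologic prior.
* `gradient_strength` (default 5, unitless) — 0 removes the location bias;
  values above ~10 concentrate nearly all striosome volume in the rostral
  caudate head (used in tests that need a planted rostral excess).
* `island_radius` (default 3 voxels) — the *maximum* island radius.

What the generator does **not** model: branching, curved striosome shapes
(islands are spherical); the caudate tail; inter-subject anatomical
variability beyond island placement; partial-volume fractions below the
voxel grid (handled statistically by the count model instead). Passing
tests on this geometry show the pipeline recovers planted truth — they do
not certify tractography accuracy on real diffusion data.

### Streamline counts

`generate_counts()` gives each bait region an expected count of
`base_rate` at voxels of its favored compartment and `base_rate /
bias_odds` at the other compartment, blurs the expected rates with a
Gaussian of `partial_volume_sigma` mm (default 0.75 mm, ~0.6 voxel) to
mimic the mixing produced by a rigid voxel grid sampling sub-voxel
striosome branches, and draws Poisson (optionally negative-binomial)
counts. At `bias_odds = 9` and no mixing, the realized bias at pure voxels
is ~0.9, matching the strongly biased end of the empirical distributions.
One consequence worth knowing: at 2 mm mixing the mean bias over striosome
voxels falls *below* 0.5, because 85% of the neighborhood of a typical
striosome voxel is matrix. That is the partial-volume dilution the
equal-volume mask rule is designed to evade — the most-biased voxels are
island cores, which survive mixing.

### BOLD series

`generate_bold()` drives the planted functional architecture with one
latent time course per hemisphere: network-node voxels follow their
hemisphere's latent; striosome voxels couple to the ipsilateral latent and
matrix voxels to the contralateral latent (coupling amplitudes in `[0, 1)`,
default 0.6, which is the planted voxel-latent correlation), everything
else is white noise. Defaults follow the acquisition the analysis targets:
2,400 timepoints at TR 0.72 s. The generator does **not** model spatial
autocorrelation of the noise, physiological confounds, motion, or
hemodynamics; series are generated "pre-cleaned". A pass-through hook for
user-supplied confound regression is deliberately absent from the synthetic
path — real data should be residualised upstream.

### Covariates

Age ~ uniform integers 22-36 and sex ~ Bernoulli (58% female), mirroring a
young-adult cohort's composition. Covariates exist so the group model has
realistic nuisance variation; no covariate effect is planted.

## Parcellation choices

* **Bias definition** `P = S / (S + M)` — a probability-like quantity
  consistent with thresholds such as `P > 0.55` and `P > 0.87`; undefined
  (NA) where `S + M = 0`, and such voxels are excluded from selection and
  classification.
* **Equal-volume rule** — each mask holds `round(0.13 x hemisphere striatal
  volume)` voxels; 13% is the two-sided Gaussian mass beyond 1.5 SD
  (`gaussian_tail_fraction(1.5)` = 0.1336). The two-sided reading is
  adopted because it reproduces the printed 13% (one-sided would be 6.7%).
  The rule is applied per hemisphere. Masks are *exactly* equal and
  disjoint: striosome-like voxels are selected first, matrix-like selection
  excludes them; ties break by (bias desc, total count desc, voxel index
  asc), making masks reproducible bit-for-bit.
* **Classification cutoff** 0.55 (and 0.87 for the segregation analysis)
  with `P > cutoff` striosome-like, `1 - P > cutoff` matrix-like, the rest
  indeterminate. Cutoffs at or below 0.5 are rejected — the classes would
  overlap.

## Negative controls

`jitter_mask()` shifts every seed voxel independently by uniform integers
in ±`max_shift` (default 3) per axis, constrained to stay in the striatum,
to avoid both original compartment masks, and to avoid collisions
(rejection resampling in stable voxel order; when a voxel's entire feasible
set is occupied, an augmenting-path repair relocates an earlier voxel that
has alternatives, so cardinality is always preserved and the no-reselection
contract never breaks). Under these constraints the mask occupies the same
neighborhood — centroids move by well under a voxel — while per-voxel
positions change by ~3 voxels RMS.

`bundle_core()` reads "uppermost 25% of voxels" as a count-based quantile
of the *nonzero* voxels (the phrase counts voxels, not amplitude range).

## Group statistics

Difference maps `d = z_striosome - z_matrix` are fit voxel-wise against an
intercept plus mean-centered age and ±0.5-coded sex, so the intercept is
the covariate-adjusted paired contrast; its t (df = n - 3) is thresholded
at one-sided `p_unc` (default 0.001) and supra-threshold voxels are grouped
under 26-connectivity. Cluster-level FWE uses sign-flip permutation of the
subject difference maps — exact under exchangeability of the sign of `d`,
with no smoothness estimation — using cluster extent as the statistic:
`p_FWE = (1 + #{perm max extent >= observed}) / (1 + n_perm)`. Both
one-sided contrasts are tested separately at alpha 0.05, mirroring paired
directional maps. Random-field-theory inference is intentionally out of
scope.

A calibration caveat that the tests make explicit: extent-based inference
at a very strict cluster-forming threshold on a small grid of spatially
*independent* noise is far below the nominal error rate, because nearly
all suprathreshold voxels are singletons and the extent distribution is
massively tied. The calibration study therefore uses smooth null fields
(Gaussian sigma 1.5 voxels — BOLD difference maps are smooth) and a
cluster-forming `p_unc` of 0.01 on the 12^3 calibration grid, where the
extent statistic has a rich null distribution; there the measured
family-wise type-I rate is ~0.04-0.05 at alpha 0.05 over 200 null cohorts
of 20 subjects.

## N-1 somatotopy

Contribution maps are cohort averages: `Avg(P, all baits) - Avg(P, baits
minus region)`, stored signed toward striosome; a region's *own-class*
amplitude flips the sign for matrix-favoring regions. Winner-take-all
segmentation labels each voxel by the region with the largest own-class
amplitude (ties by bait order; label "none" where no region pulls toward
its own class). Refinement thresholds each coarse zone at the 50th
percentile of the region's maximum amplitude, adjusts to 50-100 voxels per
hemisphere (preferring the largest admissible size), and matches left/right
volumes within 3 voxels by trimming the larger side's lowest-amplitude
voxels; no cluster-forming is applied. Dispersion is summarized as the
FWHM volume (voxels above half the region's maximum amplitude).

Cohort averaging presupposes anatomical correspondence across subjects —
in real cohorts the template space provides it. Synthetic subjects with
independent random anatomies have none, so zone-level analyses in the
tests and the acceptance script use cohorts that share one anatomical
realization with independent count noise per subject.

The zone-bias ANOVA fits
`striosome fraction ~ class + class:region + hemisphere + subject`
(regions nested in class as the nuisance term) and reports the F test of
the compartment-class effect, plus a permutation calibration that reshuffles
the region-to-class assignment.

## Numerical and degenerate-input choices

* Fisher z clips |r| at `1 - 1e-7` (z ≈ 8.4) so self-correlated voxels stay
  finite; clip counts are reported.
* Zero-variance voxels, voxels outside the brain mask, and the whole
  striatum are NA in z maps.
* `dsc()` returns 0 (with a message) when both masks are empty.
* Degenerate t statistics (zero residual variance) are capped at ±1e6 and
  flagged; all-zero differences give t = 0.
* Coordinates: voxel indices are 0-based in the affine convention
  (`world = A [i j k 1]'`); all distances are world mm; hemispheres split
  at world x = 0, and exact-midline voxels count as ipsilateral in
  laterality reports (deterministic, and rare on even-sized grids).
* Plane bins are half-open `[y, y + 2)` mm anchored at y = 0; planes with
  striatal data for under half the cohort are dropped; Holm's step-down
  controls the per-family error over planes (configurable to Bonferroni
  via `p.adjust` semantics).
* Connectivity defaults to 26 (faces + edges + corners) everywhere,
  configurable to 18 or 6.

## Problem sizes used by the tests and acceptance script

Parameter-recovery runs use 10 subjects on the default 40 x 50 x 40 grid
with 400-timepoint BOLD series and 299-permutation contrasts; calibration
uses 200 null cohorts of 20 subjects on a 12^3 grid with 199 permutations;
oracle-equivalence checks run on grids up to 1,000 voxels and 5-voxel toys.
These sizes were chosen so the full validation remains comfortable on a
single CPU while keeping every Monte-Carlo margin far from its pass
threshold.

## Known limitations

* The synthetic anatomy is a geometric idealization; none of the published
  HCP-cohort numbers (centroid distances, cluster volumes, DSC values) are
  expected to be reproduced quantitatively, only their directions and the
  arithmetic among the published values.
* Tractography itself, fMRI preprocessing, registration/resampling and
  surface-based analysis are out of scope; all volumes in one run must
  share a grid and affine.
* The permutation engine assumes sign-exchangeable difference maps; strong
  covariate-by-effect interactions would violate it.
* Nucleus accumbens is not parcellated (no validated bait connectivity).
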