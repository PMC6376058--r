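---
title: "Reproducibility-driven radiomics feature selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproducibility-driven radiomics feature selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radstab)
```

## The problem

Radiomics pipelines extract large numbers of quantitative descriptors from
medical images, but a feature is only usable as a biomarker if it survives
the variability of the humans (or algorithms) that delineate the region of
interest. `radstab` implements a complete 2D multi-sequence MRI workflow
for this technical-validation question:

1. extract 85 features per ROI (per sequence, per delineation),
2. keep the features that are stable across repeated delineations
   (intra- and inter-observer),
3. collapse the survivors into redundancy clusters, per sequence and
   pooled across sequences, and
4. quantify how sensitive steps 2-3 are to the stability thresholds.

The intended design is a cohort of patients with two lacrimal glands each,
imaged on six sequences (T1, an ADC map derived from b0/b1000 diffusion
imaging, in-phase and water DIXON T2, and post-contrast in-phase and water
DIXON T1), with three delineation sessions per ROI: `L1` by reader 1 and
`L2.1`/`L2.2` by reader 2 three weeks apart. With 37 patients this gives
444 ROIs per reading session and 37,740 feature values per reading.

Because patient images cannot be redistributed, the package ships a
synthetic cohort generator that reproduces this design with known ground
truth, so every downstream stage is testable end to end.

## Feature extraction

**Discretization.** Intensities are discretized with a fixed bin width
(default 20 signal units) anchored at zero: `level = floor(x / 20) + 1`.
The number of grey levels is the maximum occupied level in the ROI — no
global cap. Absolute (fixed-bin-size) discretization keeps a given level
meaning the same intensity range in every ROI of a sequence. ADC maps are
carried in units of 1e-6 mm^2/s (tissue values ~500-2000) so the same bin
width is meaningful there; this rescaling is a package convention — the
interaction of absolute binning with physical ADC units is genuinely
underdetermined — and it is recorded in the extraction provenance.

**Families.** Per ROI the extractor computes 13 shape, 15 first-order,
26 GLCM, 13 GLSZM, 13 GLRLM and 5 NGTDM features (85 in total, fixed
schema, family-prefixed names). Conventions worth stating explicitly:

* Shape: pixel-edge perimeter; convex hull over pixel corners (so a
  digitised rectangle has solidity exactly 1); axis lengths from the
  second-central-moment ellipse (`4 * sqrt(eigenvalue)`); the geodesic
  diameter is the longest within-mask shortest path between boundary
  pixels over the 8-connected pixel graph with Euclidean step weights.
  Only shape features consume the pixel spacing; texture works in pixel
  units.
* First order: `Entropy` and `Uniformity` use the discretized histogram;
  everything else uses raw intensities; moments are population moments
  (divisor N, kurtosis not excess-corrected).
* GLCM: distance 1, four angles, counts summed over angles and
  symmetrised, then normalised (merged-matrix convention, recorded in
  provenance). `Homogeneity 1` is inverse difference and `Homogeneity 2`
  inverse difference moment, so `Homogeneity 2` coincides with the
  separately listed `IDM`; `Correlation 1`/`Variance 1` use the
  marginal-moment parameterisation and `Correlation 2`/`Variance 2` the
  joint-deviation parameterisation — for a symmetric merged matrix the
  two members of each pair are mathematically equal, and both columns are
  kept because the 26-name schema is frozen; `Sum Mean` is half of
  `Sum Average`; `Agreement` is the chance-corrected diagonal agreement
  (Cohen's kappa of the co-occurrence matrix against its marginals).
* GLRLM: runs along the four directions, matrices summed;
  `Run Percentage` divides the total run count by (4 directions x ROI
  pixels) so that an ROI of all-distinct levels attains exactly 1.
* GLSZM: zones are 8-connected components of equal level. Note that under
  8-connectivity a two-level checkerboard forms two zones, not singleton
  zones — singleton zones require all-distinct levels.
* NGTDM: neighbourhood means over the valid in-ROI 8-neighbours;
  `Coarseness` is capped at 1e6 for flat ROIs; single-level ROIs get
  `Busyness`/`Complexity`/`Strength`/`Contrast` of 0.

**Missing-value policy.** Degenerate computations (single-pixel ROI, flat
matrices, undefined correlations) yield `NA`, never silent zeros, and a
feature-sequence pair with any missing value can never be flagged
reproducible. This is deliberate: a feature that cannot be computed on
some ROI is not a usable biomarker for that sequence.

## Reproducibility selection

For each (feature, sequence), all ROIs are pooled as subjects and three
pairwise agreement coefficients are computed on the reading pairs
(L1, L2.1), (L1, L2.2), (L2.1, L2.2) with the two-way intraclass
correlation, absolute agreement, average measures (McGraw-Wong ICC(A,k),
k = 2):

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}$$

written out from the ANOVA mean squares, so no statistics package stands
behind the number. Lin's concordance correlation coefficient on the
intra-reader pair (L2.1, L2.2) completes the rule:

$$\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}$$

with population moments. A feature is reproducible on a sequence when all
three ICCs are at least 0.8 and the CCC is at least 0.9 (both tunable).
Negative ICCs are reported as computed; zero between-subject variance is
flagged missing. Left and right glands of one patient are pooled as
independent subjects — the within-patient correlation of gland features
is ignored, a deliberate simplification.

## Redundancy clustering

Reproducible features are clustered with agglomerative hierarchical
clustering on the distance `1 - rho` (Spearman rank correlation),
complete linkage, tree cut just below `1 - cutoff` (cutoff 0.9). Complete
linkage is the only linkage for which "grouped means every within-cluster
pair has rho > 0.9" holds exactly, and the package verifies that
invariant in its tests. Signed correlation is used — strongly
anti-correlated features are *not* merged, since redundancy is defined as
"correlation above 0.9" — with an `absolute = TRUE` switch for the other
convention. The observation vectors come from a single reference reading
(`L1`), so reader variance does not leak into the redundancy structure.
Items are put in lexicographic order before clustering and ties merge
deterministically, making results invariant to input order. Constant
columns (undefined rank correlation) are isolated as singletons.

Clustering runs per sequence and pooled: in the pooled run the items are
all reproducible (sequence, feature) pairs, which supports statements
about which sequences ever share a redundancy cluster
(`sequence_cooccurrence()`).

## Threshold sensitivity sweep

`threshold_sweep()` computes the ICC/CCC statistics once and re-applies
the selection rule on a grid of thresholds (default ICC in
{0.5, ..., 0.9}, CCC from 0.5 to 0.95 in steps of 0.05 — the CCC grid is
a package choice), counting selected features and redundancy clusters per
cell and sequence. Because thresholding a fixed statistic is a filter,
the feature count is non-increasing in each threshold by construction;
the cluster count is checked empirically and behaves the same way on
generated cohorts.

## The synthetic cohort generator

The generator emulates the study design, not MR physics. Per gland:

* **Anatomy.** An ellipse (semi-axes drawn from ranges spanning roughly a
  six-fold area range, within a 96 x 96 grid at 0.5 x 0.5 mm) deformed by
  a subject-specific smooth radial field (Fourier harmonics 2-6 of the
  polar angle, magnitude 3.5 px). The lobulation matters: without it all
  glands are convex and boundary-irregularity features (solidity,
  deficit, extension, eccentricity) have no between-subject variance, so
  their ICC is undefined in practice and the selection stage cannot be
  exercised realistically.
* **Texture.** A per-case anatomy Gaussian random field (white noise
  smoothed at correlation length 3 px) shared across sequences at 50% of
  variance, plus per-sequence independent fields, mapped through a
  per-sequence monotone affine contrast (realistic arbitrary-unit offsets
  and gains) with additive Gaussian noise, clipped at zero as magnitude
  images are.
* **Diffusion.** A ground-truth ADC field in [0.75, 1.75] x 1e-3 mm^2/s
  (`adc_mid + adc_amp * tanh(field)`), b0 synthesised from its own field,
  `S_b1000 = S_b0 * exp(-1000 * ADC)`, optional multiplicative noise.
  With noise off, `compute_adc()` inverts the generator to machine
  precision — an exact pipeline test.
* **Readers.** Each delineation is the truth (or reader 2's base contour)
  passed through two error channels: a smooth random radial boundary
  deformation (harmonics 1-3, variance weights 0.8/0.12/0.08, magnitude
  in pixels) and an integer in-plane translation of the whole contour
  (contour placement offset). The translation changes which pixels are
  sampled — degrading intensity and texture agreement — while leaving the
  mask's own geometry exactly unchanged; it is the generator's stand-in
  for slice-choice and centring disagreement, which in the real protocol
  changes the sampled pixels without much changing the reported gland
  shape. Reader 1 (`L1`) and reader 2's base each perturb the truth at
  the inter-reader magnitudes; `L2.1` and `L2.2` add independent
  intra-reader perturbations (smaller by construction, enforced by the
  spec validator) on top of reader 2's shared base, giving the intra <
  inter variability hierarchy. DIXON in-phase/water pairs share their
  delineations (same acquisition geometry); T1, the diffusion pair and
  the two DIXON pairs are delineated independently.

Defaults: inter-reader deformation 1.5 px + shift 2 px; intra-reader
deformation 0.5 px + shift 0.5 px. With all four magnitudes at zero the
three readings are identical and every non-degenerate feature must come
out with ICC = CCC = 1 — the identity limit used as an acceptance check.

**What the generator does not emulate:** MR artifacts (bias fields,
motion, chemical shift), pathology classes, genuine 3D anatomy and
through-plane slice geometry, scanner and protocol variation, and the
heavy-tailed ROI-size distribution of real lesions. Passing recovery
tests on this cohort therefore demonstrates that the pipeline's
statistics behave correctly under a known reader-variability model — not
that any particular real sequence yields any particular number of
reproducible features.

## Numerical choices and degenerate inputs

* Texture matrices are built on the ROI bounding box; features are
  invariant to the surrounding grid.
* The dendrogram cut height is `(1 - cutoff) - 1e-9`, so pairs at exactly
  the cutoff correlation are *not* merged ("above 0.9" is strict).
* `perturb_mask()` keeps the largest 8-connected component, retries with
  halved magnitude if the mask would empty, and errors after five
  retries; magnitude 0 is the identity.
* ICC denominators of zero and constant inputs yield `NA`; single-pixel
  ROIs flag moment and texture features as `NA`.
* Feature tables are written at 17 significant digits so CSV round trips
  are exact, including `NaN` flags.

## Problem sizes used in the tests

The unit tests run on cohorts of 1-6 patients (seconds each). The
acceptance suite additionally runs the full 37-patient design once for
the yield check (444 ROIs for one reading, 37,740 values) and uses
10-patient cohorts on 128 px grids for the stochastic recovery checks,
with one sequence's contrast overridden to be noise-dominated
(negligible texture gain under heavy pixel noise) — the regime in which
texture agreement is driven purely by mask overlap and the shape-vs-
texture selection ordering is expected. These sizes give
stable Monte-Carlo behaviour at a few minutes of runtime while keeping
the whole suite comfortably reproducible on a single CPU.
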