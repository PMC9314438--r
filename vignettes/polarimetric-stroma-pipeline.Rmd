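---
title: "Quantifying tumour stroma with rotating crossed-polarizer microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumour stroma with rotating crossed-polarizer microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polaristroma)
```

## The measurement and its model

Collagen is birefringent; most other soft-tissue components are not. Placed
between crossed linear polarizers, a thin unstained histology section
transmits light only where ordered structures rotate its polarization, so
collagenous stroma appears bright on a dark background. Rotating the
crossed-polarizer pair through 90 degrees in 5-degree steps yields an
18-frame stack in which every pixel traces the angular response

$$ y(\theta) \;=\; A\,\sin^2\!\big(2(\theta-\varphi)\big) + c, $$

where $A$ is the birefringent signal amplitude, $\varphi$ encodes the
in-plane fiber orientation, and $c$ is the dark leak of the polarizer pair.
The signal has a 90-degree period, so orientations are equivalence classes
modulo 90 degrees. From one stack the package derives three parametric
images whose values do not depend on how the polarizers happened to be
oriented relative to the tissue:

* **Intensity** (`intensity_image`) — the sample standard deviation of each
  pixel across the $Z = 18$ frames (divisor $Z-1$). A non-modulating pixel
  scores exactly 0; the map scales linearly with brightness. For the pure
  $\sin^2(2\theta)$ profile the value is exactly $\sqrt{2.25/17}$, which the
  test suite pins down via the harmonic sums of the model.
* **Alignment** (`alignment_image`) — at each pixel the polarizer angle of
  maximum signal is noted (`orientation_image`; ties resolve to the
  smallest angle), then a sliding window (default $5\times5$ px, about
  $4\,\mu m \times 4\,\mu m$ at $0.8\,\mu m$/px) averages the wrapped
  absolute angular difference $d(a,b)=\min(|a-b|,\,90-|a-b|)$ over all
  unordered pixel pairs. Aligned fiber bundles score low, disordered stroma
  scores high; the maximum attainable mean is 45 degrees.
* **Abundance** (`abundance_image`) — each pixel's modulation is fitted to
  the sinusoid-squared family. Via $\sin^2(2(\theta-\varphi)) =
  \tfrac12 - \tfrac12\cos(4\theta - 4\varphi)$ the family is exactly the
  linear harmonic model $a_0 + a_1\cos 4\theta + a_2\sin 4\theta$, so the
  fit is closed-form least squares — deterministic, with no optimizer
  settings to tune. The goodness of fit $R^2$ is amplitude-independent:
  weakly and strongly birefringent collagen both score near 1. Pixels with
  $R^2 > 0.75$ are counted as collagen.

### Numerical choices

* The angular-difference computation wraps at 90 degrees. Signed
  differences would average toward zero and contradict the interpretation
  of the statistic as dispersion; the wrap treats orientations as the
  equivalence classes the physics dictates.
* The intensity formula uses the sample divisor $Z-1 = 17$.
* $R^2$ is clamped to $[0,1]$ (an unstructured pixel can produce a
  negative raw score) and defined as 0 where the modulation variance is
  exactly zero, so the detection threshold always acts on a bounded score.
* The harmonic fit includes the constant offset term. The offset absorbs
  the dark leak; omitting it would spuriously depress $R^2$ on bright
  backgrounds.
* Alignment values are computed only where the full window fits inside the
  image (`valid_mask`); downstream ROI medians and texture features crop to
  valid pixels rather than padding. ROIs (about 250 px square) are far
  larger than the window, so the lost border is negligible.
* The peak-signal angle uses the discrete 18-angle argmax rather than the
  fitted phase, with ties to the smallest angle. The orientation map
  therefore has 5-degree resolution, which is sufficient because only
  pairwise differences of neighbouring pixels enter the analysis.

## From images to an 18-feature ROI description

Each pathologist-style region of interest (a pixel rectangle, 0-based and
half-open; 250 px $\approx$ 200 $\mu m$ at the default pixel size)
contributes:

1. three polarimetric summaries — median intensity, median alignment (valid
   pixels only), and the abundance ratio (fraction of ROI pixels above the
   $R^2$ threshold);
2. five Haralick co-occurrence features (contrast, correlation, energy,
   homogeneity, entropy) on each of the three parametric images, for 15
   texture features.

The co-occurrence analysis quantizes the ROI patch to 8 gray levels over
the patch's own min–max range, builds symmetric, normalized GLCMs at unit
pixel offset in the four directions 0, 45, 90 and 135 degrees, and averages
the five features over directions to remove the remaining anisotropy.
Choices worth noting:

* Quantization is per-ROI rather than against a global intensity range.
  This makes the texture features invariant to affine rescaling of the
  parametric image, which is desirable because the intensity image has
  arbitrary brightness units.
* Entropy is reported in bits; homogeneity uses the inverse-difference
  form $\sum_{ij} p_{ij}/(1+|i-j|)$. Any fixed entropy base or homogeneity
  variant is absorbed by the z-scoring below, so downstream clustering is
  unaffected by these conventions.
* Correlation of a texture-free (single-level) patch is defined as 0
  rather than NaN so degenerate ROIs cannot poison the feature table.

## Normalization, clustering, and patient-level aggregation

The 18 features live on wildly different scales and are skewed, so the
cohort table is normalized in two steps (`fit_normalizer`): a logarithm,
then a per-feature z-score. Features that reach zero or negative values
(GLCM correlation legitimately can) are shifted by $s = 1 - \min x$ first,
which maps the minimum to $\log 1 = 0$ and preserves order. The fitted
shift/mean/SD are retained so that any later vector — in particular a
patient's averaged feature vector — is mapped into exactly the same space
(`apply_normalizer`).

Three unsupervised models with $k=2$ are fit on the normalized ROI rows:
K-means (Lloyd iterations from k-means++ seeds, best of 20 restarts by
within-cluster SSE), Fuzzy C-means (fuzzifier $m=2$, the conventional
default; best of 20 restarts), and a full-covariance Gaussian mixture.
Labels are canonicalized so that **Cluster 1 is the larger cluster** (ties
broken toward the lower centroid norm); this pins the survivor-enriched
majority group to a fixed label so reports are comparable across models
and seeds. The mixture model uses deterministic model-based initialization,
so its restart count is a no-op; a regularizing prior is applied only if
the unconstrained fit is singular.

ROI labels are collapsed to one cluster per patient by two rules:

* **Majority vote** — a strict majority of ROI labels wins, however slim;
  a patient with an even ROI count split exactly 50–50 is left
  *unassigned* and excluded from the association statistics (their count
  is reported).
* **Feature averaging** — the patient's normalized ROI vectors are
  averaged into one patient-representing vector, which the fitted model
  then classifies (nearest centroid, membership formula, or posterior).
  Every patient receives a label; exact ties are resolved by where the
  average falls. Averaging is done in normalized space because that is the
  space the fitted models live in.

## Association with survival

Patient clusters are cross-tabulated against 5-year survival with the cell
convention $a$ = non-survivors in Cluster 2, $b$ = non-survivors in
Cluster 1, $c$ = survivors in Cluster 2, $d$ = survivors in Cluster 1 —
i.e. Cluster 2 is read as a positive (non-survival) prediction.
`fisher_two_tailed` computes the exact two-sided p-value (summing all
tables with the observed margins that are no more probable than the
observed one), `diagnostics` the five screening metrics with explicit
undefined flags on zero denominators, and `odds_ratio` $ad/bc$ with a
Woolf log-method 95% interval. No continuity correction is applied: a zero
cell yields an honestly incalculable odds ratio rather than a corrected
one. `crc_reference_tables()` ships the six reconstructed
cluster-vs-survival tables of a 32-patient stage III colorectal-cancer
reference cohort (23 survivors, 9 non-survivors), and the acceptance
script recomputes every statistic from them at run time.

```{r}
t <- crc_reference_tables()$gmm_majority
t
fisher_two_tailed(t)$p
odds_ratio(crc_reference_tables()$kmeans_average)$or
```

## What the synthetic data emulates — and what it does not

No patient images ship with the package; every downstream stage is instead
exercised on two synthetic generators with known ground truth.

**Fiber phantoms** (`phantom_spec`/`generate_stack`) render anti-aliased
straight fibers with von Mises-distributed orientations (on the doubled,
90-degree-periodic circle), uniform amplitudes in a configurable range,
and a dark offset, then evaluate the sinusoid-squared model at the 18
acquisition angles. Optional ingredients mimic the two dominant
instrument effects: a smooth multiplicative flood-field gain (mean
exactly 1) and additive Gaussian noise clipped at zero, because detectors
report nonnegative counts. Where fibers overlap, the stronger fiber wins
both amplitude and orientation, keeping the ground truth single-valued.
Fibers are added until a target coverage fraction is reached, so planted
coverage is directly comparable with the recovered abundance ratio.

**Feature cohorts** (`cohort_spec`/`generate_cohort`) skip the imaging
stage and plant two-class structure directly in the 18-dimensional raw
feature space: 32 patients, 3–14 ROIs each, about 72% of patients in the
survivor-enriched class, ROI classes flipped from their patient's with
probability 0.1 (real patients show mixed ROI labels), and survival drawn
at 0.9 versus 0.3 by class. The default class means differ by 4 SD in
every feature — clearly resolvable planted structure, chosen so that an
end-to-end failure indicates a pipeline defect rather than statistical
ambiguity. The second feature's means are negative to exercise the
log-shift path of the normalizer.

The phantoms are deliberately not optically realistic: no Mueller-matrix
physics, no wavelength dependence, no scattering, no spatially varying
retardance within a fiber. Likewise the cohort generator plants Gaussian,
feature-independent classes, which real stromal features are not. Passing
tests therefore demonstrate that the estimators recover what the model
says they should recover (correctness), not that the biomarkers separate
real patients (validity) — the latter needs real cohorts.

## Problem sizes and reproducibility

The bundled checks run phantoms up to $512\times512$ px and cohorts of
about 300 ROIs — the scale at which the estimators' sampling behaviour is
already stable — and derive every random draw from one root seed per run;
`run_pipeline` writes a manifest (seed, constants, sizes, package version)
sufficient to replay a run exactly. Fixed seeds give bit-identical stacks,
cohorts, feature tables and reports.

## Known limitations

* The orientation map is quantized to the 5-degree acquisition grid;
  sub-degree orientation estimation is out of scope.
* Fuzzy C-means with $m=2$ biases boundary assignments toward
  equal-sized clusters when classes are unbalanced and weakly separated;
  with planted structure this is invisible, but on borderline real data
  the three models can legitimately disagree.
* A full-covariance mixture in 18 dimensions estimates many covariance
  parameters from few ROIs; on small cohorts its solution is more
  variable than K-means'.
* The majority-vote rule discards exactly-tied patients by design; the
  feature-average rule never does, which is why their denominators differ.
* Flood-field correction assumes the reference stack shares the sample
  stack's illumination exactly and is strictly positive.
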