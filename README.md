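# polaristroma

Quantitative stromal biomarkers from rotating crossed-polarizer light
microscopy, for researchers studying the prognostic value of peri-tumoral
collagen architecture (e.g. the desmoplastic response in colorectal
cancer) on unstained histology slides.

## What it computes

A thin unstained section between crossed linear polarizers is imaged 18
times while the polarizer pair rotates 0°–85° in 5° steps. Every pixel of
the stack follows the birefringence model

    y(θ) = A · sin²(2(θ − φ)) + c,

with amplitude `A`, fiber orientation `φ` (period 90°) and dark leak `c`.
From one stack the package derives three geometry-independent parametric
images:

| image | definition | meaning |
|---|---|---|
| intensity | per-pixel SD of `y` across the 18 angles (divisor Z−1) | birefringence (collagen) signal strength |
| alignment | windowed (5×5) mean pairwise wrapped angular difference of peak-signal angles, `d(a,b) = min(\|a−b\|, 90−\|a−b\|)` | fiber disorder: low = aligned, high = disordered |
| abundance | R² of the closed-form harmonic fit `a₀ + a₁cos4θ + a₂sin4θ`, thresholded at R² > 0.75 | amplitude-independent collagen detector |

Each region of interest is then summarised by 18 features (median
intensity, median alignment, abundance ratio, plus 5 direction-averaged
Haralick texture features — contrast, correlation, energy, homogeneity,
entropy — on each of the three images), log/z-score normalized, clustered
with K-means, Fuzzy C-means and a Gaussian mixture (k = 2), aggregated to
patients by majority vote or feature averaging, and tested for association
with 5-year survival via two-tailed Fisher's exact tests, diagnostic
metrics, and odds ratios with Woolf 95% intervals.

Synthetic generators with full ground truth (fiber phantoms rendered under
the same sinusoid-squared model; feature cohorts with planted two-class
structure) make the entire pipeline testable without patient data. See the
vignette in `vignettes/polarimetric-stroma-pipeline.Rmd` for the methods
account.

## Worked example

```r
library(polaristroma)

# render a phantom stack and derive ROI features
ph   <- generate_stack(phantom_spec(width = 96, height = 96,
                                    coverage_fraction = 0.4,
                                    fiber_orientation_concentration = 8,
                                    seed = 42))
imgs <- parametric_images(ph$stack)
round(roi_features(imgs, list(x = 16, y = 16, width = 64, height = 64))[1:3], 4)
#> median_intensity median_alignment  abundance_ratio
#>           0.0113          19.8000           0.4070
```

The ROI's median birefringence is 0.0113 (arbitrary brightness units), the
median local fiber dispersion is 19.8° (moderately aligned; 0° would be
perfectly parallel fibers, 45° fully disordered), and 40.7% of ROI pixels
pass the collagen detector — close to the planted 40% fiber coverage.

```r
# full cohort pipeline on a synthetic 32-patient cohort
rep <- run_pipeline(pipeline_config(seed = 42, cohort = cohort_spec(seed = 42)))
rep$summary[, c("model", "method", "n", "accuracy", "npv", "fisher_p")]
#>    model          method  n accuracy   npv fisher_p
#> 1 kmeans   majority_vote 32    0.875 0.941 2.94e-05
#> 2 kmeans feature_average 32    0.875 0.941 2.94e-05
#> 3    fcm   majority_vote 32    0.875 0.941 2.94e-05
#> 4    fcm feature_average 32    0.875 0.941 2.94e-05
#> 5    gmm   majority_vote 32    0.875 0.941 2.94e-05
#> 6    gmm feature_average 32    0.844 0.889 1.90e-04
```

All three models recover the planted clusters; cluster membership is
strongly associated with the planted survival labels (Fisher p ≪ 0.05),
and the high negative predictive values say that Cluster 1 (the larger,
survivor-enriched cluster by convention) indeed collects the survivors.

```r
# association statistics for a reference cohort table
t <- crc_reference_tables()$fcm_average
t
#> <2x2> non-surv: C2=8 C1=1 | surv: C2=6 C1=17 (N=32)
fisher_two_tailed(t)$p   #> 0.003731924
odds_ratio(t)$or         #> 22.66667
```

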