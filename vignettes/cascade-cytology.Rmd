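---
title: "Nuclear morphometry and two-level cascade classification: methods"
author: "cytocascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear morphometry and two-level cascade classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocascade)
```

## The problem and the pipeline

Cervical cytology specimens contain a mixture of epithelial cells (the
diagnostic target), lymphocytes, neutrophils and non-diagnostic junk
(debris, contaminants, overlapping clumps). Classifying all five groups
with one flat classifier forces a single model to both filter
contaminants and make the subtle normal/abnormal call. The cascade
design splits the task: a fast tree first routes every nucleus to one of
four coarse classes, then a probabilistic model specialised on the
epithelial subset makes the normal-vs-abnormal call. When the stages err
independently with correct rates $c_1$ and $c_2$, the composed rate of
the cascade is the product $c_1 c_2$ (the additive form occasionally
seen for stage-rate bookkeeping can exceed 1 and is provided only as an
option in `composeRates()`).

The pipeline is: preprocess → threshold → segment → extract 28 features
→ classify → evaluate. Each stage is an exported function; `runPipeline()`
wires them together.

## Imaging assumptions and parameters

The input is a single-channel 8-bit image in which nuclei are
*stain-dark on a light background*, as produced by DNA-stoichiometric
stains. All operations assume integer intensities in $[0,255]$ and
(row, col) coordinates with row increasing downward.

* **Detail-preserving equalization** (`equalizeWithDetail()`,
  `detailRadius = 3` px). The base layer is a median blur of window
  $2r+1$; global histogram equalization is applied to the base and the
  detail residual (input − base) added back, clipped to $[0,255]$. The
  additive base/detail split is the simplest decomposition that lets
  global contrast stretching coexist with preserved local extrema
  (chromatin granules, nuclear rims). Equalization is **off by default**
  in `pipelineConfig()`: it exists for unevenly stained or poorly
  exposed material, and on well-exposed images it remaps each image's
  intensity scale independently, which destroys the cross-image
  comparability of the intensity features (`Mean`, `Deviation`).
* **Median denoising** (`medianDenoise()`, `window = 3`). Replicate
  padding keeps the output the same size; the filter is the standard
  salt-and-pepper suppressor that preserves edges. Window 3 removes
  single-pixel noise without eroding small lobes.
* **Adaptive threshold** (`adaptiveThreshold()`). The 256-bin histogram
  is smoothed with a moving average of width 5; peaks are local maxima
  with prominence at least 1 % of the pixel count; the cutoff is the
  minimum bin strictly between the two tallest peaks, ties broken toward
  the lower intensity. Two guards make this robust: the two selected
  peaks must be at least 16 gray levels apart (sampling noise can
  produce two near-equal local maxima a few bins apart inside a single
  mode, and no real nucleus/background pair is that close), and if
  fewer than two qualifying peaks exist the exhaustive
  between-class-variance (Otsu) scan is used instead. A constant image
  returns its own value — a documented degenerate case.
* **Segmentation** (`segmentNuclei()`, `minArea = 50` px). Pixels at or
  below the threshold form the foreground (`polarity = "light"`
  inverts); 8-connected components smaller than `minArea` are dropped as
  debris. Touching nuclei are *not* split — overlapping clumps are the
  junk class by definition. Each region carries a clockwise Moore-traced
  closed contour started at the topmost-then-leftmost boundary pixel,
  so every contour is deterministic and 8-connected.

## The 28 features

Twenty morphologic features are computed from the mask and contour, and
eight texture features from the intensities under the mask. Three
design choices deserve explanation:

* **Contour-distance statistics.** `Distance` and `Sigma` are the mean
  and *population* standard deviation of the Euclidean distances from
  contour points to the centroid (the mean of mask coordinates). They
  feed `Roundness = 1 − Sigma/Distance` and the equivalent-polygon side
  count `Sides = 1.4111 (Distance/Sigma)^{0.4724}`; a perfect circle has
  `Sigma = 0` and `Sides = Inf` (returned as a sentinel, not an error).
* **Two circle scores.** `Compactness = P^2/(4\pi A)` is the classical
  isoperimetric quotient computed from the chain-code perimeter
  (diagonal steps count $\sqrt2$). `Circularity = A/(\pi\,d_{max}^2)`,
  with $d_{max}$ the largest contour-to-centroid distance, is a
  bounded circle-similarity score that punishes single protrusions more
  than boundary roughness. Both are kept because they respond to
  different deformations.
* **Moments and the equivalent ellipse.** `M20`, `M02`, `M11` are
  *geometric* central second moments of the pixel coordinates (x =
  column): intensity-weighted variants would conflate shape with
  staining, and only the geometric form guarantees the trace identity
  $I_a + I_b = M_{20} + M_{02}$ used as a standing invariant. The
  principal values $I_{a,b} = h \pm \sqrt{h^2 - M_{20}M_{02} +
  M_{11}^2}$ are the eigenvalues of the second-moment matrix; tiny
  negative discriminants from floating point are clamped to zero. The
  ellipse with the same moments and area has semi-axes
  $R_a = 2\sqrt{I_a/A}$, $R_b = 2\sqrt{I_b/A}$ — the factor 2 is fixed
  by requiring a perfect ellipse to report `Bulkiness`
  $= \pi R_a R_b / A = 1$ — giving `Anisometry` $= R_a/R_b =
  \sqrt{I_a/I_b}$ and the exact identity `StructureFactor` $=$
  `Anisometry`·`Bulkiness` $− 1$.
* **Convexity and Rectangularity** use the convex hull of the *pixel
  corners* (each pixel contributes its four unit-square corners), not
  the pixel centers: the center hull underestimates the covered area by
  half a boundary pixel all around, which would push a perfect
  rectangle's convexity to ~0.90 at typical nucleus sizes. The minimum
  enclosing rectangle comes from rotating calipers on that hull and the
  enclosing circle from an exact incremental smallest-circle
  construction on the contour hull.

Texture uses a gray-level co-occurrence matrix with **32 levels over the
region's own [min, max] range**, accumulated symmetrically over the four
unit offsets (0°, 45°, 90°, 135°) — the conventional distance-1,
orientation-pooled setting, exposed in `buildGLCM()`. Quantizing over
the region's own range makes Contrast and Energy invariant to adding a
constant to all intensities. Energy, Contrast, Homogeneity, Correlation
and Entropy (base-2 logs, zero cells contribute nothing) are the
standard co-occurrence descriptors; Correlation of a constant region is
defined as 1 with a warning. `Anisotropy` is a **reconstruction**: the
original formula behind this feature name is not recoverable, so the
package defines it as $-k^*/L$ where $k^*$ is the smallest quantized
level at which the cumulative histogram entropy reaches half its total
— near $-0.5$ for symmetric histograms, more negative for
bottom-heavy ones. It should not be compared against externally
published Anisotropy values. `Mean` and `Deviation` use the raw 8-bit
intensities, not the quantized levels.

## The cascade

* **Level 1** (`trainTree()`): binary threshold splits on continuous
  features, chosen by information gain ratio with candidate thresholds
  at midpoints of consecutive distinct sorted values; stopping at
  `minLeaf = 5`, `maxDepth = 12`, or zero gain; no post-pruning. Gain
  ratio rather than raw gain is the defining C4.5 ingredient — it
  normalises the gain by the split's intrinsic information. Ties are
  broken toward the lower feature index, then the lower threshold, so
  training is fully deterministic.
* **Level 2** (`trainLogistic()`): ridge-penalized logistic regression
  (`lambda = 1e-4` on internally standardized features, intercept
  unpenalized) fitted by IRLS with step halving to penalized gradient
  norm `1e-8` (max 100 iterations; non-convergence warns and returns
  the best iterate). The small penalty exists to keep weights finite on
  separable data — with well-separated classes an unpenalized fit
  diverges. The decision threshold is 0.5 with **ties going to
  abnormal**: in a screening context a missed abnormal cell costs more
  than a false alarm, and the threshold is exposed in the config for
  sites that want higher sensitivity still.
* **Training protocol**: stratified 70/30 split with a fixed seed
  (`pipelineConfig(trainFraction = 0.7, seed = 1)`). All reported rates
  are held-out rates.

## The synthetic generator

`generateDataset()` emulates what the feature extractor needs to see —
not what a microscope sees. Each cell is an ellipse with a seeded radial
boundary perturbation $r(\theta) = R\,(1 + a \sum_{k=2}^{6} c_k
\cos(k\theta + \varphi_k))$ (unit-norm coefficients, radius clamped at
$0.25R$), filled with Gaussian intensities on a light noisy background
(230 ± 8); neutrophils are unions of 2–3 overlapping ellipse lobes and
junk uses a high perturbation amplitude. The class recipes fix the
inter-class *ordering* of area (neutrophil ≈ 342 < lymphoid ≈ 403 <
normal epithelial ≈ 538 < junk ≈ 972 < abnormal epithelial ≈ 2455 px²),
staining (lymphoid darkest at ≈ 80), boundary regularity (junk worst)
and chromatin granularity (abnormal coarsest); the area and intensity
centers follow published class-typical magnitudes for stained cervical
material, with spreads (area sd ≈ 14 % of the mean, cell-mean intensity
sd 6–10 gray levels) chosen once as plausible biological variability.
1 px = 1 unit throughout; physical μm scaling is available via
`umPerPx` but synthetic areas are unitless.

What the generator does **not** emulate: overlapping-cell clumps beyond
the junk class, cytoplasm, uneven illumination, focus blur, staining
batch effects, and the long tails of real morphology. Passing the
synthetic performance floors (test suite: 5-way cascade accuracy ≥
0.90, abnormal recall ≥ 0.90, level-2 AUC ≥ 0.95 at 200 cells/class)
therefore demonstrates that the pipeline is wired correctly and that
the features separate well-separated classes — it is *not* evidence of
clinical-grade performance on real slides, where published systems of
this design report mid-90 % rates on curated data.

## Numerical choices and degenerate inputs

* Histogram equalization of a single-level image is the identity.
* A single-pixel region has a one-point contour; contour statistics
  require ≥ 3 points and error otherwise.
* `sides()` returns `Inf` (not an error) for `Sigma = 0`.
* GLCM construction errors when no intra-mask pixel pair exists.
* AUC uses trapezoids over threshold groups, equivalent to Mann-Whitney
  counting with half credit for ties; undefined precision/recall
  (empty prediction column) yields `NA` with a warning rather than 0.
* The chain-code perimeter ($1/\sqrt2$ steps) carries an
  orientation-dependent bias of a few percent on small shapes, so
  perimeter-derived features (Compactness) are rotation-stable to ~3 %
  only for areas ≳ 1000 px²; the 90°-rotation case is exact.
* Problem sizes in the test suite — 200 cells/class for the cascade
  floors, ≤ 10×10 fixtures for the brute-force oracles, 100 seeded
  mixtures for the threshold property — were chosen so the whole suite
  exercises every stage at statistically meaningful sizes while
  remaining quick to run on a laptop.

## Known limitations

Touching nuclei are never split; color and multichannel input are
reduced to luminance; the Anisotropy feature is a package-defined
reconstruction; the flat-baseline comparison shares the cascade's
feature set and split, so it measures the value of the cascade
*structure*, not of the features; and all performance statements in
this package are about the synthetic testbed, not clinical material.
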