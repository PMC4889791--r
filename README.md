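# cytocascade

Automatic detection of abnormal cervical epithelial cells in stained
cytology images.

Cervical-cancer screening by liquid-based cytology (LBC) asks a reviewer
to find rare abnormal epithelial cells among thousands of normal
epithelial cells, lymphocytes, neutrophils and debris. `cytocascade`
implements the image-analysis side of that task for 8-bit grayscale
crops of Feulgen-thionin-stained slides, where nuclei appear stain-dark
on a light background: it segments nuclei, measures 28 nuclear features,
and classifies each nucleus with a two-level cascade. It is aimed at
researchers in quantitative cytology and biomedical image analysis who
want a transparent, fully scripted reference pipeline rather than a
black box.

## Method

**Segmentation.** Images are enhanced by detail-preserving histogram
equalization (a median-blur base layer is equalized globally and the
detail residual added back) and denoised with a median filter. The
nucleus/background cutoff is the valley between the two dominant peaks
of the smoothed intensity histogram, falling back to the
between-class-variance (Otsu) optimum; stain-dark pixels are grouped
into 8-connected components and each component's closed boundary is
traced (Moore tracing).

**Features.** Every nucleus yields 20 morphologic and 8 texture
features. The morphologic core, with `Distance` and `Sigma` the mean and
standard deviation of contour-to-centroid distances, `P` the contour
length and `A` the area:

    Roundness   = 1 − Sigma / Distance
    Sides       = 1.4111 · (Distance / Sigma)^0.4724
    Compactness = P² / (4π·A)
    I_a, I_b    = h ± √(h² − M20·M02 + M11²),   h = (M20 + M02)/2

where `M20`, `M02`, `M11` are central second moments of the pixel
coordinates and `I_a ≥ I_b` their principal values. Equivalent-ellipse
semi-axes `R_a = 2√(I_a/A)`, `R_b = 2√(I_b/A)` give `Anisometry =
R_a/R_b`, `Bulkiness = π·R_a·R_b/A` and `StructureFactor = Anisometry ·
Bulkiness − 1`. Texture combines first-order statistics (`Mean`,
`Deviation`) with gray-level co-occurrence matrix descriptors (Energy,
Correlation, Homogeneity, Contrast, Entropy, plus a histogram-entropy
Anisotropy score) at 32 quantization levels over four unit offsets.

**Cascade classification.** Level 1 is a C4.5-style decision tree
(binary threshold splits chosen by information gain ratio) separating
epithelial / lymphoid / neutrophil / junk. Epithelial nuclei are
forwarded to level 2, an L2-penalized logistic regression fitted by
IRLS, which calls normal vs abnormal. With per-level correct rates `c1`
and `c2`, the composed cascade rate is the product `c1·c2`: stage rates
of 0.97185 and 0.9858 compose to an overall 95.805 %.

Because no public image set accompanies the method, the package includes
a seeded synthetic generator (`generateDataset()`) producing the five
cell classes with class-conditional nuclear area, shape regularity and
staining statistics in the characteristic inter-class order, plus
ground-truth masks, so the whole pipeline is testable end to end.

## Worked example

```r
library(cytocascade)

scenes <- generateDataset(50, seed = 42)      # 250 cells, 5 classes
res    <- runPipeline(scenes, pipelineConfig(seed = 42))
print(res$report)
```

```
Two-level cascade evaluation
  level 1 (rough, 4-class) accuracy: 100.000%
  level 2 (normal/abnormal) accuracy: 100.000%  AUC: 1.000
  composed stage rate (product):     100.000%
  cascade end-to-end 5-way accuracy: 100.000%
  abnormal-epithelial recall:        100.000%
  flat 5-class baseline accuracy:     97.333%
```

The report reads: on the held-out 30 % of nuclei, the level-1 tree
routed every nucleus to the right coarse class, the level-2 logistic
model separated normal from abnormal epithelial nuclei perfectly
(AUC 1.0 over its decision thresholds), and the product of the two stage
rates — the cascade's composed accuracy — matches the end-to-end 5-way
accuracy. The flat baseline is a single 5-class tree on the same
features; the cascade's margin over it is the point of the two-level
design. Individual feature rows look like:

```r
round(unlist(res$features[1, c("Area","Roundness","Sides","Anisometry","Mean","Contrast")]), 3)
#       Area  Roundness      Sides Anisometry       Mean   Contrast
#    326.000      0.964      6.757      1.041     82.850     24.656
```

— a small, round, dark nucleus: a lymphocyte.

A thin command-line wrapper over the same functions is installed at
`inst/cli/cytocascade.R` with subcommands `simulate`, `preprocess`,
`segment`, `features`, `train`, `predict` and `pipeline`, configured by
a YAML file plus flag overrides.

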