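---
title: "Self-learning Bayesian detection of clustered microcalcifications"
author: "mcdetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-learning Bayesian detection of clustered microcalcifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clustered microcalcifications (MCs) — calcium deposits of roughly 0.1–1 mm —
are among the earliest mammographic signs of breast cancer. On a digitized
film mammogram (mini-MIAS convention: 1024 × 1024 pixels at 200 µm/pixel)
an individual MC spans only about 1–5 pixels, and its contrast against the
surrounding tissue depends strongly on breast composition: dense-glandular
tissue is brighter and more variable than fatty tissue, and hides MCs more
effectively. Clinically, a *cluster* is three or more calcifications within
a 1 cm² area (a 50 × 50 pixel block at 200 µm/pixel); isolated spots are of
far less concern.

`mcdetect` segments a mammogram into MC versus healthy-tissue pixels in a
single stage, using a Gaussian Bayesian (quadratic discriminant) classifier
whose training data come *from the input image itself* — the self-learning
idea at the core of the package.

## The classifier

Each pixel is described by a four-component pattern vector
$x = [x_1, x_2, x_3, x_4]^T$:

* $x_1$ — graylevel. MCs are brighter than their surround.
* $x_2$ — local-maximum rank: the fraction of the 9 × 9 neighborhood that
  is strictly darker than the center, in $[0, 1]$. It is 1 exactly at a
  strict local maximum and is invariant to monotone intensity remappings.
* $x_3$ — wavelet highpass: the image is decomposed with a separable
  2-level db4 DWT, the deepest approximation subband is zeroed, and the
  detail subbands are reconstructed. Smooth tissue, which lives in the
  approximation, is suppressed; point anomalies survive. The value is the
  signed reconstruction.
* $x_4$ — ED₈ point singularity: the sum of absolute graylevel differences
  between a pixel and its 8 neighbors. Flat regions give 0; an isolated
  bright pixel of height $h$ gives $8h$.

Assuming each class $\omega_j$ (MC vs. healthy) is Gaussian in feature
space with mean $m_j$ and covariance $C_j$, and taking equal priors, the
log-posterior reduces to

$$ d_j(x) = -\tfrac12 \ln |C_j| - \tfrac12 (x - m_j)^T C_j^{-1} (x - m_j), $$

dropping the $(n/2)\ln 2\pi$ term common to both classes. A pixel is
labeled MC when $d_{MC}(x) > d_{bg}(x)$ strictly; exact ties go to healthy,
so a detection requires positive evidence. We maximize $d_j$ — the
direction consistent with its derivation as a log-posterior — even though
informal descriptions of such classifiers sometimes speak of a "minimum
distance" rule.

## Self-learning: synthetic MCs and the modeling constant K

The MC class has no labeled training data. Instead the pipeline *plants*
synthetic MCs:

1. A binary **standard model** is generated: clusters of at least three
   filled discs (radius 1–3 px ≈ 0.2–1 mm) within a cluster radius of at
   most 25 px, so each cluster fits a 1 cm² block. Disc placement is
   seeded and discs are kept mutually non-adjacent so each synthetic MC is
   its own connected component. Total synthetic area is capped at 1 % of
   the image, matching the prevalence of real MCs.
2. **Blending**: each synthetic pixel receives added brightness
   proportional to its own underlying graylevel, $L = K \cdot I \cdot M$,
   the raw hybrid $I + L$ is smoothed with a small lowpass kernel $H$
   (default 3 × 3 Gaussian, σ = 0.8), and smoothing replaces values only on
   the synthetic support dilated by $H$'s footprint — the rest of the
   mammogram is bit-identical to the input. $K = 0$ is the exact identity.
3. **Training sets**: the MC class is estimated from the hybrid image at
   exactly the standard-model pixels; the healthy class from two square
   background ROIs (~4300 pixels total, about 50× the MC sample) placed at
   seeded-random positions disjoint from the dilated model, from any
   annotated real MCs, and from each other. The ≥ 3× class-size ratio is
   enforced. Classification then runs on the *original* image's feature
   stack, so the planted MCs cannot surface as detections.

The modeling constant $K \in (0, 1]$ controls how strongly the synthetic
MCs stand out. Too large, and the classifier keys on a single bright tone;
too small, and class separation collapses and false signals multiply. The
`meanDifferenceDiagnostic()` record (per-channel interclass mean
differences, variance ratios, and the normalized mean difference
NMD = (mean MC graylevel − mean breast graylevel)/255) exposes this
trade-off. Defaults follow tissue type: `chooseK()` returns 0.2 for
dense-glandular tissue and 0.5 for fatty tissue, or applies a breast-
variance rule (threshold 400) when no hint is given. NMD's normalizer
(255) is a package choice — the 8-bit range — and is configurable, since a
breast-mean normalizer is equally defensible.

## Post-processing and evaluation

Raw pixel classifications are cleaned in two physiologically motivated
steps:

* **Breast masking.** Otsu's threshold (exhaustive 256-level scan
  maximizing between-class variance; ties to the smallest threshold) on
  the original graylevel image, followed by keeping the largest
  8-connected component and filling holes. Detections outside the mask —
  dark background, film borders, radiographic labels — are vetoed.
* **Cluster rule.** Detected components are reduced to centroids and a
  component survives only if at least `minCount = 3` centroids share its
  1 cm² area. Two geometries are provided: a fixed non-overlapping 50-px
  tiling, and a sliding window centered on each candidate (iterated to a
  fixed point, so the filter stays idempotent). The *pipeline* defaults to
  the sliding rule: the fixed tiling erases valid clusters whose ~30 px
  extent happens to straddle two tile boundary lines, an arbitrary
  penalty the sliding rule removes. The standalone
  `applyPhysiologyFilter()` keeps the tiled geometry as its default.

Evaluation (`labelBlocks()`) tiles the mask into non-overlapping blocks
(residual rows/columns are dropped; 1024 = 20·50 + 24). Blocks touching an
annotated MC circle are excluded from the healthy census; each annotated
region scores TP if any detected component centroid falls inside its
circle, else FN; each remaining block is FP if it holds ≥ 3 centroids,
else TN. Sensitivity = 100·TP/(TP+FN), specificity = 100·TN/(TN+FP); zero
denominators yield NA rather than NaN. A comparison variant
(`evaluateVariant87()`) uses 87-px blocks and counts a single detected MC
as an FP, the convention of earlier two-stage systems. A detected "image
location" is always a connected component's centroid, so a 10-pixel blob
counts once, not ten times.

## The phantom

`generatePhantom()` provides ground-truthed synthetic mammograms so every
stage is testable without clinical data. Design:

* **Geometry**: a half-ellipse breast anchored at the left edge on a dark
  background (level 10), optionally with a bright rectangular film label.
* **Texture**: tissue is modeled as a *stationary lowpass background* —
  the regime in which MCs are the only point anomalies. Both tissue
  presets share a fine-grain field (sd 12, correlation length 3 px).
  The dense preset adds a coarser glandular-structure field (sd 22,
  correlation length 12 px), reflecting that dense tissue owes its larger
  variance (total sd 25 vs. 12, mean 170 vs. 120) to anatomical structure
  rather than fine noise. Concentrating the full dense variance at the MC
  scale would contradict the lowpass-background premise and make the
  phantom adversarial rather than representative.
* **Planted MCs**: disc clusters built by the same generator as the
  standard model (5 discs of radius 1–2.5 px within 15 px, by default),
  with additive contrast smoothed at the edges. Default contrasts (fatty
  52, dense 45 graylevels) put the planted clusters at NMD ≈ 0.1–0.2,
  the working regime of the detector, with fatty clusters carrying the
  larger contrast-to-texture ratio as in real film.
* Everything is bit-exact reproducible from the seed, and the truth mask
  and per-cluster annotations satisfy the clinical cluster definition by
  construction.

What the phantom does **not** emulate: pectoral muscle, vasculature,
ductal structure, scanner artifacts, film-density nonlinearity, and MC
shape irregularity (malignant morphology classes); planted MCs are discs.
Passing the phantom study therefore demonstrates that the implementation
is faithful and self-consistent under the stated texture model — not
clinical performance on real mammograms.

## Numerical and design choices

* **Boundary handling**: replicate padding for ED₈ and the rank window
  (zero padding would fabricate border singularities); symmetric
  half-sample extension for the DWT, keeping the redundant boundary
  coefficients so the synthesis bank inverts the analysis bank exactly
  (round-trip error < 1e−12 in tests).
* **Covariance regularization**: a near-singular class covariance
  (smallest eigenvalue < 1e−6 · trace/4) receives a ridge of that size on
  the diagonal; a fully degenerate sample (all channels constant) is an
  error naming the offending channels. This matters in practice: a flat
  background ROI makes the rank channel constant.
* **"Local histogram tail ratio"** for $x_2$ is operationalized as the
  strict-rank statistic described above and isolated in one function.
* **Coordinates** are R-native 1-based (row, col) with row 1 at the top;
  the MIAS bottom-left origin is converted once, at parse time, via
  `center_row = image_height − y`.
* **Seeding**: one user seed per run; per-stage seeds (standard model,
  cluster placement, ROI placement) are derived from it deterministically,
  and the run log records all of them. Identical logs imply identical
  outputs.
* **Problem sizes in the test-suite studies**: the end-to-end phantom
  study runs ten 512 × 512 phantoms (5 fatty at K = 0.5, 5 dense at
  K = 0.2, clusters at NMD ≥ 0.1) — large enough for ~45 evaluation
  blocks per breast and stable statistics, small enough to keep the
  whole suite fast. The statistical oracles use 10⁵ samples (parameter
  recovery), 1000 random SPD systems (decision function), and 200 random
  histograms (Otsu).

## Known limitations

* Random background-ROI placement can land on unrepresentative tissue;
  the effect grows with long-range texture correlation. The remedy —
  explicit ROI boxes, or an inclusion mask such as an eroded breast or
  glandular mask — is exposed via `selectTrainingSamples()` arguments.
* A single $K$ serves the whole image; mammograms mixing dense and fatty
  regions would benefit from spatially adaptive modeling.
* The two-class model assumes equal priors; MC prevalence is far below
  50 %, so the decision boundary is permissive by design and the cluster
  rule carries much of the specificity burden.
* Only the db4 family is built in; the wavelet back end is isolated
  behind `waveletSpec()` should other families be added.

## A minimal run

```{r example}
library(mcdetect)

ph <- generatePhantom(phantomSpec(shape = c(512, 512), tissue = "fatty",
                                  seed = 7))
res <- detectMC(ph$image, config = list(k = 0.5, seed = 1),
                annotations = ph$annotations)
print(res)
report <- labelBlocks(res$filtered, ph$annotations, blockPx = res$blockPx)
show(report)
```
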