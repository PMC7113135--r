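---
title: "Methods: from whole-slide image to diagnosis"
author: "wsidiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from whole-slide image to diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsidiag)
```

`wsidiag` implements a three-stage analysis of hematoxylin-and-eosin
(H&E) stained breast biopsy rasters: (1) detect diagnostically relevant
regions of interest (ROIs) on the whole slide, (2) segment each ROI into
eight histopathologic tissue classes, and (3) assign one of four
diagnoses — benign, atypia, ductal carcinoma in situ (DCIS), invasive —
from features of the tissue map. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic
test bed does and does not demonstrate.

## 1. ROI detection: a visual bag of words

A slide is tiled into non-overlapping 120 x 120 px *words* (partial
border tiles are discarded, since descriptors feed fixed-length
histograms). Each word is described by

* a joint CIELAB color histogram (8 x 8 x 8 = 512 bins; L clamped to
  [0, 100], a and b to [-100, 100]), and
* a texture histogram of uniform local binary patterns (LBP, 8
  neighbors at radius 1; 59 bins per channel) computed on the
  hematoxylin and eosin concentration channels after stain
  deconvolution (118 bins).

Both blocks are L1-normalized. CIELAB uses the standard sRGB decoding
under D65, implemented directly so white maps to exactly (100, 0, 0)
and the output agrees with published reference tables to better than
0.01. LBP codes compare each interior pixel with its ring of neighbors
(`>=` convention), and histograms use only a word's interior, so the
batch extractor over a whole slide is bit-identical to computing each
word in isolation.

A *visual dictionary* of k = 64 centroids (k-means, fixed seed;
centroids sorted lexicographically so the fit does not depend on the
clustering's internal label order) quantizes words to cluster ids.
Analysis windows of 3600 x 3600 px advance with 2400 px overlap
(stride 1200); a final window is clamped to the image edge so every
pixel is covered. Each window becomes the L1-normalized histogram of
its words' cluster ids — normalization matters because clamped border
windows contain fewer words. A linear-kernel support vector machine
separates ROI windows from background, trained with windows inside
annotated ROIs as positives and windows *near but not inside* them
(zero overlap, center within one window of an ROI) as negatives; the
near restriction keeps the negatives informative for the margin.
Positive windows are merged by connected components of their overlap
graph into consolidated boxes, drawn as red outlines on the overlay.

Histogram bin counts, k, the 0.5 positive-overlap threshold and the
one-window near margin are package choices (exposed as arguments);
only the 120 / 3600 / 2400 geometry is fixed by the reference
operating point.

## 2. Stain machinery

Optical density is `OD = -log10((I + 1) / 255)` per channel; the +1
keeps the transform finite at I = 0 and the base only rescales
concentrations. Stain vectors are estimated by the Macenko procedure:
drop pixels whose OD vector norm is below 0.15 (background), take the
top two principal directions of the remaining OD cloud, and return the
robust extreme directions of the projected angle distribution at the
1st/99th percentiles. We threshold the OD *norm* rather than requiring
every channel to clear the threshold: eosin absorbs almost only green,
and a per-channel rule silently discards exactly the near-pure eosin
pixels the extreme-angle step needs. Hematoxylin is identified as the
vector with the larger blue-channel OD component; components are
clipped to non-negative and renormalized. Deconvolution is per-pixel
least squares onto the two stain directions with negative
concentrations clipped to zero; normalization rescales each
concentration channel so its 99th-percentile maximum matches the
reference (Ruifrok-Johnston vectors, maxima 1.9705 / 1.0308) and
reconstructs RGB in the reference basis. By default each slide is
normalized from its own estimated stains to this fixed package
reference.

On 8-bit images, quantization alone moves individual reconstructed
concentrations by up to ~1% at OD near 1, so recovery accuracy is
stated as the *mean* per-pixel relative error (about 0.5% on
forward-model fixtures; stain angles recover to well under 2 degrees).

## 3. Tissue segmentation

The eight classes and their display palette are fixed: 0 background
(white), 2 benign epithelium (magenta), 3 malignant epithelium (blue),
4 normal stroma (pink), 5 desmoplastic stroma (violet), 6 secretion
(green), 7 blood (yellow), 8 necrosis (red). Code 1 is deliberately
absent from the scheme; label maps containing it are rejected, never
remapped.

Superpixels come from SLIC in (L, a, b, x, y): local k-means with
spatial weight `compactness / step` (compactness 10 by default),
followed by connectivity enforcement that absorbs 4-connected
fragments below 25% of the target size. The target count defaults to
one superpixel per 3000 px at full scale; the synthetic tests use one
per ~300 px because their ducts are drawn at roughly one fifth linear
scale. Returned ids are contiguous from 0 and each id is 4-connected.

Per-pixel classification is a pluggable interface with two backends:

* **classical** (default): each pixel is described by RGB, CIELAB,
  H&E concentrations and the 5 x 5 local mean and standard deviation
  of L, and classified by a random forest (100 trees, single-threaded
  and seeded, hence deterministic). It trains in seconds and serves as
  the reference implementation for everything downstream.
* **espnet**: a small encoder-decoder written directly on matrix
  operations, with ESP-style units (1 x 1 reduction feeding parallel
  3 x 3 convolutions at dilations 1 and 2, hierarchical fusion), a
  downsampling stage that also ingests a pooled copy of the RGB input
  (input-aware encoding), a decoder concatenating upsampled deep
  features with the shallower encoder stage and the raw input (dense
  skips), and class scores summed from three decoding paths. Training
  minimizes per-pixel softmax cross-entropy with Adam (default step
  1e-2, base width 8); gradients are verified against finite
  differences in the test suite. Inference tiles the image with 50%
  overlap, averages class scores over overlaps, and reflection-pads
  images smaller than the patch.

Pixel labels transfer to superpixels by majority vote; ties break to
the lowest class code everywhere, for determinism. Segmentation
quality is summarized as mean intersection-over-union (mIOU), pooled
over a held-out set per class as is standard for segmentation
benchmarks — a per-patch average lets one absorbed sliver zero a class
in a single patch and misrepresent an otherwise near-perfect
segmentation.

## 4. Diagnosis features and the cascade

From a per-superpixel label map the package computes:

* **frequency**: an 8-bin histogram counting one unit per superpixel
  (the superpixel, not the pixel, is the labeling unit; a
  pixel-weighted variant is available),
* **co-occurrence**: an 8 x 8 matrix where each adjacent superpixel
  pair with classes (a, b) adds one to (a, b) and (b, a) — same-class
  pairs add two to the diagonal — then L1-normalized. Adjacency is
  4-connectivity at pixel level (8-connectivity by option). The
  mid-level feature vector is the 8 frequency bins followed by the 64
  row-major co-occurrence cells,
* **structure**: ducts are connected components (superpixel
  adjacency) of epithelial superpixels (codes 2 or 3) with at least 3
  members. Around each duct, one-superpixel-wide layers are peeled:
  inward through the region enclosed by the filled duct outline, and
  outward through the rest; peeling stops early when a layer is
  empty. Each layer (and the duct itself) contributes an 8-bin class
  histogram, ordered `inner_2, inner_1, duct, outer_1, outer_2` with
  two layers per side by default. Multiple ducts in an ROI are
  *averaged* into one vector (concatenating a top-k variant was the
  alternative; averaging keeps the feature length fixed and matches
  the one-heatmap-per-ROI presentation of the feature).

Classification is a tree of three binary linear SVMs: invasive vs
rest on all samples; benign vs proliferative (atypia + DCIS) on the
non-invasive; DCIS vs atypia last. This order puts the easiest, most
consequential separation first and mirrors the reference cascade.
Prediction short-circuits down the tree and records each evaluated
stage's margin. Training sorts samples into a canonical order first,
so the fitted cascade is invariant to input permutation; the
mid-level and structure classifiers share this machinery and differ
only in their input features (a combined mode concatenates both, 112
features with the defaults).

## 5. The synthetic test bed

Because the clinical datasets behind the original operating points are
proprietary, every stage is exercised on a deterministic synthetic
generator:

* ROIs are stromal canvases (normal stroma with a blobby desmoplastic
  fraction set by quantile thresholding of a smoothed noise field, so
  the requested fraction is hit almost exactly) carrying
  concentric-disk ducts: lumen (background or secretion), epithelial
  ring (benign epithelium for benign/atypia, malignant for
  DCIS/invasive), necrotic lumen cores for DCIS, scattered malignant
  islands for invasive. Class-conditional desmoplastic fractions
  (0.10 / 0.25 / 0.45 / 0.65) create the composition signal the
  classifiers are supposed to find.
* Rendering paints each class with a base H&E-like color plus a
  class-specific sinusoidal texture and Gaussian noise, so LBP
  histograms carry class information without any learned texture.
* A ring fixture draws exact concentric bands split into angular
  sectors that double as a ground-truth superpixel map; every band is
  one superpixel wide, so the band index *is* the layer that peeling
  must recover, giving an exact oracle for the structure feature.
* Slides place rendered ROI blocks on a white canvas with recorded
  rectangles for window labeling.

Everything is a pure function of spec + seed (bit-identical reruns).
What passing these tests shows: the geometry, color, clustering,
voting, peeling and cascade machinery are correct, deterministic and
learnable end to end. What it does not show: performance on real
histology — no nuclei, no staining variability beyond the forward
model, no scanner artifacts, and class palettes chosen to be
separable. Published accuracies on clinical material are therefore
not comparable quantities here and are not claimed.

## 6. Problem sizes, tolerances, degenerate inputs

The test suite and acceptance script run the detector at one-fifth
linear scale (words 24 px, windows 240 px with 160 px overlap,
1200 x 1200 slides holding 300 x 300 tissue blocks — the same
window/word and overlap/window ratios as full scale), train the
segmenter on 20 patches of 64 x 64 px and the cascade on 40 ROIs of
300 x 300 px with 16 held out. These sizes are the package's chosen
operating point for a reproducible single-CPU run; the geometry code
is size-independent and the full-scale defaults are exercised by the
counting tests.

Degenerate inputs are handled explicitly: blank windows (no complete
word) are treated as negative with a logged skip; blank images raise
an insufficient-tissue error in stain estimation; collinear stain
matrices are rejected; ducts without an enclosed region flag empty
inner layers; an ROI without ducts yields the all-zero structure
vector, flagged. Window-level detector evaluation treats windows that
partially overlap a tissue block (below the 0.5 positive threshold
but above zero) as ambiguous and excludes them from precision,
mirroring the in/near training label design.

## 7. Known limitations

* SVS / pyramidal slide formats are out of scope; inputs are plain
  TIFF / PNG / JPEG / BMP rasters.
* The espnet backend is deliberately small; it is faithful to the
  architectural ideas, not to any particular trained network, and the
  original weights are unavailable by construction.
* Stain estimation assumes exactly two stains.
* The structure feature presumes ring-like ducts; diffuse invasive
  growth without epithelial rings yields few or no ducts, in which
  case the mid-level features carry the signal.
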