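---
title: "Methods: dense centroid encoding and two-stage vertebra segmentation"
author: "spineseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dense centroid encoding and two-stage vertebra segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineseg)
```

## The problem

Instance segmentation of vertebrae in spine CT asks for two things at
once: *where* each vertebra is (localization) and *which voxels belong
to it* (segmentation), with neighboring vertebrae — which look nearly
identical — kept apart.  spineseg implements a two-stage approach:

1. **Localization.** Vertebra centroids are detected on transversal
   (axial) slices by regressing a *dense label*: a per-voxel encoding of
   centroid proximity that a 2D convolutional network can learn from
   slice stacks, decoded back to discrete centroids by a deterministic
   aggregation procedure.
2. **Segmentation.** Each detected centroid anchors a fixed-size
   80×128×112 voxel region of interest (ROI) in which a 3D network
   produces a per-voxel foreground probability; thresholding, small
   component removal, and a sequential merge produce the final labeled
   spine, which is resampled back to the native grid.

All volumes use (z, y, x) axis order with z the transversal slice
index.  Coordinates are 0-based voxel indices; the working grid is 1 mm
isotropic, so voxel-space distances are millimetres.  Native scans with
anisotropic spacing are brought to this grid with linear interpolation
for images and nearest-neighbor for labels, with output shapes
`round(shape * spacing)` and voxel-center alignment.

## The dense label

For vertebra $i$ with mask $V_i$, centroid $c_i$, approximate radius
$d_{\max}$ and height $h_i$, every foreground voxel $v_j$ at Euclidean
distance $d_j = \lVert v_j - c_i \rVert$ receives the coefficient

$$
p_j = (d_{\max} - d_j)\,\Bigl(1 - \tan\bigl(\lvert \Delta z / h_i\rvert
\cdot \tfrac{\pi}{2}\bigr)\Bigr),
$$

with $d_j$ first clamped to $d_{\max}$, and the voxel value stored as
$p_j / d_{\max} \times 255$.  Three numerical decisions deserve
explanation, because the formula leaves them open:

* **Argument of the tangent.** We evaluate
  $\tan(\lvert\Delta z/h\rvert\cdot\pi/2)$, which drives the slice
  factor to exactly 0 at $\lvert\Delta z\rvert = h/2$ — the encoding's
  purpose is to keep the center slice of each vertebra most prominent,
  and this reading makes the decay vanish at the vertebra boundary.
  The alternative grouping, $\tan(\lvert\Delta z/h\rvert)\cdot\pi/2$,
  never reaches zero and can exceed 1.  Past the pole
  ($\lvert\Delta z/h\rvert \ge 1$) the factor is defined as 0 rather
  than evaluating the tangent.
* **Clamping.** Negative coefficients (beyond the half-height) are
  clamped to 0 so that stored values stay in $[0, 255]$.
* **Distance.** $d_j$ is the full 3D distance, not the in-plane
  distance: the per-voxel definition gives $\lVert v_j - c_i\rVert$
  with no projection.

The radius $d_{\max}$ is estimated as the 95th percentile of
foreground-voxel distances from the centroid.  A maximum would be
dominated by the long posterior process, and an external per-level
radius table is not available; the percentile is robust and
configurable (`estimate_geometry(prob = )`).  A 1 mm floor guards
degenerate single-voxel masks.  The height is the mask's z extent.
Overlapping per-vertebra contributions are combined by voxel-wise
maximum, which makes the construction invariant to processing order.

Dense labels are stored on the 0–255 scale and divided by 255 when used
as network regression targets; the decode threshold of 50 below is
applied on the 0–255 scale.  This reconciles the stored-integer-range
convention with sigmoid-output training.

## Decoding: from dense map to centroids

Given a (predicted or exact) dense volume:

1. The per-slice maximum forms a 1D profile over z.
2. The profile is smoothed with a Savitzky–Golay filter.  Window 11
   slices, polynomial order 3 by default: the window must stay well
   below the smallest vertebra height (≈ 18 mm on the 1 mm grid) so
   that adjacent peaks do not fuse, and order 3 preserves the local
   peak shape (the filter reproduces cubics exactly).
3. Profile peaks give the centroid slices $\hat z_c$.  The peak rule is
   plateau-aware local maxima with a minimum height of 0.2 × the global
   profile maximum and a minimum separation of 10 slices (just under
   the smallest vertebra height); when two candidates are closer, the
   higher one wins.
4. On each peak slice, values ≤ 50 are zeroed.  With $S_{\max}$ and
   $S_{\min}$ the maximum and minimum of the retained values, four
   ring-like contours are extracted at levels
   $S_{\min}\cdot 0.1 j + S_{\max}\cdot 0.1 (10 - j)$ for
   $j \in \{2,3,4,5\}$ (a ±5 intensity band on the 0–255 scale), each
   fitted with an algebraic least-squares (Kåsa) circle; the mean of
   the successfully fitted centers is the in-plane centroid
   $(\hat y, \hat x)$.  The Kåsa fit is linear, deterministic, and
   exact on noiseless circles; contours with fewer than 3 pixels or
   collinear pixels are skipped, and a slice where every contour is
   degenerate yields no centroid (the peak is dropped).

Two conventions here were genuinely open.  The contour index range is
the half-open $[2, 6)$ — four contours — although prose descriptions of
such schemes sometimes say "five"; we follow the explicit range.
$S_{\min}$ is the minimum of the *retained* (above-threshold) values,
not 0; otherwise every level would collapse toward $S_{\max}$.

Decoded centroids get vertebra ids by cranio-caudal rank.  Anatomical
naming (which rank is T1) is out of scope; ids are ranks.

## The networks

Both stages use a Dense-U-Net: a U-Net encoder–decoder in which every
resolution block carries two extra links beside the usual U-Net skips —
a *dense interconnection* that concatenates the unprocessed block input
onto the input of the block's second convolution, and a *residual
interconnection* that concatenates the block input onto the block
output.  Both are realized as channel concatenation rather than
addition: concatenation imposes no channel-count matching and
subsumes addition in what the following convolution can express.

Defaults: depth 5 (inputs divisible by 16), base 32 filters doubling
per level, 3×3(×3) convolutions with "same" padding and ReLU, 2× max
pooling down and 2× nearest-neighbor upsampling up, no normalization
layers, and a final 1×1 convolution with sigmoid so outputs always lie
in (0, 1) — which keeps the downstream 0.5/0.9 thresholds meaningful.
The 2D localization variant takes 2k+1 neighboring slices (k = 4, nine
channels; out-of-range neighbors are zero-filled) so that 3D context
enters a 2D network as channels; the 3D variant takes the ROI volume.
CT intensities are windowed from [−1000, 2000] HU to [0, 1] before
entering either network.

Training uses binary cross-entropy, batch size 1, and Adam with
learning rate 1e-5, β₁ 0.9, β₂ 0.999, ε 1e-8 and step decay 1.99e-7
(learning rate `lr / (1 + decay · step)`); 30 epochs for the 2D net and
50 for the 3D net by default.  The implementation is a self-contained
reverse-mode tape over compiled convolution/pooling kernels; gradients
are verified against finite differences in the test suite, and runs are
bit-reproducible for a fixed seed.  This is a desk-scale implementation:
it trains smoke-test problems in seconds but is not meant for
GPU-scale experiments.

## Stage-2 postprocessing

Probability maps are binarized with a level-dependent threshold: 0.5
for T1–T9, 0.9 for T10–L5 (small upper-thoracic vertebrae occupy little
of the fixed ROI, so a permissive threshold preserves them; the large
lumbar vertebrae need a strict one to suppress responses to their
neighbors).  Values exactly at the threshold map to background — the
rule is stated in terms of strictly-less and strictly-greater, and
equality must be decided; background is the conservative choice.
Connected components smaller than 500 voxels are removed
(26-connectivity by default, configurable to 6; a component of exactly
500 voxels is kept, since the rule removes objects *smaller than* 500).
The level-group mapping is derived from rank when 17 vertebrae are
present and must be supplied explicitly otherwise; `run_pipeline()`
uses the single permissive group for non-anatomical stacks such as
phantoms.

Merging is sequential and cranio-caudal: each binary mask claims only
voxels still empty, so a voxel claimed by two adjacent instances keeps
the more cranial label.  The merged volume is resampled back to the
native grid with nearest-neighbor interpolation.

## Metrics

Location error is the Euclidean centroid distance in mm; detection
rate is the percentage of a vertebra's voxels inside its ROI.  Dice and
IoU follow the standard overlap definitions (empty vs empty is defined
as 1, empty vs non-empty as 0); the identity IoU = DC/(2 − DC) is
verified on random masks.  The Hausdorff distance is symmetric and
computed between *surface* voxels — foreground voxels with a background
6-neighbor (volume borders count) — matching its definition in terms of
segmented and ground-truth surfaces.  Pixel accuracy is
(TP+TN)/(TP+FP+TN+FN).  Reports aggregate per vertebra, per case, and
per anatomical group (T1–T6, T7–T12, L1–L5) for 17-vertebra stacks.

## The phantom generator

Every stage is exercised on synthetic spine phantoms: a cranio-caudal
stack of vertebra-like bodies, each an ellipsoid (per-level in-plane
radius and height) plus a posterior rectangular process, over a uniform
background with additive Gaussian noise.  Defaults emulate a
thoracolumbar stack: 17 vertebrae, radii ramping 10→18 mm and heights
18→30 mm cranio-caudally (upper thoracic vertebrae are smaller than
lumbar ones), 4 mm intervertebral gaps, bone/soft-tissue contrast
400/50 intensity units, noise SD 15.  For stacks of other lengths the
ramps are interpolated over the same ranges.  Masks, exact voxel-mean
centroids, and the image are returned together; generation is
bit-reproducible from the seed, and a non-positive gap is rejected
because adjacent bodies would overlap.

What the phantom does *not* emulate: cortical/trabecular texture,
ribs and costovertebral junctions, partial-volume effects, fractures,
scanner noise correlation.  Passing phantom tests therefore
demonstrates that the encoding, decoding, geometry, and bookkeeping are
correct — not that the networks reach clinical accuracy on real CT,
which requires real training data at scale.

## Problem sizes and tolerances in the shipped checks

The test suite and the acceptance script run at deliberately small
sizes so the full pipeline executes in minutes on one CPU core: the
encode/decode property uses ten 5-vertebra phantoms (50 centroids,
recovered with mean error well under 2 mm); the oracle pipeline (both
networks bypassed, ground-truth dense labels and masks fed through
every remaining stage) uses 48×64×56 ROIs on 5-vertebra phantoms;
training smoke tests use a depth-3, 2-filter 2D net on one 48×40 slice
stack for 10 epochs, and the 3D forward-pass check uses a depth-4,
1-filter net on the full 80×128×112 ROI.  The coefficient, circle-fit,
smoothing, and metric checks compare against independent oracles
(scalar re-evaluation, per-window polynomial fits, exhaustive pairwise
distances) at tolerances 1e-9 to 1e-6.

## Known limitations

* Vertebra identification (assigning T1 vs T2 to a rank) is not
  attempted; ids are cranio-caudal ranks.
* The reader supports MetaImage mhd/raw only (including compressed
  payloads); DICOM and NIfTI are out of scope.
* The networks are CPU-bound reference implementations; headline
  clinical accuracies require external CT datasets and GPU-scale
  training, neither of which this package ships.
* Elastic augmentation interpolates a 3×3×3 control grid trilinearly
  (control displacement SD 3 mm by default); a B-spline field would be
  smoother but changes nothing structurally.
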