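# spineseg

Two-stage vertebra localization and instance segmentation for spine CT,
in R.

Automatic per-vertebra analysis of CT — identifying each vertebra
T1…L5 and delineating its voxels — underpins spinal deformity
assessment, biomechanical modeling, and image-guided intervention.  It
is hard because neighboring vertebrae look nearly identical and their
size and shape vary along the spine and between patients.  spineseg
implements a complete two-stage pipeline for this problem, aimed at
researchers in medical image analysis who want an inspectable,
fully-tested reference implementation that runs on a laptop:

1. **Localization.**  Sparse centroid annotations are converted into a
   *dense label*: every voxel of vertebra $i$ gets
   $p_j/d_{\max}\times 255$ with
   $p_j = (d_{\max} - d_j)\bigl(1 - \tan(|\Delta z/h_i|\,\pi/2)\bigr)$,
   where $d_j = \lVert v_j - c_i\rVert$ is the distance to the centroid,
   $d_{\max}$ the approximate vertebra radius and $h_i$ its height — a
   learnable regression target that peaks at the centroid and vanishes at
   the centroid slice's half-height.  A 2D Dense-U-Net (U-Net plus
   dense and residual concatenation links inside every block) regresses
   this map from stacks of 2k+1 = 9 transversal slices.  Centroids are
   decoded by a deterministic aggregation: per-slice maxima →
   Savitzky–Golay smoothing → peak slices → threshold at 50 → four
   iso-intensity ring contours → algebraic least-squares circle fits →
   mean center.
2. **Segmentation.**  Each centroid anchors a fixed 80×128×112 voxel
   ROI on the 1 mm isotropic grid; a 3D Dense-U-Net scores each ROI
   voxel, thresholded at 0.5 (T1–T9) or 0.9 (T10–L5); components under
   500 voxels are removed; instances merge cranio-caudally (first
   claim wins) and the labeled spine is resampled to the native grid.
   Evaluation reports location error, detection rate, Dice, IoU,
   symmetric surface Hausdorff distance, and pixel accuracy.

The package includes MetaImage (mhd/raw) I/O, isotropic resampling,
elastic-deformation and Gaussian-noise augmentation, a command-line
interface, and a synthetic spine-phantom generator with exact
ground-truth masks and centroids so every stage is testable without any
external dataset.  The networks are a self-contained CPU implementation
(compiled convolution kernels plus a minimal reverse-mode tape) with
finite-difference-verified gradients — suitable for smoke-scale
training and full-size inference, not GPU-scale experiments.

## Worked example

Generate a 5-vertebra phantom, encode its dense labels, decode the
centroids, and run the full oracle pipeline (networks bypassed; every
other stage exercised end to end):

```r
library(spineseg)
ph <- generate_spine_phantom(spine_phantom_spec(n_vertebrae = 5, seed = 42))
print(ph$labels)
#> <spine_label_volume> 144 x 56 x 44 (z,y,x), spacing 1 x 1 x 1 mm
#> labels: 1 2 3 4 5

dense <- densify_spine(ph$labels, ph$centroids)
aggregate_centroids(dense)
#>   vertebra_id   z        y  x
#> 1           1  13 25.61051 22
#> 2           2  37 24.79107 22
#> 3           3  63 24.76268 22
#> 4           4  93 24.31847 22
#> 5           5 125 23.97513 22

res <- run_pipeline(ph$image, ph$labels, oracle_dense = TRUE,
                    roi_size = c(48, 64, 56))
res$report$summary[, c("scope", "n", "LE_mm", "DR_pct", "DC", "IoU", "HD_mm", "PA")]
#>   scope n     LE_mm DR_pct DC IoU HD_mm PA
#> 1   all 5 0.2231665    100  1   1     0  1
```

The decoded centroids sit within a fraction of a millimetre of the true
voxel-mean centroids (`LE_mm`, here 0.22 mm on average), every
vertebra lies fully inside its ROI (`DR_pct` 100), and ground-truth
masks pass through thresholding, component filtering and merging
unchanged (Dice/IoU/PA 1, Hausdorff 0) — which is exactly what the
oracle path should produce when the surrounding machinery is correct.

Training and inference with the networks follow the same surfaces:

```r
net <- build_dense_unet(net_config(2, depth = 3, base_filters = 2), seed = 7)
fit <- train_dense_unet(net, dataset, train_config(epochs = 10, seed = 5))
L   <- predict_dense(volume_1mm, fit$net)   # dense map, 0..255
```

A command-line wrapper covering `phantom`, `densify`, `localize`,
`segment`, `train-loc`, `train-seg`, `evaluate` and `pipeline` is
installed at `system.file("cli", "spineseg.R", package = "spineseg")`.

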