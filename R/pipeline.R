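# End-to-end wiring of the two stages.  An oracle mode feeds the
# ground-truth dense labels (stage 1) and ground-truth masks (stage 2)
# through every bespoke non-network step -- encoding, aggregation,
# cropping, thresholding, component filtering, merging, evaluation -- so
# the whole pipeline is testable in minutes without training.

#' Stage 1: localize vertebra centroids in a volume
#'
#' @param v a [volume()] on the 1 mm isotropic grid.
#' @param net 2D localization network; required unless `dense` is given.
#' @param dense optional precomputed dense label volume (e.g. the
#'   ground-truth encoding, for oracle runs).
#' @param ... passed to [aggregate_centroids()].
#' @return List with `centroids` (data frame) and `dense` (the dense
#'   volume used).
#' @export
localize_spine <- function(v, net = NULL, dense = NULL, ...) {
  if (is.null(dense)) {
    if (is.null(net)) stop("either a localization net or a dense volume is required")
    dense <- predict_dense(v, net)
  }
  list(centroids = aggregate_centroids(dense, ...), dense = dense)
}

#' Stage 2: segment each vertebra and merge into a labeled spine
#'
#' For every centroid an ROI is cropped; the per-vertebra probability
#' map comes either from the 3D network or, in oracle mode, from the
#' ground-truth label crop.  Maps are thresholded (level-dependent),
#' cleaned of sub-500-voxel components, and merged cranio-caudally into
#' one instance labeling.
#'
#' @param v the intensity [volume()] (1 mm grid).
#' @param centroids data frame `vertebra_id`, `z`, `y`, `x`.
#' @param net 3D segmentation network; required unless `truth_labels`
#'   is given.
#' @param truth_labels oracle mode: ground-truth [label_volume()] whose
#'   per-vertebra crops stand in for network probabilities.
#' @param roi_size ROI shape (z, y, x).
#' @param level_groups per-centroid `"T1-T9"`/`"T10-L5"`; derived from
#'   rank for 17-vertebra stacks, otherwise required.
#' @param min_component_voxels,connectivity see
#'   [remove_small_components()].
#' @param window intensity window for network input normalization.
#' @return List: `labels` (merged [label_volume()]), `rois` (named list
#'   of the ROI crops used), `parts` (cleaned binary masks).
#' @export
segment_spine <- function(v, centroids, net = NULL, truth_labels = NULL,
                          roi_size = c(80, 128, 112), level_groups = NULL,
                          min_component_voxels = 500, connectivity = 26,
                          window = c(-1000, 2000)) {
  n <- nrow(centroids)
  if (n == 0L) stop("no centroids to segment")
  if (is.null(net) && is.null(truth_labels))
    stop("either a segmentation net or oracle truth labels are required")
  if (is.null(level_groups)) {
    if (n != 17)
      stop("level_groups must be given explicitly for stacks of ", n,
           " vertebrae")
    level_groups <- ifelse(centroids$vertebra_id <= 9, "T1-T9", "T10-L5")
  }
  parts <- list()
  rois <- list()
  for (i in seq_len(n)) {
    id <- centroids$vertebra_id[i]
    cc <- as.numeric(centroids[i, c("z", "y", "x")])
    roi <- crop_roi(v, cc, roi_size)
    rois[[as.character(id)]] <- roi
    prob <- if (!is.null(truth_labels)) {
      crop_roi(truth_labels, cc, roi_size, vertebra_id = id)$data
    } else {
      predict(net, normalize_intensity(roi$data, window))
    }
    pred <- vertebra_prediction(prob, roi$offset, id,
                                level_group = level_groups[i])
    bin <- threshold_prediction(pred)
    bin <- remove_small_components(bin, min_component_voxels, connectivity)
    parts[[i]] <- bin
  }
  merged <- merge_spine(parts, dim(vol_data(v)),
                        spacing = vol_spacing(v))
  list(labels = merged, rois = rois, parts = parts)
}

#' Run the full localization-segmentation-evaluation pipeline
#'
#' @param image intensity [volume()] on the 1 mm grid.
#' @param labels ground-truth [label_volume()]; required for oracle mode
#'   and for evaluation.
#' @param loc_net,seg_net trained networks (ignored in oracle mode).
#' @param oracle_dense bypass both networks: stage 1 decodes the
#'   ground-truth dense encoding, stage 2 thresholds ground-truth crops.
#' @param reference optional native-resolution reference volume; when
#'   given the merged labels are also resampled back to it
#'   (`native_labels`).
#' @param roi_size ROI shape.
#' @param evaluate compute a [evaluate_spine()] report (needs `labels`).
#' @return List: `centroids`, `dense`, `segmentation` (merged labels),
#'   `rois`, `report` (or `NULL`), `native_labels` (or `NULL`).
#' @export
run_pipeline <- function(image, labels = NULL, loc_net = NULL, seg_net = NULL,
                         oracle_dense = FALSE, reference = NULL,
                         roi_size = c(80, 128, 112),
                         evaluate = !is.null(labels)) {
  dense <- NULL
  if (oracle_dense) {
    if (is.null(labels)) stop("oracle mode needs ground-truth labels")
    dense <- densify_spine(labels)
  }
  loc <- localize_spine(image, net = loc_net, dense = dense)
  centroids <- loc$centroids
  if (nrow(centroids) == 0L) stop("no centroids detected")
  n <- nrow(centroids)
  # single-threshold group for non-anatomical stacks (e.g. phantoms)
  level_groups <- if (n == 17) NULL else rep("T1-T9", n)
  seg <- segment_spine(image, centroids,
                       net = seg_net,
                       truth_labels = if (oracle_dense) labels else NULL,
                       roi_size = roi_size, level_groups = level_groups)
  report <- NULL
  if (evaluate && !is.null(labels)) {
    centroids_true <- do.call(rbind, lapply(vertebra_labels(labels), function(id) {
      cc <- compute_centroid(labels$data == id)
      data.frame(vertebra_id = id, z = cc[1], y = cc[2], x = cc[3])
    }))
    report <- evaluate_spine(labels, seg$labels,
                             centroids_true = centroids_true,
                             centroids_pred = centroids,
                             rois = seg$rois)
  }
  native <- if (!is.null(reference))
    resample_to_reference(seg$labels, reference) else NULL
  list(centroids = centroids, dense = loc$dense, segmentation = seg$labels,
       rois = seg$rois, report = report, native_labels = native)
}
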