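# Evaluation criteria: location error and detection rate for
# localization; Dice, IoU, Hausdorff distance and pixel accuracy for
# segmentation; per-vertebra, per-case and anatomical-group reporting.

#' Location error between two centroids
#'
#' Euclidean distance on the 1 mm grid (voxel units = mm).  When both
#' inputs carry a `vertebra_id` the ids must agree.
#'
#' @param c1,c2 numeric (z, y, x) vectors or single-row centroid data
#'   frames.
#' @return Distance in mm.
#' @export
location_error <- function(c1, c2) {
  get <- function(cc) {
    if (is.data.frame(cc)) list(id = cc$vertebra_id[1],
                                p = as.numeric(cc[1, c("z", "y", "x")]))
    else list(id = NULL, p = as.numeric(cc))
  }
  a <- get(c1); b <- get(c2)
  if (!is.null(a$id) && !is.null(b$id) && a$id != b$id)
    stop("vertebra_id mismatch in location_error")
  sqrt(sum((a$p - b$p)^2))
}

#' Detection rate of a vertebra in its ROI
#'
#' `100 * (vertebra voxels inside the ROI box) / (total vertebra
#' voxels)`.
#'
#' @param mask binary 3D array of one vertebra (parent grid).
#' @param roi a `roi_crop` (its offset and size define the box).
#' @return Percent in `[0, 100]`.
#' @export
detection_rate <- function(mask, roi) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty vertebra mask")
  lo <- roi$offset            # 0-based inclusive
  hi <- roi$offset + roi$size - 1L
  inside <- idx[, 1] - 1 >= lo[1] & idx[, 1] - 1 <= hi[1] &
            idx[, 2] - 1 >= lo[2] & idx[, 2] - 1 <= hi[2] &
            idx[, 3] - 1 >= lo[3] & idx[, 3] - 1 <= hi[3]
  100 * sum(inside) / nrow(idx)
}

#' Dice coefficient and intersection over union
#'
#' `DC = 2|X intersect Y| / (|X| + |Y|)`, `IoU = |X intersect Y| /
#' |X union Y|`.  Two empty masks score 1 by convention; empty vs
#' non-empty scores 0.
#'
#' @param X,Y binary grids of equal shape.
#' @return Named vector `c(dice, iou)`.
#' @export
dice_iou <- function(X, Y) {
  if (!all(dim(X) == dim(Y))) stop("shape mismatch")
  x <- X != 0; y <- Y != 0
  nx <- sum(x); ny <- sum(y)
  if (nx == 0 && ny == 0) return(c(dice = 1, iou = 1))
  inter <- sum(x & y)
  c(dice = 2 * inter / (nx + ny), iou = inter / (nx + ny - inter))
}

# Foreground voxels with at least one background 6-neighbor (voxels on
# the array border count as surface).
surface_voxels <- function(mask) {
  m <- mask != 0
  d <- dim(m)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  interior <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
              pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
              pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
              pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
              pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
              pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  m & !interior
}

#' Symmetric Hausdorff surface distance
#'
#' `HD = max(h(G, P), h(P, G))` with `h(G, P) = max_g min_p ||g - p||`
#' over surface voxels (foreground voxels with a background 6-neighbor),
#' in mm on the 1 mm grid.
#'
#' @param G,P non-empty binary grids of equal shape.
#' @export
hausdorff_distance <- function(G, P) {
  if (!all(dim(G) == dim(P))) stop("shape mismatch")
  sg <- which(surface_voxels(G), arr.ind = TRUE)
  sp <- which(surface_voxels(P), arr.ind = TRUE)
  if (nrow(sg) == 0L || nrow(sp) == 0L)
    stop("hausdorff_distance requires two non-empty masks")
  a <- matrix(as.numeric(sg), ncol = 3)
  b <- matrix(as.numeric(sp), ncol = 3)
  max(max(cpp_min_dists(a, b)), max(cpp_min_dists(b, a)))
}

#' Pixel accuracy
#'
#' `(TP + TN) / (TP + FP + TN + FN)` over all voxels.
#'
#' @param G,P binary grids of equal shape.
#' @export
pixel_accuracy <- function(G, P) {
  if (!all(dim(G) == dim(P))) stop("shape mismatch")
  mean((G != 0) == (P != 0))
}

.anatomical_group <- function(id, n) {
  if (n != 17) return("all")
  if (id <= 6) "upper thoracic (T1-T6)"
  else if (id <= 12) "lower thoracic (T7-T12)"
  else "lumbar (L1-L5)"
}

#' Per-vertebra evaluation report
#'
#' Computes, for every vertebra present in the ground truth, the
#' segmentation metrics (DC, IoU, HD, PA) against the prediction and --
#' when centroids and ROIs are supplied -- the localization metrics (LE,
#' DR).  Aggregates are reported as mean and sd overall and per
#' anatomical group (upper thoracic T1-T6, lower thoracic T7-T12,
#' lumbar L1-L5) when the stack has 17 vertebrae.
#'
#' @param truth,pred [label_volume()]s on the same grid.
#' @param centroids_true,centroids_pred optional centroid data frames
#'   (`vertebra_id`, `z`, `y`, `x`).
#' @param rois optional named list of `roi_crop`s keyed by vertebra id.
#' @return A `metrics_report`: list with `per_vertebra` and `summary`
#'   data frames.
#' @export
evaluate_spine <- function(truth, pred, centroids_true = NULL,
                           centroids_pred = NULL, rois = NULL) {
  stopifnot(is_label_volume(truth), is_label_volume(pred))
  if (!all(dim(truth$data) == dim(pred$data))) stop("grid mismatch")
  ids <- vertebra_labels(truth)
  n <- length(ids)
  rows <- lapply(ids, function(id) {
    g <- truth$data == id
    p <- pred$data == id
    di <- dice_iou(g, p)
    hd <- if (any(g) && any(p)) hausdorff_distance(g, p) else NA_real_
    le <- NA_real_
    if (!is.null(centroids_true) && !is.null(centroids_pred) &&
        id %in% centroids_true$vertebra_id &&
        id %in% centroids_pred$vertebra_id) {
      le <- location_error(centroids_true[centroids_true$vertebra_id == id, ],
                           centroids_pred[centroids_pred$vertebra_id == id, ])
    }
    dr <- NA_real_
    if (!is.null(rois) && !is.null(rois[[as.character(id)]]))
      dr <- detection_rate(g, rois[[as.character(id)]])
    data.frame(vertebra_id = id,
               group = .anatomical_group(id, n),
               LE_mm = le, DR_pct = dr,
               DC = di[["dice"]], IoU = di[["iou"]],
               HD_mm = hd, PA = pixel_accuracy(g, p))
  })
  per_vertebra <- do.call(rbind, rows)
  agg <- function(df, label) {
    data.frame(scope = label,
               n = nrow(df),
               LE_mm = mean(df$LE_mm), LE_sd = sd(df$LE_mm),
               DR_pct = mean(df$DR_pct),
               DC = mean(df$DC), DC_sd = sd(df$DC),
               IoU = mean(df$IoU), IoU_sd = sd(df$IoU),
               HD_mm = mean(df$HD_mm), HD_sd = sd(df$HD_mm),
               PA = mean(df$PA), PA_sd = sd(df$PA))
  }
  summary <- agg(per_vertebra, "all")
  if (n == 17) {
    for (grp in unique(per_vertebra$group))
      summary <- rbind(summary,
                       agg(per_vertebra[per_vertebra$group == grp, ], grp))
  }
  structure(list(per_vertebra = per_vertebra, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-vertebra metrics:\n")
  print(x$per_vertebra, digits = 4, row.names = FALSE)
  cat("\nAggregates (mean, sd):\n")
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as CSV
#' @param report a `metrics_report`.
#' @param path output CSV (per-vertebra rows; the summary goes to
#'   `<path>.summary.csv`).
#' @export
write_metrics_report <- function(report, path) {
  write.csv(report$per_vertebra, path, row.names = FALSE)
  write.csv(report$summary, paste0(sub("\\.csv$", "", path), ".summary.csv"),
            row.names = FALSE)
  invisible(path)
}
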