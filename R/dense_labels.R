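# Dense centroid-proximity encoding.  Sparse vertebra centroids are
# converted into a per-voxel regression target on the 0..255 scale: the
# value decays with 3D distance from the centroid and is driven to zero
# away from the centroid slice, so that the center slice of each vertebra
# stays the most focused.

#' Voxel-mean centroid of a binary mask
#'
#' @param mask 3D logical/0-1 array, (z, y, x).
#' @return Numeric (z, y, x), 0-based continuous voxel coordinates.
#' @export
compute_centroid <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("cannot compute the centroid of an empty mask")
  out <- colMeans(idx) - 1
  names(out) <- c("z", "y", "x")
  out
}

#' Approximate radius and height of a vertebra mask
#'
#' The height is the z extent of the mask; the radius `d_max` is the 95th
#' percentile of the Euclidean distances between foreground voxels and
#' the centroid, which is robust to the elongated posterior process.  A
#' floor of 1 mm guards degenerate single-voxel masks.
#'
#' @param mask 3D binary array on the 1 mm grid.
#' @param centroid centroid as from [compute_centroid()]; computed if
#'   missing.
#' @param prob distance percentile used for `d_max`.
#' @return List with `d_max` (mm) and `h` (mm).
#' @export
estimate_geometry <- function(mask, centroid = NULL, prob = 0.95) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  if (is.null(centroid)) centroid <- colMeans(idx) - 1
  h <- diff(range(idx[, 1])) + 1
  d <- sqrt((idx[, 1] - 1 - centroid[1])^2 +
            (idx[, 2] - 1 - centroid[2])^2 +
            (idx[, 3] - 1 - centroid[3])^2)
  d_max <- max(quantile(d, prob, names = FALSE), 1)
  list(d_max = d_max, h = as.numeric(h))
}

#' Dense-label coefficient for one voxel
#'
#' `p = (d_max - d) * (1 - tan(|dz / h| * pi / 2))`, with `d` first
#' clamped to `d_max`, the slice factor clamped to 0 once `|dz| >= h/2`
#' (the tangent reaches its pole at `|dz/h| = 1`), and the result clamped
#' to be non-negative.  At the centroid (`d = 0`, `dz = 0`) the
#' coefficient equals `d_max`.
#'
#' @param d_max approximate vertebra radius, mm (> 0).
#' @param d_j voxel-to-centroid Euclidean distance, mm (>= 0).
#' @param dz signed slice offset from the centroid slice, mm.
#' @param h approximate vertebra height, mm (> 0).
#' @return Coefficient in `[0, d_max]`; vectorized over all arguments.
#' @export
eq1_coefficient <- function(d_max, d_j, dz, h) {
  stopifnot(all(d_max > 0), all(h > 0), all(d_j >= 0))
  d_j <- pmin(d_j, d_max)
  frac <- abs(dz / h)
  slice_factor <- ifelse(frac >= 1, 0, 1 - tan(pmin(frac, 1 - 1e-12) * pi / 2))
  pmax((d_max - d_j) * pmax(slice_factor, 0), 0)
}

#' Dense-label contribution of a single vertebra
#'
#' Every foreground voxel receives `p / d_max * 255`; the background is 0.
#'
#' @param mask binary 3D array on the 1 mm grid.
#' @param centroid 0-based (z, y, x) centroid.
#' @param geom geometry from [estimate_geometry()]; computed if missing.
#' @return Numeric 3D array with values in `[0, 255]`.
#' @export
densify_vertebra <- function(mask, centroid = NULL, geom = NULL) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  if (is.null(centroid)) centroid <- colMeans(idx) - 1
  if (is.null(geom)) geom <- estimate_geometry(mask, centroid)
  out <- array(0, dim = dim(mask))
  out[idx] <- .dense_values(idx, centroid, geom)
  out
}

.dense_values <- function(idx, centroid, geom) {
  d <- sqrt((idx[, 1] - 1 - centroid[1])^2 +
            (idx[, 2] - 1 - centroid[2])^2 +
            (idx[, 3] - 1 - centroid[3])^2)
  dz <- idx[, 1] - 1 - centroid[1]
  eq1_coefficient(geom$d_max, d, dz, geom$h) / geom$d_max * 255
}

#' Dense centroid labels for a whole spine
#'
#' Applies the per-vertebra encoding to every labeled vertebra and
#' combines overlapping contributions by voxel-wise maximum.  The input
#' is expected on the 1 mm isotropic grid.
#'
#' @param labels a [label_volume()].
#' @param centroids data frame (`vertebra_id`, `z`, `y`, `x`); computed
#'   from the masks when `NULL`.  Every `vertebra_id` must be present in
#'   `labels`.
#' @return A [volume()] with values in `[0, 255]` (the dense label
#'   volume); persist as MET_FLOAT via [write_mhd()].
#' @export
densify_spine <- function(labels, centroids = NULL) {
  stopifnot(is_label_volume(labels))
  present <- vertebra_labels(labels)
  if (is.null(centroids)) {
    centroids <- do.call(rbind, lapply(present, function(i) {
      cc <- compute_centroid(labels$data == i)
      data.frame(vertebra_id = i, z = cc[1], y = cc[2], x = cc[3])
    }))
  }
  if (!all(centroids$vertebra_id %in% present))
    stop("centroid refers to a label absent from the label volume")
  out <- array(0, dim = dim(labels$data))
  for (k in seq_len(nrow(centroids))) {
    id <- centroids$vertebra_id[k]
    cc <- as.numeric(centroids[k, c("z", "y", "x")])
    idx <- which(labels$data == id, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    geom <- estimate_geometry(labels$data == id, cc)
    out[idx] <- pmax(out[idx], .dense_values(idx, cc, geom))
  }
  volume(out, spacing = labels$spacing, origin = labels$origin)
}
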