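# Stage-2 data preparation: fixed-size regions of interest centered on
# vertebra centroids, plus the two training-time augmentations (elastic
# deformation on a 3x3x3 control grid, additive Gaussian noise with
# uniformly drawn sigma).

#' Crop a fixed-size ROI around a centroid
#'
#' The crop is centered at `round(centroid)`: its 0-based offset in the
#' parent volume is `round(centroid) - size/2`.  Voxels sourced outside
#' the parent are zero-filled.  For a label volume with `vertebra_id`
#' given, only that vertebra is retained, as a binary target.
#'
#' @param v [volume()] or [label_volume()] on the 1 mm grid.
#' @param centroid numeric (z, y, x), 0-based.
#' @param size ROI size (z, y, x); default 80 x 128 x 112.
#' @param vertebra_id for label input: the target vertebra.
#' @return A `roi_crop`: list with `data` (array of `size`), `offset`
#'   (0-based integer (z, y, x)) and `vertebra_id`.
#' @export
crop_roi <- function(v, centroid, size = c(80, 128, 112), vertebra_id = NULL) {
  data <- vol_data(v)
  d <- dim(data)
  centroid <- as.numeric(centroid)
  if (any(centroid < 0) || any(centroid > d - 1))
    stop("centroid outside volume bounds")
  size <- as.integer(size)
  offset <- as.integer(round(centroid) - size %/% 2L)
  out <- array(0, size)
  src_lo <- pmax(offset, 0L)                 # 0-based inclusive
  src_hi <- pmin(offset + size - 1L, d - 1L)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - offset
    block <- data[(src_lo[1]:src_hi[1]) + 1,
                  (src_lo[2]:src_hi[2]) + 1,
                  (src_lo[3]:src_hi[3]) + 1, drop = FALSE]
    if (!is.null(vertebra_id) && is_label_volume(v)) {
      block <- (block == vertebra_id) * 1
    }
    out[(dst_lo[1] + 1):(dst_lo[1] + dim(block)[1]),
        (dst_lo[2] + 1):(dst_lo[2] + dim(block)[2]),
        (dst_lo[3] + 1):(dst_lo[3] + dim(block)[3])] <- block
  }
  structure(list(data = out, offset = offset, vertebra_id = vertebra_id,
                 size = size),
            class = "roi_crop")
}

#' @export
print.roi_crop <- function(x, ...) {
  cat(sprintf("<roi_crop> %s at offset (%s)%s\n",
              paste(x$size, collapse = "x"),
              paste(x$offset, collapse = ", "),
              if (!is.null(x$vertebra_id))
                paste0(", vertebra ", x$vertebra_id) else ""))
  invisible(x)
}

# Trilinear interpolation of a (g1,g2,g3) control array onto a full grid
# of dims d, with control points spanning the grid (corners aligned).
.interp_control_grid <- function(control, d) {
  g <- dim(control)
  ax <- lapply(1:3, function(a) {
    t <- if (d[a] == 1L) rep(0, d[a])
         else (seq_len(d[a]) - 1) / (d[a] - 1) * (g[a] - 1)
    i0 <- pmin(floor(t), g[a] - 2)
    i0 <- pmax(i0, 0)
    list(i0 = i0, f = t - i0)
  })
  out <- array(0, d)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wz <- if (dz) ax[[1]]$f else 1 - ax[[1]]$f
    wy <- if (dy) ax[[2]]$f else 1 - ax[[2]]$f
    wx <- if (dx) ax[[3]]$f else 1 - ax[[3]]$f
    vals <- control[cbind(rep(ax[[1]]$i0 + 1 + dz, times = d[2] * d[3]),
                          rep(rep(ax[[2]]$i0 + 1 + dy, each = d[1]), times = d[3]),
                          rep(ax[[3]]$i0 + 1 + dx, each = d[1] * d[2]))]
    w <- as.vector(outer(outer(wz, wy), wx))
    out <- out + array(vals * w, d)
  }
  out
}

#' Elastically deform an image/label ROI pair
#'
#' One random smooth displacement field, built from normal displacements
#' at a coarse control grid (default 3 x 3 x 3) interpolated over the
#' ROI, is applied identically to both crops: the image is resampled
#' with trilinear interpolation, the label with nearest-neighbor (so a
#' binary label stays binary).  Reproducible under `seed`.
#'
#' @param image,label `roi_crop`s sharing shape and offset.
#' @param grid control-grid size per axis.
#' @param sd control-point displacement standard deviation, mm
#'   (voxels on the 1 mm grid).
#' @param seed RNG seed (optional).
#' @return List with deformed `image` and `label` crops.
#' @export
elastic_deform_pair <- function(image, label, grid = c(3, 3, 3), sd = 3,
                                seed = NULL) {
  stopifnot(inherits(image, "roi_crop"), inherits(label, "roi_crop"),
            all(image$offset == label$offset),
            all(dim(image$data) == dim(label$data)))
  if (!is.null(seed)) set.seed(seed)
  d <- dim(image$data)
  disp <- lapply(1:3, function(a) {
    if (sd == 0) array(0, d)
    else .interp_control_grid(array(rnorm(prod(grid), 0, sd), grid), d)
  })
  img <- image
  lab <- label
  img$data <- cpp_warp(image$data * 1.0, disp[[1]], disp[[2]], disp[[3]], 1L)
  lab$data <- cpp_warp(label$data * 1.0, disp[[1]], disp[[2]], disp[[3]], 0L)
  list(image = img, label = lab)
}

#' Add Gaussian noise to a normalized ROI
#'
#' Draws `sigma ~ U(0, sigma_max)` once per ROI and adds `N(0, sigma^2)`
#' noise per voxel.  Intended for intensities already normalized to
#' `[0, 1]` (see [normalize_intensity()]).
#'
#' @param image a `roi_crop`.
#' @param seed RNG seed (optional).
#' @param sigma_max upper bound of the uniform sigma distribution.
#' @return The noisy `roi_crop`.
#' @export
add_gaussian_noise <- function(image, seed = NULL, sigma_max = 0.1) {
  stopifnot(inherits(image, "roi_crop"))
  if (!is.null(seed)) set.seed(seed)
  sigma <- runif(1, 0, sigma_max)
  out <- image
  out$data <- image$data + rnorm(length(image$data), 0, sigma)
  out
}
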