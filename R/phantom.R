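# Synthetic spine phantom: a cranio-caudal stack of vertebra-like bodies
# (ellipsoid plus a posterior rectangular process) with known instance
# masks and centroids, used to exercise every stage of the pipeline
# without external data.

#' Specification of a synthetic spine phantom
#'
#' Defaults emulate a thoracolumbar stack (T1..L5): 17 vertebrae whose
#' in-plane radii grow cranio-caudally from 10 to 18 mm and heights from
#' 18 to 30 mm, separated by intervertebral gaps, over a soft-tissue
#' background with additive Gaussian noise.  When `n_vertebrae` differs
#' from 17 the radius/height ramps are interpolated over the same ranges.
#'
#' @param n_vertebrae number of vertebrae (>= 1).
#' @param body_radius_mm per-level in-plane body radius, mm.
#' @param body_height_mm per-level body height (z extent), mm.
#' @param gap_mm intervertebral gap along z, mm; must be > 0.
#' @param process_length_mm posterior process length, mm.
#' @param fg_intensity,bg_intensity foreground (bone) and background
#'   intensities, HU-like units.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param spacing voxel spacing (z, y, x), mm.
#' @param seed RNG seed; the generator is fully reproducible.
#' @return A `spine_phantom_spec` list.
#' @export
spine_phantom_spec <- function(n_vertebrae = 17,
                               body_radius_mm = NULL,
                               body_height_mm = NULL,
                               gap_mm = 4,
                               process_length_mm = 12,
                               fg_intensity = 400,
                               bg_intensity = 50,
                               noise_sd = 15,
                               spacing = c(1, 1, 1),
                               seed = 1) {
  n <- as.integer(n_vertebrae)
  if (n < 1L) stop("n_vertebrae must be >= 1")
  if (is.null(body_radius_mm)) body_radius_mm <- seq(10, 18, length.out = n)
  if (is.null(body_height_mm)) body_height_mm <- seq(18, 30, length.out = n)
  if (length(body_radius_mm) != n || length(body_height_mm) != n)
    stop("radius/height lists must have length n_vertebrae")
  if (any(body_radius_mm <= 0) || any(body_height_mm <= 0))
    stop("radii and heights must be positive")
  if (gap_mm <= 0)
    stop("gap_mm must be > 0: adjacent vertebral bodies would overlap")
  if (process_length_mm <= 0) stop("process_length_mm must be positive")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("invalid spacing")
  structure(list(n_vertebrae = n,
                 body_radius_mm = as.numeric(body_radius_mm),
                 body_height_mm = as.numeric(body_height_mm),
                 gap_mm = gap_mm,
                 process_length_mm = process_length_mm,
                 fg_intensity = fg_intensity,
                 bg_intensity = bg_intensity,
                 noise_sd = noise_sd,
                 spacing = spacing,
                 seed = as.integer(seed)),
            class = "spine_phantom_spec")
}

#' Generate a synthetic spine phantom
#'
#' Each vertebra is one connected component: an ellipsoid body of the
#' specified per-level radius and height plus a posterior rectangular
#' process, labeled 1..n in cranio-caudal order and pairwise disjoint.
#' The image is `bg + (fg - bg) * mask + N(0, noise_sd)`.  Returned
#' centroids are the exact voxel-mean centroids of each labeled mask in
#' 0-based (z, y, x) voxel coordinates.
#'
#' @param spec a [spine_phantom_spec()].
#' @return A list with elements `image` ([volume()]), `labels`
#'   ([label_volume()]) and `centroids` (data frame with columns
#'   `vertebra_id`, `z`, `y`, `x`).
#' @export
generate_spine_phantom <- function(spec = spine_phantom_spec()) {
  stopifnot(inherits(spec, "spine_phantom_spec"))
  set.seed(spec$seed)
  sp <- spec$spacing
  margin <- 4
  r <- spec$body_radius_mm
  h <- spec$body_height_mm
  n <- spec$n_vertebrae
  rmax <- max(r)
  proc_w <- 8   # process width in x, mm
  ny <- ceiling((2 * rmax + spec$process_length_mm + 2 * margin) / sp[2])
  nx <- ceiling((2 * rmax + 2 * margin) / sp[3])
  z_total <- 2 * margin + sum(h) + (n - 1) * spec$gap_mm
  nz <- ceiling(z_total / sp[1])
  cy <- margin + rmax                      # body axis position, mm
  cx <- nx * sp[3] / 2
  lab <- array(0L, dim = c(nz, ny, nx))
  zs <- (seq_len(nz) - 1) * sp[1]          # physical voxel-center positions
  ys <- (seq_len(ny) - 1) * sp[2]
  xs <- (seq_len(nx) - 1) * sp[3]
  z0 <- margin
  for (i in seq_len(n)) {
    cz <- z0 + h[i] / 2
    zi <- which(abs(zs - cz) <= h[i] / 2)
    for (z in zi) {
      dz <- zs[z] - cz
      rz <- r[i] * sqrt(max(0, 1 - (dz / (h[i] / 2))^2))
      inpl <- outer((ys - cy)^2, (xs - cx)^2, "+") <= rz^2
      if (abs(dz) <= h[i] / 4) {
        # posterior process: overlaps the body so the component is connected
        yr <- ys >= cy + 0.8 * r[i] - 2 & ys <= cy + r[i] + spec$process_length_mm
        xr <- abs(xs - cx) <= proc_w / 2
        inpl <- inpl | outer(yr, xr, "&")
      }
      sl <- lab[z, , ]
      sl[inpl] <- i
      lab[z, , ] <- sl
    }
    z0 <- z0 + h[i] + spec$gap_mm
  }
  img <- spec$bg_intensity + (spec$fg_intensity - spec$bg_intensity) * (lab > 0)
  if (spec$noise_sd > 0)
    img <- img + rnorm(length(img), 0, spec$noise_sd)
  dim(img) <- dim(lab)
  labels <- label_volume(lab, spacing = sp)
  cents <- do.call(rbind, lapply(seq_len(n), function(i) {
    cc <- compute_centroid(lab == i)
    data.frame(vertebra_id = i, z = cc[1], y = cc[2], x = cc[3])
  }))
  list(image = volume(img, spacing = sp), labels = labels, centroids = cents)
}

#' Write a phantom triplet to disk
#'
#' Writes `image.mhd`, `labels.mhd` and `centroids.csv` under `dir`.
#'
#' @param phantom output of [generate_spine_phantom()].
#' @param dir output directory (created if needed).
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mhd(phantom$image, file.path(dir, "image.mhd"),
            element_type = "MET_SHORT")
  write_mhd(phantom$labels, file.path(dir, "labels.mhd"))
  write_centroids(phantom$centroids, file.path(dir, "centroids.csv"))
  invisible(dir)
}

#' Read / write centroid tables
#'
#' CSV with columns `vertebra_id`, `z`, `y`, `x`; coordinates are 0-based
#' voxel indices on the 1 mm isotropic grid.
#'
#' @param centroids data frame as returned by [generate_spine_phantom()]
#'   or [aggregate_centroids()].
#' @param path CSV file path.
#' @export
write_centroids <- function(centroids, path) {
  write.csv(centroids[, c("vertebra_id", "z", "y", "x")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("vertebra_id", "z", "y", "x") %in% names(df)))
  df
}
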