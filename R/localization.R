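# Stage 1: vertebra localization.  The 2D network regresses a dense
# centroid-proximity map per transversal slice from a stack of 2k+1
# neighboring slices; the aggregation procedure then decodes centroids
# from the predicted dense volume: per-slice maxima form a z profile,
# Savitzky-Golay smoothing suppresses outliers, profile peaks give the
# centroid slices, and on each peak slice least-squares circle fits to
# iso-intensity contours of the thresholded map give the in-plane
# center.

#' Build a 2k+1 slice stack
#'
#' Channels are slices `z - k .. z + k` in order; neighbors falling
#' outside the volume are all-zero.
#'
#' @param v a [volume()] (1 mm grid) or 3D array.
#' @param z 0-based transversal slice index.
#' @param k half-width (default 4, i.e. 9 channels).
#' @return `(H, W, 2k+1)` array.
#' @export
build_slice_stack <- function(v, z, k = 4) {
  data <- vol_data(v)
  nz <- dim(data)[1]
  if (z < 0 || z >= nz) stop("slice index out of range")
  out <- array(0, c(dim(data)[2], dim(data)[3], 2 * k + 1))
  for (c in seq_len(2 * k + 1)) {
    zi <- z - k + (c - 1)
    if (zi >= 0 && zi < nz) out[, , c] <- data[zi + 1, , ]
  }
  out
}

#' Map CT intensities to [0, 1]
#'
#' Linear windowing used to normalize network inputs; values outside the
#' window are clipped.
#'
#' @param x numeric array.
#' @param window intensity window (default -1000..2000 HU).
#' @export
normalize_intensity <- function(x, window = c(-1000, 2000)) {
  pmin(pmax((x - window[1]) / (window[2] - window[1]), 0), 1)
}

#' Predict a dense centroid map for a whole volume
#'
#' Runs the 2D network slice by slice on normalized 2k+1 stacks and
#' rescales the sigmoid output to the 0..255 dense-label scale.
#'
#' @param v a [volume()] on the 1 mm grid.
#' @param net a 2D [build_dense_unet()] network.
#' @param window normalization window passed to [normalize_intensity()].
#' @return A [volume()] with values in `[0, 255]`, same shape as `v`.
#' @export
predict_dense <- function(v, net, window = c(-1000, 2000)) {
  stopifnot(inherits(net, "dense_unet"), net$cfg$dims == 2L)
  k <- (net$cfg$in_channels - 1L) %/% 2L
  data <- vol_data(v)
  out <- array(0, dim(data))
  for (z in seq_len(dim(data)[1]) - 1L) {
    stack <- normalize_intensity(build_slice_stack(data, z, k), window)
    out[z + 1, , ] <- predict(net, stack) * 255
  }
  volume(out, spacing = vol_spacing(v), origin = if (inherits(v, "spine_volume")) v$origin else c(0, 0, 0))
}

#' Per-slice maximum profile of a dense volume
#' @param L dense label [volume()] or 3D array.
#' @return Numeric vector, one per-slice maximum per transversal slice.
#' @export
max_profile <- function(L) {
  data <- vol_data(L)
  apply(data, 1, max)
}

#' Savitzky-Golay smoothing of a slice-maximum profile
#'
#' @param p numeric profile.
#' @param window odd filter length, `polyorder < window <= length(p)`.
#' @param polyorder polynomial order; the filter reproduces polynomials
#'   up to this order exactly.
#' @export
smooth_profile <- function(p, window = 11, polyorder = 3) {
  if (window %% 2 != 1) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (window > length(p)) stop("window exceeds profile length")
  as.numeric(signal::sgolayfilt(p, p = polyorder, n = window))
}

#' Peaks of a smoothed profile
#'
#' Local maxima (plateau-aware: a flat run counts once, at its center)
#' that reach `min_height_frac` of the global maximum, thinned so that
#' retained peaks are at least `min_separation` slices apart (higher
#' peaks win).  Indices are 0-based, ascending.
#'
#' @param p smoothed profile.
#' @param min_height_frac minimum height as a fraction of `max(p)`.
#' @param min_separation minimum slice distance between peaks
#'   (about the smallest vertebra height).
#' @return Integer vector of 0-based slice indices (possibly empty).
#' @export
find_peak_slices <- function(p, min_height_frac = 0.2, min_separation = 10) {
  n <- length(p)
  if (n == 0L || max(p) <= 0) return(integer(0))
  r <- rle(p)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  peaks <- integer(0)
  for (i in seq_len(k)) {
    left <- if (i > 1L) r$values[i - 1L] else -Inf
    right <- if (i < k) r$values[i + 1L] else -Inf
    if (r$values[i] > left && r$values[i] > right)
      peaks <- c(peaks, (starts[i] + ends[i]) %/% 2L)
  }
  peaks <- peaks[p[peaks] >= min_height_frac * max(p) & p[peaks] > 0]
  if (length(peaks) == 0L) return(integer(0))
  keep <- integer(0)
  for (i in peaks[order(p[peaks], decreasing = TRUE)]) {
    if (all(abs(keep - i) >= min_separation)) keep <- c(keep, i)
  }
  sort(keep) - 1L  # to 0-based
}

#' Algebraic (Kasa) least-squares circle fit
#'
#' Solves the linear system `2 y c_y + 2 x c_x + d = y^2 + x^2` in the
#' least-squares sense; exact on noiseless circles.
#'
#' @param y,x point coordinates (>= 3 points, not collinear).
#' @return Named vector `c(y, x, r)`: center and radius.
#' @export
fit_circle_kasa <- function(y, x) {
  if (length(y) < 3L) stop("circle fit needs at least 3 points")
  A <- cbind(2 * y, 2 * x, 1)
  rhs <- y^2 + x^2
  qa <- qr(A)
  if (qa$rank < 3L) stop("degenerate (collinear) points in circle fit")
  sol <- qr.coef(qa, rhs)
  c(y = sol[[1]], x = sol[[2]],
    r = sqrt(max(sol[[3]] + sol[[1]]^2 + sol[[2]]^2, 0)))
}

#' In-plane centroid of a dense slice
#'
#' Zeroes values at or below `threshold` (0..255 scale), then extracts
#' four ring-like iso-intensity contours at levels
#' `S_min*0.1*j + S_max*0.1*(10-j)` for `j = 2..5` (a `+-band` window
#' around each level), fits each contour with a least-squares circle,
#' and returns the mean of the successfully fitted centers.  `S_min` is
#' the minimum of the retained (above-threshold) values.
#'
#' @param slice 2D `(y, x)` matrix of dense values on the 0..255 scale.
#' @param threshold erroneous-response cutoff (default 50).
#' @param band half-width of the contour intensity window.
#' @return `c(y, x)` 0-based, or `NULL` when no value exceeds the
#'   threshold or all contours are degenerate.
#' @export
fit_inplane_center <- function(slice, threshold = 50, band = 5) {
  if (!is.matrix(slice)) stop("slice must be a 2D (y, x) matrix")
  S <- slice
  S[S <= threshold] <- 0
  vals <- S[S > 0]
  if (length(vals) == 0L) return(NULL)
  s_max <- max(vals)
  s_min <- min(vals)
  centers <- list()
  for (j in 2:5) {
    level <- s_min * 0.1 * j + s_max * 0.1 * (10 - j)
    pts <- which(S > 0 & abs(S - level) <= band, arr.ind = TRUE)
    if (nrow(pts) < 3L) next
    fit <- tryCatch(fit_circle_kasa(pts[, 1] - 1, pts[, 2] - 1),
                    error = function(e) NULL)
    if (!is.null(fit)) centers[[length(centers) + 1L]] <- fit[c("y", "x")]
  }
  if (length(centers) == 0L) return(NULL)
  out <- colMeans(do.call(rbind, centers))
  names(out) <- c("y", "x")
  out
}

#' Decode vertebra centroids from a dense volume
#'
#' The full aggregation procedure: slice-maximum profile, Savitzky-Golay
#' smoothing, peak detection for the centroid slices, and per-peak
#' in-plane circle fitting.  Peaks whose slice yields no in-plane center
#' are dropped; vertebra ids are assigned by cranio-caudal rank
#' (ascending z).
#'
#' @param L predicted (or ground-truth) dense label [volume()]/array on
#'   the 1 mm grid.
#' @param threshold,band passed to [fit_inplane_center()].
#' @param sg_window,sg_polyorder passed to [smooth_profile()]; the
#'   window shrinks to the largest odd value not exceeding the slice
#'   count.
#' @param min_height_frac,min_separation passed to [find_peak_slices()].
#' @return Data frame `vertebra_id`, `z`, `y`, `x` (0-based, 1 mm grid),
#'   possibly empty.
#' @export
aggregate_centroids <- function(L, threshold = 50, band = 5,
                                sg_window = 11, sg_polyorder = 3,
                                min_height_frac = 0.2, min_separation = 10) {
  prof <- max_profile(L)
  empty <- data.frame(vertebra_id = integer(0), z = numeric(0),
                      y = numeric(0), x = numeric(0))
  if (max(prof) <= 0) return(empty)
  win <- min(sg_window, length(prof) - (length(prof) + 1) %% 2)
  smoothed <- if (win > sg_polyorder) smooth_profile(prof, win, sg_polyorder) else prof
  zs <- find_peak_slices(smoothed, min_height_frac, min_separation)
  if (length(zs) == 0L) return(empty)
  data <- vol_data(L)
  rows <- lapply(zs, function(z) {
    yx <- fit_inplane_center(data[z + 1, , ], threshold, band)
    if (is.null(yx)) return(NULL)
    data.frame(z = as.numeric(z), y = yx[["y"]], x = yx[["x"]])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$z), , drop = FALSE]
  cbind(vertebra_id = seq_len(nrow(out)), out)
}
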