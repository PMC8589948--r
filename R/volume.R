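#' Scalar CT volume
#'
#' A 3D scalar image grid in (z, y, x) axis order with physical voxel
#' spacing and origin in millimetres.  z indexes transversal (axial)
#' slices.
#'
#' @param data 3D numeric array, (z, y, x) order.
#' @param spacing numeric length-3, mm per voxel along (z, y, x); all > 0.
#' @param origin numeric length-3, physical position of voxel (0,0,0) in mm.
#' @return An object of class `spine_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array (z, y, x)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers")
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume data must be finite")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "spine_volume")
}

#' Vertebra instance label volume
#'
#' Integer instance labels on the same grid conventions as [volume()]:
#' 0 is background and positive labels are vertebrae in cranio-caudal
#' order.
#'
#' @inheritParams volume
#' @return An object of class `spine_label_volume` (also a `spine_volume`).
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("label data must be a 3D array (z, y, x)")
  if (anyNA(data) || any(data < 0) || any(data != round(data)))
    stop("labels must be non-negative integers")
  storage.mode(data) <- "integer"
  v <- volume(data, spacing, origin)
  class(v) <- c("spine_label_volume", class(v))
  v
}

#' @export
print.spine_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d (z,y,x), spacing %s mm\n",
              class(x)[1], d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  if (is_label_volume(x))
    cat("labels:", paste(vertebra_labels(x), collapse = " "), "\n")
  invisible(x)
}

#' Test for a label volume
#' @param x object.
#' @export
is_label_volume <- function(x) inherits(x, "spine_label_volume")

#' Present vertebra labels, in increasing (cranio-caudal) order
#' @param x a `spine_label_volume`.
#' @export
vertebra_labels <- function(x) {
  u <- sort(unique(as.integer(x$data)))
  u[u > 0L]
}

vol_data <- function(v) if (inherits(v, "spine_volume")) v$data else v

vol_spacing <- function(v, default = c(1, 1, 1)) {
  if (inherits(v, "spine_volume")) v$spacing else default
}
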