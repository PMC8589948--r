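# Resampling between the native anisotropic grid and the 1 mm isotropic
# working grid.  Output shapes follow round(shape * spacing / target);
# sampling uses voxel-center alignment.

#' Resample a volume to 1 mm isotropic resolution
#'
#' Images are interpolated linearly, label volumes with nearest-neighbor
#' interpolation (which never introduces new label values).  The output
#' shape along each axis is `round(shape * spacing)`.
#'
#' @param v a `spine_volume` or `spine_label_volume`.
#' @param mode `"linear"` or `"nearest"`; defaults to `"nearest"` for
#'   label volumes and `"linear"` otherwise.  Linear interpolation of a
#'   label volume is a contract violation and errors.
#' @param target_spacing target spacing in mm (default 1 mm isotropic).
#' @return A volume of the same type on the target grid.
#' @export
resample_isotropic <- function(v, mode = NULL, target_spacing = c(1, 1, 1)) {
  stopifnot(inherits(v, "spine_volume"))
  if (is.null(mode)) mode <- if (is_label_volume(v)) "nearest" else "linear"
  mode <- match.arg(mode, c("linear", "nearest"))
  if (is_label_volume(v) && mode == "linear")
    stop("label volumes must be resampled with mode = \"nearest\"")
  out_dim <- as.integer(round(dim(v$data) * v$spacing / target_spacing))
  out_dim <- pmax(out_dim, 1L)
  .resample_volume(v, out_dim, target_spacing, mode)
}

#' Resample a label volume onto a reference grid
#'
#' Nearest-neighbor resampling onto the shape and spacing of `reference`
#' (typically the original native-resolution scan), used to return a
#' merged segmentation from the isotropic working grid to the native one.
#'
#' @param v a `spine_label_volume` (or `spine_volume`).
#' @param reference a volume carrying the target shape and spacing.
#' @return `v` resampled to the reference grid.
#' @export
resample_to_reference <- function(v, reference) {
  stopifnot(inherits(v, "spine_volume"), inherits(reference, "spine_volume"))
  .resample_volume(v, dim(reference$data), reference$spacing, "nearest",
                   origin = reference$origin)
}

.resample_volume <- function(v, out_dim, out_spacing, mode, origin = v$origin) {
  x <- v$data
  storage.mode(x) <- "double"
  out <- cpp_resample(x, as.integer(out_dim), as.numeric(v$spacing),
                      as.numeric(out_spacing),
                      if (mode == "nearest") 0L else 1L)
  if (is_label_volume(v)) {
    label_volume(out, out_spacing, origin)
  } else {
    volume(out, out_spacing, origin)
  }
}
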