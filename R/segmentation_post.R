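# Stage-2 postprocessing: probability maps -> clean binary vertebra
# masks.  The binarization threshold is level-dependent (upper/mid
# thoracic vertebrae are small inside the fixed ROI, so a permissive 0.5
# is used for T1-T9 and a strict 0.9 for T10-L5), and isolated objects
# below 500 voxels -- typically responses to the neighboring vertebrae
# inside the ROI -- are removed.

#' A per-vertebra probability prediction
#'
#' @param prob array of probabilities in (0, 1) (ROI-sized).
#' @param offset 0-based (z, y, x) crop offset in the parent volume.
#' @param vertebra_id instance id.
#' @param level_group `"T1-T9"` or `"T10-L5"`; when `NULL` it is derived
#'   from `vertebra_id` for a full 17-vertebra (T1..L5) stack
#'   (`n_vertebrae = 17`), otherwise it must be given explicitly.
#' @param n_vertebrae total vertebrae in the stack, used for the
#'   automatic mapping.
#' @return A `vertebra_prediction`.
#' @export
vertebra_prediction <- function(prob, offset, vertebra_id, level_group = NULL,
                                n_vertebrae = 17) {
  if (is.null(level_group)) {
    if (n_vertebrae != 17)
      stop("level_group must be given explicitly unless the stack has ",
           "17 vertebrae (T1..L5)")
    level_group <- if (vertebra_id <= 9) "T1-T9" else "T10-L5"
  }
  if (!level_group %in% c("T1-T9", "T10-L5"))
    stop("unknown level group: ", level_group)
  structure(list(prob = prob, offset = as.integer(offset),
                 vertebra_id = as.integer(vertebra_id),
                 level_group = level_group),
            class = "vertebra_prediction")
}

#' Threshold a probability prediction
#'
#' Level-dependent binarization: threshold 0.5 for group T1-T9 and 0.9
#' for T10-L5; values strictly greater than the threshold map to 1,
#' values at or below it to 0.
#'
#' @param p a [vertebra_prediction()].
#' @return A binary `roi_crop`.
#' @export
threshold_prediction <- function(p) {
  stopifnot(inherits(p, "vertebra_prediction"))
  t <- switch(p$level_group, "T1-T9" = 0.5, "T10-L5" = 0.9,
              stop("unknown level group"))
  structure(list(data = (p$prob > t) * 1L, offset = p$offset,
                 vertebra_id = p$vertebra_id, size = dim(p$prob)),
            class = "roi_crop")
}

#' Remove small connected components
#'
#' Deletes stand-alone objects strictly smaller than `min_voxels`
#' (components of exactly `min_voxels` are kept).  Idempotent.
#'
#' @param mask binary `roi_crop` or 3D array.
#' @param min_voxels size cutoff (default 500).
#' @param connectivity 26 (default) or 6.
#' @return Object of the same type with small components removed.
#' @export
remove_small_components <- function(mask, min_voxels = 500, connectivity = 26) {
  is_roi <- inherits(mask, "roi_crop")
  data <- if (is_roi) mask$data else mask
  m <- array(as.integer(data != 0), dim(data))
  lab <- cpp_label_components(m, as.integer(connectivity))
  if (max(lab) > 0L) {
    sizes <- tabulate(lab)
    drop <- which(sizes < min_voxels)
    if (length(drop)) data[lab %in% drop] <- 0
  }
  if (is_roi) {
    mask$data <- data
    mask
  } else data
}
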