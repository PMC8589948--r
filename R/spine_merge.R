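#' Merge per-vertebra masks into a labeled spine
#'
#' Starting from an empty volume, each binary ROI mask is assigned its
#' vertebra id voxel by voxel, in the given cranio-caudal order, only
#' where the target voxel is still empty -- so a voxel claimed by two
#' adjacent instances keeps the earlier (more cranial) label.  Crop
#' regions outside the parent bounds are ignored.
#'
#' @param parts list of binary `roi_crop`s, each with a distinct
#'   `vertebra_id`, ordered cranio-caudally.
#' @param shape parent volume shape (z, y, x) on the 1 mm grid.
#' @param spacing,origin grid metadata of the output.
#' @return A [label_volume()].
#' @export
merge_spine <- function(parts, shape, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  ids <- vapply(parts, function(p) as.integer(p$vertebra_id), integer(1))
  if (anyDuplicated(ids)) stop("duplicate vertebra_id in parts")
  out <- array(0L, shape)
  for (p in parts) {
    d <- dim(p$data)
    src_lo <- pmax(p$offset, 0L)                     # 0-based in parent
    src_hi <- pmin(p$offset + d - 1L, shape - 1L)
    if (any(src_lo > src_hi)) next
    crop_lo <- src_lo - p$offset
    blk <- out[(src_lo[1]:src_hi[1]) + 1,
               (src_lo[2]:src_hi[2]) + 1,
               (src_lo[3]:src_hi[3]) + 1, drop = FALSE]
    msk <- p$data[(crop_lo[1] + 1):(crop_lo[1] + dim(blk)[1]),
                  (crop_lo[2] + 1):(crop_lo[2] + dim(blk)[2]),
                  (crop_lo[3] + 1):(crop_lo[3] + dim(blk)[3]), drop = FALSE]
    blk[msk != 0 & blk == 0L] <- as.integer(p$vertebra_id)
    out[(src_lo[1]:src_hi[1]) + 1,
        (src_lo[2]:src_hi[2]) + 1,
        (src_lo[3]:src_hi[3]) + 1] <- blk
  }
  label_volume(out, spacing, origin)
}
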