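#' Fuse blob objects with the regression region mask
#'
#' For each Hessian-DoG object, the overlap fraction is the share of its
#' pixels inside the region mask. Objects with fraction `>= o_thr`
#' (`> o_thr` when `strict`) are retained with their full pixel extent —
#' objects are not clipped to the region, preserving their shape for
#' downstream morphology features.
#'
#' @param objects A `segmented_objects` (or `hdog_segmentation`).
#' @param region_mask Binary matrix from thresholding the predicted
#'   proximity map; same shape as the segmentation.
#' @param o_thr Overlap threshold in `[0, 1]`, default 0.3.
#' @param strict Use strict `>` instead of `>=` at the boundary.
#' @return An object of class `final_segmentation`: `mask` (union of
#'   retained objects), `objects`, `blobs`, `overlap` (per retained
#'   object), plus the rejected count.
#' @export
combine_segmentation <- function(objects, region_mask, o_thr = 0.3,
                                 strict = FALSE) {
  stopifnot(inherits(objects, "segmented_objects"))
  region_mask <- as.matrix(region_mask) != 0
  if (!all(dim(region_mask) == objects$shape))
    stop("region mask shape does not match the segmentation")
  if (o_thr < 0 || o_thr > 1) stop("o_thr must lie in [0, 1]")
  keep <- logical(length(objects$objects))
  frac <- numeric(length(objects$objects))
  for (i in seq_along(objects$objects)) {
    pix <- objects$objects[[i]]
    frac[i] <- sum(region_mask[pix]) / length(pix)
    keep[i] <- if (strict) frac[i] > o_thr else frac[i] >= o_thr
  }
  mask <- matrix(0L, objects$shape[1], objects$shape[2])
  for (pix in objects$objects[keep]) mask[pix] <- 1L
  structure(list(mask = mask, objects = objects$objects[keep],
                 blobs = objects$blobs[keep, , drop = FALSE],
                 overlap = frac[keep], rejected = sum(!keep),
                 shape = objects$shape),
            class = "final_segmentation")
}

#' @export
print.final_segmentation <- function(x, ...) {
  cat(sprintf("final_segmentation: %d object(s) retained, %d rejected, %d px\n",
              length(x$objects), x$rejected, sum(x$mask)))
  invisible(x)
}

#' Run the full two-branch segmentation on one image
#'
#' Blob branch ([hdog_segment()]), regression branch
#' ([predict_proximity()] thresholded at `config$p_thr`), and fusion at
#' `config$o_thr`.
#'
#' @param img Normalized [mammogram_image()] or matrix.
#' @param model A trained `mc_regressor`.
#' @param config A [pipeline_config()].
#' @param tile Tile size for full-image inference.
#' @return A `final_segmentation` with the intermediate `hdog` and
#'   `proximity` results attached.
#' @export
segment_image <- function(img, model, config = pipeline_config(),
                          tile = 512L) {
  seg <- hdog_segment(img, config)
  prox <- predict_proximity(model, img, tile = tile,
                            xi = config$xi, alpha = config$alpha)
  region <- threshold_map(prox, config$p_thr)
  fused <- combine_segmentation(seg, region, config$o_thr)
  fused$hdog <- seg
  fused$proximity <- prox
  fused
}
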