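#' Free-response ROC curve over a proximity-threshold sweep
#'
#' For each threshold in the sweep, every image's predicted proximity map is
#' thresholded into a region mask, fused with that image's blob objects at
#' `o_thr`, and the retained objects are matched against ground truth. TPR
#' is pooled over images (`sum TP / sum truth objects`); false positives are
#' normalized by the total imaged area in cm^2
#' (`rows * cols * spacing_mm^2 / 100` per image).
#'
#' @param images List of per-image lists with elements `proximity`
#'   (predicted map or matrix), `objects` (a `segmented_objects` from the
#'   blob branch), and `truth` (labeled matrix, or `centroids`/`pixels`
#'   list; point annotations are centroid-only).
#' @param p_grid Descending or ascending vector of proximity thresholds.
#' @param spacing_mm Pixel spacing (mm).
#' @param o_thr Fusion overlap threshold.
#' @param dist_px,iou_min Matching rules (see [match_detections()]).
#' @return Object of class `froc_curve`: data frame `curve` with columns
#'   `p_thr`, `tpr`, `fp_per_cm2`, plus `area_cm2` and `n_truth`.
#' @export
froc_curve <- function(images, p_grid = seq(0.05, 0.95, by = 0.05),
                       spacing_mm = 0.070, o_thr = 0.3, dist_px = 5,
                       iou_min = 0.3) {
  stopifnot(length(images) >= 1)
  p_grid <- sort(unique(p_grid), decreasing = TRUE)
  area <- sum(vapply(images, function(im) {
    sh <- im$objects$shape
    sh[1] * sh[2] * spacing_mm^2 / 100
  }, numeric(1)))
  truth_objs <- lapply(images, function(im) as_objects(im$truth, NULL))
  n_truth <- sum(vapply(truth_objs, function(t) nrow(t$centroids), 1))
  rows <- lapply(p_grid, function(p) {
    tp <- 0L; fp <- 0L
    for (k in seq_along(images)) {
      im <- images[[k]]
      region <- threshold_map(im$proximity, p)
      fused <- combine_segmentation(im$objects, region, o_thr)
      pred <- list(
        centroids = if (length(fused$objects))
          t(vapply(fused$objects, function(pix) {
            n <- fused$shape[1]
            c(mean((pix - 1L) %% n), mean((pix - 1L) %/% n))
          }, numeric(2))) else matrix(numeric(0), ncol = 2),
        pixels = fused$objects)
      m <- match_detections(pred, truth_objs[[k]], dist_px = dist_px,
                            iou_min = iou_min)
      tp <- tp + m$TP; fp <- fp + m$FP
    }
    data.frame(p_thr = p, tpr = if (n_truth) tp / n_truth else NA_real_,
               fp_per_cm2 = fp / area)
  })
  structure(list(curve = do.call(rbind, rows), area_cm2 = area,
                 n_truth = n_truth),
            class = "froc_curve")
}

#' @export
print.froc_curve <- function(x, ...) {
  cat(sprintf("froc_curve: %d threshold(s), %d truth object(s), %.2f cm^2\n",
              nrow(x$curve), x$n_truth, x$area_cm2))
  print.data.frame(utils::head(x$curve, 12))
  invisible(x)
}

#' @export
plot.froc_curve <- function(x, fp_max = NULL, ...) {
  cv <- x$curve[order(x$curve$fp_per_cm2), ]
  graphics::plot(cv$fp_per_cm2, cv$tpr, type = "b", pch = 16,
                 xlab = expression(FP / cm^2), ylab = "TPR",
                 ylim = c(0, 1),
                 xlim = c(0, if (is.null(fp_max)) max(cv$fp_per_cm2) else fp_max),
                 ...)
  invisible(x)
}

#' Normalized partial AUC of an FROC curve
#'
#' Trapezoidal integral of TPR over FP/cm^2 in `fp_range`, divided by the
#' range width so a perfect detector scores 1. The curve is linearly
#' interpolated between points and constant-extrapolated at both ends.
#'
#' @param curve A `froc_curve` or a data frame with `tpr`, `fp_per_cm2`.
#' @param fp_range Integration range, default `c(0, 1)`.
#' @return Scalar in `[0, 1]`.
#' @export
partial_auc <- function(curve, fp_range = c(0, 1)) {
  cv <- if (inherits(curve, "froc_curve")) curve$curve else curve
  if (!nrow(cv)) stop("empty curve")
  o <- order(cv$fp_per_cm2, cv$tpr)
  fp <- cv$fp_per_cm2[o]; tpr <- cv$tpr[o]
  # collapse duplicate FP values to their maximal TPR
  agg <- tapply(tpr, fp, max)
  fp <- as.numeric(names(agg)); tpr <- as.numeric(agg)
  xs <- sort(unique(c(fp_range, fp[fp > fp_range[1] & fp < fp_range[2]])))
  ys <- interp_const_ends(fp, tpr, xs)
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2) /
    diff(fp_range)
}

interp_const_ends <- function(x, y, xout) {
  if (length(x) == 1) return(rep(y, length(xout)))
  stats::approx(x, y, xout = xout, rule = 2)$y
}

#' Bootstrap partial AUC
#'
#' Resamples images with replacement `B` times, recomputes the FROC curve
#' and its partial AUC each time, and reports the bootstrap mean with the
#' 2.5/97.5 percentile confidence bounds.
#'
#' @param images As in [froc_curve()] (>= 2 images).
#' @param B Bootstrap replicates, default 100.
#' @param seed RNG seed.
#' @param fp_range Integration range.
#' @param ... Passed to [froc_curve()].
#' @return Named vector `mean`, `ci_low`, `ci_high`.
#' @export
bootstrap_pauc <- function(images, B = 100L, seed = 1L, fp_range = c(0, 1),
                           ...) {
  stopifnot(length(images) >= 2)
  set.seed(seed)
  vals <- vapply(seq_len(B), function(b) {
    idx <- sample(length(images), replace = TRUE)
    partial_auc(froc_curve(images[idx], ...), fp_range)
  }, numeric(1))
  c(mean = mean(vals),
    ci_low = unname(stats::quantile(vals, 0.025, type = 7)),
    ci_high = unname(stats::quantile(vals, 0.975, type = 7)))
}

#' Operating point of an FROC curve
#'
#' The threshold whose point `(FP/cm^2, TPR)` is closest (Euclidean) to the
#' ideal `(0, 1)`; ties resolve to the larger threshold.
#'
#' @param curve A `froc_curve`.
#' @return The selected `p_thr`.
#' @export
operating_point <- function(curve) {
  cv <- if (inherits(curve, "froc_curve")) curve$curve else curve
  if (!nrow(cv)) stop("empty curve")
  d <- sqrt(cv$fp_per_cm2^2 + (1 - cv$tpr)^2)
  best <- which(d == min(d))
  cv$p_thr[best][which.max(cv$p_thr[best])]
}

#' Write an FROC curve as CSV
#' @param curve A `froc_curve`.
#' @param path Output path.
#' @export
write_froc <- function(curve, path) {
  utils::write.csv(curve$curve, path, row.names = FALSE)
  invisible(path)
}
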