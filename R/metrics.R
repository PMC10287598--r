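#' Intersection over union of two binary masks
#'
#' `|A ∩ B| / |A ∪ B|`; defined as 1 when both masks are empty.
#'
#' @param a,b Binary matrices of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
iou <- function(a, b) {
  a <- as.matrix(a) != 0; b <- as.matrix(b) != 0
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Mean IoU per image
#'
#' Average of the foreground-class IoU and the background-class IoU between
#' prediction and truth.
#'
#' @param pred,truth Binary matrices of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
mean_iou_per_image <- function(pred, truth) {
  pred <- as.matrix(pred) != 0; truth <- as.matrix(truth) != 0
  (iou(pred, truth) + iou(!pred, !truth)) / 2
}

#' IoU per object
#'
#' For each truth object, the prediction object with the largest
#' intersection is found and the IoU of that pair recorded (0 when nothing
#' intersects); the mean over truth objects is returned.
#'
#' @param pred_lab,truth_lab Labeled object matrices (0 = background), as
#'   from [label_components()].
#' @return Scalar; `NA` with a warning when the truth has no objects.
#' @export
iou_per_object <- function(pred_lab, truth_lab) {
  truth_ids <- setdiff(unique(as.vector(truth_lab)), 0L)
  if (!length(truth_ids)) {
    warning("no truth objects; IoU per object undefined")
    return(NA_real_)
  }
  vals <- vapply(truth_ids, function(ti) {
    tpix <- which(truth_lab == ti)
    over <- pred_lab[tpix]
    over <- over[over != 0L]
    if (!length(over)) return(0)
    best <- as.integer(names(which.max(table(over))))
    ppix <- which(pred_lab == best)
    length(intersect(tpix, ppix)) / length(union(tpix, ppix))
  }, numeric(1))
  mean(vals)
}

#' Match detections to ground truth
#'
#' A prediction and a truth object are candidates when their centroid
#' distance is at most `dist_px` pixels (default 5 px = 0.35 mm at
#' 0.070 mm/px) or their IoU is at least `iou_min` (default 0.3). Matching
#' is greedy one-to-one in ascending centroid distance. Truth objects may
#' be bare points (centroid only, empty pixel set).
#'
#' @param pred Either a labeled matrix or a list with `centroids` (n x 2,
#'   0-based row/col) and `pixels` (list of linear index sets).
#' @param truth Same structure for the ground truth.
#' @param shape Image shape (needed when both are given as lists).
#' @param dist_px Distance rule (px).
#' @param iou_min IoU rule.
#' @return List of class `match_result`: `TP`, `FP`, `FN`, `pairs`
#'   (matrix of matched prediction/truth indices and their distance).
#' @export
match_detections <- function(pred, truth, shape = NULL, dist_px = 5,
                             iou_min = 0.3) {
  P <- as_objects(pred, shape); G <- as_objects(truth, shape)
  np <- nrow(P$centroids); nt <- nrow(G$centroids)
  if (np == 0 || nt == 0)
    return(structure(list(TP = 0L, FP = np, FN = nt,
                          pairs = matrix(numeric(0), ncol = 3)),
                     class = "match_result"))
  cand <- NULL
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    d <- sqrt(sum((P$centroids[i, ] - G$centroids[j, ])^2))
    ok <- d <= dist_px
    if (!ok && length(P$pixels) >= i && length(G$pixels) >= j &&
        length(G$pixels[[j]])) {
      inter <- length(intersect(P$pixels[[i]], G$pixels[[j]]))
      if (inter > 0) {
        un <- length(P$pixels[[i]]) + length(G$pixels[[j]]) - inter
        ok <- inter / un >= iou_min
      }
    }
    if (ok) cand <- rbind(cand, c(i, j, d))
  }
  if (is.null(cand))
    return(structure(list(TP = 0L, FP = np, FN = nt,
                          pairs = matrix(numeric(0), ncol = 3)),
                     class = "match_result"))
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  usedP <- logical(np); usedT <- logical(nt)
  pairs <- NULL
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!usedP[i] && !usedT[j]) {
      usedP[i] <- TRUE; usedT[j] <- TRUE
      pairs <- rbind(pairs, cand[k, ])
    }
  }
  structure(list(TP = sum(usedT), FP = sum(!usedP), FN = sum(!usedT),
                 pairs = pairs),
            class = "match_result")
}

# Normalize the two accepted object representations.
as_objects <- function(x, shape) {
  if (is.list(x) && !is.null(x$centroids)) {
    cent <- matrix(x$centroids, ncol = 2)
    pix <- if (is.null(x$pixels)) rep(list(integer(0)), nrow(cent)) else x$pixels
    return(list(centroids = cent, pixels = pix))
  }
  lab <- as.matrix(x)
  list(centroids = label_centroids(lab), pixels = label_pixel_sets(lab))
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: TP %d, FP %d, FN %d\n", x$TP, x$FP, x$FN))
  invisible(x)
}
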