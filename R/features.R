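#' Extract a fixed-size ROI
#'
#' A `size` x `size` window centered on the bounding box center; when the
#' window would exceed an image border it is shifted minimally to fit.
#' Images smaller than `size` are reflect-padded first (flagged).
#'
#' @param image Normalized image matrix or [mammogram_image()].
#' @param mask Binary segmentation mask of the same shape.
#' @param bbox Bounding box `c(row0, col0, row1, col1)`, 0-based inclusive.
#' @param size Window side (px), default 256.
#' @param label Optional benign/malignant label carried on the ROI.
#' @param patient_id Optional patient identifier.
#' @return Object of class `mc_roi`: `image`, `mask` (both `size x size`),
#'   `center` (0-based), `label`, `patient_id`, `padded` flag.
#' @export
extract_roi <- function(image, mask, bbox, size = 256L, label = NA,
                        patient_id = NA_character_) {
  img <- as_pixels(image); msk <- as.matrix(mask)
  stopifnot(all(dim(img) == dim(msk)), length(bbox) == 4)
  padded <- FALSE
  if (nrow(img) < size || ncol(img) < size) {
    p <- max(size - nrow(img), size - ncol(img))
    img <- reflect_pad(img, p)[seq_len(max(nrow(img), size)) ,
                               seq_len(max(ncol(img), size)), drop = FALSE]
    msk <- reflect_pad(msk, p)[seq_len(nrow(img)), seq_len(ncol(img)),
                               drop = FALSE]
    padded <- TRUE
  }
  ctr <- c((bbox[1] + bbox[3]) / 2, (bbox[2] + bbox[4]) / 2)
  r0 <- round(ctr[1]) - size %/% 2
  c0 <- round(ctr[2]) - size %/% 2
  r0 <- min(max(r0, 0), nrow(img) - size)
  c0 <- min(max(c0, 0), ncol(img) - size)
  structure(list(image = img[r0 + seq_len(size), c0 + seq_len(size)],
                 mask = msk[r0 + seq_len(size), c0 + seq_len(size)],
                 center = ctr, label = label, patient_id = patient_id,
                 padded = padded),
            class = "mc_roi")
}

# Central moment mu_pq of a binary mask (0-based coordinates).
central_moments <- function(mask) {
  idx <- which(mask != 0)
  n <- nrow(mask)
  r <- (idx - 1L) %% n; c <- (idx - 1L) %/% n
  rb <- mean(r); cb <- mean(c)
  mu <- function(p, q) sum((r - rb)^p * (c - cb)^q)
  list(area = length(idx), rbar = rb, cbar = cb, mu = mu)
}

#' Hu invariant moments of a binary mask
#'
#' The seven moment invariants computed from normalized central moments;
#' invariant to translation, scale, and rotation.
#'
#' @param mask Binary matrix with at least one foreground pixel.
#' @return Numeric vector of length 7.
#' @export
hu_moments <- function(mask) {
  cm <- central_moments(mask)
  m00 <- cm$area
  eta <- function(p, q) cm$mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

# Ellipse-equivalent shape descriptors from the central second-moment
# tensor of a pixel set.
ellipse_props <- function(mask) {
  cm <- central_moments(mask)
  a <- cm$area
  cov <- matrix(c(cm$mu(2, 0), cm$mu(1, 1), cm$mu(1, 1), cm$mu(0, 2)),
                2, 2) / a
  ev <- eigen(cov, symmetric = TRUE)
  l1 <- max(ev$values[1], 0); l2 <- max(ev$values[2], 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- if (l1 > 0) sqrt(1 - l2 / l1) else 0
  # orientation of the major axis w.r.t. the row axis, in (-90, 90]
  theta <- 0.5 * atan2(2 * cov[1, 2], cov[1, 1] - cov[2, 2]) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  list(major = major, minor = minor, eccentricity = ecc,
       orientation = theta, inertia = c(l1, l2))
}

# Pixel count of the filled convex hull of a mask: pixels whose centers
# fall inside the hull polygon, unioned with the mask itself (so the hull
# always contains the region and solidity of a convex region is ~1).
convex_hull_area <- function(mask) {
  idx <- which(mask != 0)
  n <- nrow(mask)
  r <- (idx - 1L) %% n; c <- (idx - 1L) %/% n
  if (length(idx) <= 2) return(length(idx))
  pts <- unique(cbind(r, c))
  if (nrow(pts) <= 2) return(length(idx))
  h <- grDevices::chull(pts[, 2], pts[, 1])
  poly <- pts[h, , drop = FALSE]
  if (nrow(poly) < 3) return(length(idx))
  r0 <- min(poly[, 1]); r1 <- max(poly[, 1])
  c0 <- min(poly[, 2]); c1 <- max(poly[, 2])
  grid <- as.matrix(expand.grid(row = r0:r1, col = c0:c1))
  inside <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), grid + 0.0)
  hull <- matrix(0L, n, ncol(mask))
  hit <- grid[inside, , drop = FALSE]
  if (nrow(hit)) hull[cbind(hit[, 1] + 1L, hit[, 2] + 1L)] <- 1L
  sum(hull | (mask != 0))
}

#' The 31 morphology and intensity features of an ROI
#'
#' Regional features (17) describe all segmented microcalcifications as one
#' region: foreground area, convex hull area, ellipse-equivalent major and
#' minor axis length, orientation, eccentricity, solidity, the two inertia
#' moments (eigenvalues of the central second-moment tensor), the seven Hu
#' moments, and the object count. Per-object features (14) are the mean and
#' standard deviation over 8-connected components of area, major and minor
#' axis, maximum, minimum, and mean interior intensity, and eccentricity
#' (the standard deviation of a single object is 0).
#'
#' @param roi An [extract_roi()] result, or a list with `image` and `mask`.
#' @return Named numeric vector of length 31; all `NA` when the mask is
#'   empty (to be imputed downstream).
#' @export
compute_features <- function(roi) {
  img <- roi$image; mask <- as.matrix(roi$mask) != 0
  nm <- feature_names()
  if (!any(mask)) {
    out <- rep(NA_real_, 31); names(out) <- nm
    return(out)
  }
  ep <- ellipse_props(mask)
  hull <- convex_hull_area(mask)
  area <- sum(mask)
  lab <- label_components(mask)
  nobj <- max(lab)
  per <- vapply(seq_len(nobj), function(l) {
    om <- lab == l
    oe <- ellipse_props(om)
    vals <- img[om]
    c(area = sum(om), major = oe$major, minor = oe$minor,
      max_int = max(vals), min_int = min(vals), mean_int = mean(vals),
      ecc = oe$eccentricity)
  }, numeric(7))
  agg_mean <- rowMeans(per)
  agg_sd <- apply(per, 1, function(v) if (length(v) > 1) stats::sd(v) else 0)
  out <- c(area, hull, ep$major, ep$minor, ep$orientation,
           ep$eccentricity, area / hull, ep$inertia, hu_moments(mask),
           nobj, agg_mean, agg_sd)
  names(out) <- nm
  out
}

feature_names <- function() {
  c("area", "hull_area", "major_axis", "minor_axis", "orientation",
    "eccentricity", "solidity", "inertia_1", "inertia_2",
    paste0("hu_", 1:7), "n_objects",
    paste0("obj_mean_", c("area", "major", "minor", "max_int", "min_int",
                          "mean_int", "ecc")),
    paste0("obj_sd_", c("area", "major", "minor", "max_int", "min_int",
                        "mean_int", "ecc")))
}

#' Feature table for a set of ROIs
#'
#' @param rois List of [extract_roi()] objects.
#' @return Data frame: 31 feature columns plus `label` and `patient_id`.
#' @export
feature_table <- function(rois) {
  feats <- t(vapply(rois, compute_features, numeric(31)))
  df <- as.data.frame(feats)
  df$label <- unlist(lapply(rois, function(r) r$label))
  df$patient_id <- vapply(rois, function(r) as.character(r$patient_id), "")
  df
}
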