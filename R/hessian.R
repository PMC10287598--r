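# Central finite differences with reflective borders, consistent with the
# convolution border policy.
deriv2_rr <- function(x) {
  xp <- reflect_pad(x, 1L)
  n <- nrow(x); m <- ncol(x)
  xp[3:(n + 2), 2:(m + 1)] - 2 * x + xp[1:n, 2:(m + 1)]
}
deriv2_cc <- function(x) {
  xp <- reflect_pad(x, 1L)
  n <- nrow(x); m <- ncol(x)
  xp[2:(n + 1), 3:(m + 2)] - 2 * x + xp[2:(n + 1), 1:m]
}
deriv2_rc <- function(x) {
  xp <- reflect_pad(x, 1L)
  n <- nrow(x); m <- ncol(x)
  (xp[3:(n + 2), 3:(m + 2)] - xp[3:(n + 2), 1:m] -
     xp[1:n, 3:(m + 2)] + xp[1:n, 1:m]) / 4
}

#' Hessian of a DoG plane
#'
#' Second spatial derivatives of the DoG response at one scale, by central
#' finite differences with reflective borders. The mixed derivative is a
#' single plane, so the field is symmetric by construction.
#'
#' @param dog_plane Numeric matrix (one scale plane of the DoG stack).
#' @return List with matrices `drr`, `dcc`, `drc`.
#' @export
hessian_field <- function(dog_plane) {
  list(drr = deriv2_rr(dog_plane), dcc = deriv2_cc(dog_plane),
       drc = deriv2_rc(dog_plane))
}

#' Hessian convexity-constraint mask
#'
#' A pixel is foreground iff `tr(H) < 0` and (`det(H) < 0` or
#' `det(H) / tr(H)^2 <= h_thr`): the Hessian is either negative definite or
#' has one large negative and one small eigenvalue, selecting bright
#' blob-like and tubular structures. At `tr(H) = 0` the first clause already
#' fails, so the ratio is never evaluated on a zero denominator.
#'
#' Note: with `det >= 0` and `tr < 0` the ratio is analytically at most 1/4,
#' so any `h_thr >= 0.25` (including the default 1.4) reduces the constraint
#' to `tr(H) < 0`. The constraint is still evaluated literally.
#'
#' @param dog_plane DoG plane at one scale, or a precomputed
#'   [hessian_field()].
#' @param h_thr Ratio threshold.
#' @return Binary integer matrix.
#' @export
hessian_constraint_mask <- function(dog_plane, h_thr = 1.4) {
  H <- if (is.list(dog_plane)) dog_plane else hessian_field(dog_plane)
  tr <- H$drr + H$dcc
  det <- H$drr * H$dcc - H$drc^2
  mask <- tr < 0 & (det < 0 | ifelse(tr != 0, det / tr^2 <= h_thr, FALSE))
  mode(mask) <- "integer"
  mask
}

#' Extract per-blob objects from the constraint masks
#'
#' For each blob, the 8-connected component of the constraint mask at the
#' blob's own scale that spans the blob location is taken as the object.
#' Blobs whose seed pixel is background are dropped (with a message). All
#' components are unioned into one merged mask; the blob link is retained.
#'
#' @param blobs A `blob_set` (with `scale_index`).
#' @param masks List of binary constraint masks, one per DoG scale plane.
#' @param quiet Suppress the dropped-seed message.
#' @return List of class `segmented_objects`: `objects` (list of 1-based
#'   pixel-index vectors), `blobs` (the seeding rows), `mask` (merged binary
#'   matrix), `dropped` (count).
#' @export
extract_blob_objects <- function(blobs, masks, quiet = FALSE) {
  if (nrow(blobs) && max(blobs$scale_index) > length(masks))
    stop("missing constraint mask for some blob scale")
  shape <- if (length(masks)) dim(masks[[1]]) else c(0L, 0L)
  labs <- lapply(masks, label_components)
  objects <- list(); kept <- integer(0); dropped <- 0L
  merged <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(nrow(blobs))) {
    li <- labs[[blobs$scale_index[i]]]
    lab <- li[blobs$row[i] + 1L, blobs$col[i] + 1L]
    if (lab == 0L) { dropped <- dropped + 1L; next }
    pix <- which(li == lab)
    objects[[length(objects) + 1L]] <- pix
    kept <- c(kept, i)
    merged[pix] <- 1L
  }
  if (dropped && !quiet)
    message(dropped, " blob seed(s) fell on constraint background; dropped")
  structure(list(objects = objects,
                 blobs = blobs[kept, , drop = FALSE],
                 mask = merged, dropped = dropped, shape = shape),
            class = "segmented_objects")
}

#' @export
print.segmented_objects <- function(x, ...) {
  cat(sprintf("segmented_objects: %d object(s), %d px foreground, %d dropped seed(s)\n",
              length(x$objects), sum(x$mask), x$dropped))
  invisible(x)
}

#' Hessian-constrained multiscale blob segmentation
#'
#' The full blob branch: scale sequence, Gaussian scale space, normalized
#' DoG stack, 3-D maxima detection with `T_dog`, overlap pruning with
#' `O_dog`, per-scale Hessian constraint masks with `h_thr`, and per-blob
#' object extraction merged into one binary mask.
#'
#' @param img A normalized [mammogram_image()] or matrix on `[0, 1]`.
#' @param config A [pipeline_config()].
#' @return An object of class `hdog_segmentation`: fields of
#'   [extract_blob_objects()] plus `all_blobs`, `scales`, `config`.
#' @export
hdog_segment <- function(img, config = pipeline_config()) {
  x <- as_pixels(img)
  scales <- build_scale_sequence(config$sigma_min, config$sigma_max, config$k)
  L <- gaussian_scale_space(x, scales)
  dog <- normalized_dog_stack(L, scales)
  blobs <- detect_blobs(dog, config$T_dog)
  blobs <- prune_overlapping_blobs(blobs, config$O_dog)
  masks <- lapply(seq_len(dim(dog$values)[3]), function(n)
    hessian_constraint_mask(dog$values[, , n], config$h_thr))
  seg <- extract_blob_objects(blobs, masks, quiet = TRUE)
  seg$all_blobs <- blobs
  seg$scales <- scales
  seg$config <- config
  class(seg) <- c("hdog_segmentation", class(seg))
  seg
}

#' @export
print.hdog_segmentation <- function(x, ...) {
  cat(sprintf("Hessian-DoG segmentation: %d object(s) from %d blob(s), scales %s\n",
              length(x$objects), nrow(x$all_blobs),
              paste(sprintf("%.2f", x$scales), collapse = " ")))
  invisible(x)
}

#' @export
plot.hdog_segmentation <- function(x, img = NULL, ...) {
  if (!is.null(img)) {
    graphics::image(t(as_pixels(img))[, nrow(x$mask):1], col = gray.colors(256),
                    axes = FALSE, asp = nrow(x$mask) / ncol(x$mask), ...)
  }
  m <- x$mask
  graphics::image(t(m)[, nrow(m):1], col = c(NA, "#d62728"),
                  axes = FALSE, add = !is.null(img),
                  asp = nrow(m) / ncol(m))
  invisible(x)
}

#' Serialize a blob set to CSV
#' @param blobs A `blob_set`.
#' @param path Output path.
#' @export
write_blobs <- function(blobs, path) {
  utils::write.csv(as.data.frame(blobs)[, c("row", "col", "sigma", "response")],
                   path, row.names = FALSE)
  invisible(path)
}
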