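#' Geometric scale sequence
#'
#' Builds the scale ladder `sigma_n = k^n * sigma_min` for `n = 0..n_max`,
#' where `n_max` is the smallest integer with `k^n_max * sigma_min >=
#' sigma_max`, so both endpoints are honored.
#'
#' @param sigma_min,sigma_max Scale endpoints (px), `0 < sigma_min <
#'   sigma_max`.
#' @param k Multiplicative ratio, > 1. Default `2^(1/3)`.
#' @return Numeric vector of scales, strictly increasing.
#' @export
build_scale_sequence <- function(sigma_min, sigma_max, k = 2^(1 / 3)) {
  if (!(sigma_min > 0 && sigma_max > sigma_min))
    stop("require 0 < sigma_min < sigma_max")
  if (k <= 1) stop("scale ratio k must be > 1")
  n_max <- ceiling(log(sigma_max / sigma_min) / log(k) - 1e-12)
  sigma_min * k^(0:n_max)
}

# Gaussian convolution with reflective border handling. filter2 is circular,
# so the image is reflect-padded by the kernel half-width first.
gaussian_filter <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  g1 <- stats::dnorm(-half:half, sd = sigma)
  kern <- outer(g1, g1)
  kern <- kern / sum(kern)
  xp <- reflect_pad(x, half)
  out <- EBImage::filter2(xp, kern, boundary = "circular")
  out[(half + 1):(half + nrow(x)), (half + 1):(half + ncol(x)), drop = FALSE]
}

# Reflective (mirror, edge not repeated) padding by p pixels on each side.
reflect_pad <- function(x, p) {
  n <- nrow(x); m <- ncol(x)
  ri <- c((p + 1):2, 1:n, (n - 1):(n - p))
  ci <- c((p + 1):2, 1:m, (m - 1):(m - p))
  ri <- pmax(1L, pmin(n, ri)); ci <- pmax(1L, pmin(m, ci))
  x[ri, ci, drop = FALSE]
}

#' Gaussian scale-space stack
#'
#' Smooths a normalized image with a 2-D Gaussian at every scale:
#' `L(x, y; sigma) = G(sigma) * I`. Borders are handled reflectively.
#'
#' @param img A normalized [mammogram_image()] or a numeric matrix on
#'   `[0, 1]`.
#' @param scales Scale vector from [build_scale_sequence()].
#' @return 3-D array `(row, col, scale)` of smoothed planes.
#' @export
gaussian_scale_space <- function(img, scales) {
  x <- as_pixels(img)
  out <- array(0, c(dim(x), length(scales)))
  for (i in seq_along(scales)) out[, , i] <- gaussian_filter(x, scales[i])
  out
}

as_pixels <- function(img) {
  if (inherits(img, "mammogram_image")) {
    if (!isTRUE(img$normalized))
      stop("image must be normalized before scale-space analysis")
    img$pixels
  } else as.matrix(img)
}

#' Scale-normalized difference-of-Gaussians stack
#'
#' For adjacent scales, `DoG(x, y, n) = sigma_n / (sigma_{n+1} - sigma_n) *
#' (L(sigma_n) - L(sigma_{n+1}))`, forming a 3-D representation with one
#' fewer plane than the Gaussian stack. The sign convention makes the
#' response positive at the center of a bright blob, so bright structures
#' are 3-D maxima above the positive threshold `T_dog` and the Hessian of
#' the DoG plane is negative definite there.
#'
#' @param L 3-D Gaussian stack from [gaussian_scale_space()].
#' @param scales The matching scale vector (>= 2 scales).
#' @return List of class `dog_stack`: `values` (3-D array, last dim =
#'   `length(scales) - 1`), `scales`.
#' @export
normalized_dog_stack <- function(L, scales) {
  if (length(scales) < 2) stop("need at least 2 scales")
  stopifnot(dim(L)[3] == length(scales))
  vals <- array(0, c(dim(L)[1:2], length(scales) - 1))
  for (n in seq_len(length(scales) - 1)) {
    vals[, , n] <- scales[n] / (scales[n + 1] - scales[n]) *
      (L[, , n] - L[, , n + 1])
  }
  structure(list(values = vals, scales = scales), class = "dog_stack")
}

#' Detect blobs as 3-D local maxima of the DoG stack
#'
#' Values below `T_dog` are suppressed first; a voxel is a blob iff it is
#' `>=` all of its (up to) 26 neighbors in (scale, row, col) and strictly
#' `>` at least one. Maxima are allowed on the first/last scale plane and at
#' spatial borders (compared only against existing neighbors). Among a
#' connected equal-valued plateau of qualifying voxels, only the
#' lexicographically smallest (scale, row, col) is kept.
#'
#' @param dog A `dog_stack` from [normalized_dog_stack()].
#' @param T_dog Response threshold (lower bound).
#' @return Data frame of class `blob_set`: `row`, `col` (0-based), `sigma`,
#'   `response`, `scale_index` (1-based DoG plane).
#' @export
detect_blobs <- function(dog, T_dog = 0.006) {
  v <- dog$values
  v[v < T_dog] <- -Inf
  d <- dim(v)
  # pad with -Inf so border voxels compare only against existing neighbors
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  ge_all <- array(TRUE, d)
  gt_any <- array(FALSE, d)
  for (dr in -1:1) for (dc in -1:1) for (dn in -1:1) {
    if (dr == 0 && dc == 0 && dn == 0) next
    nb <- pad[(2:(d[1] + 1)) + dr, (2:(d[2] + 1)) + dc,
              (2:(d[3] + 1)) + dn, drop = FALSE]
    ge_all <- ge_all & (v >= nb)
    gt_any <- gt_any | (v > nb)
  }
  cand <- which(is.finite(v) & ge_all & gt_any, arr.ind = TRUE)
  if (nrow(cand)) {
    cand <- resolve_plateaus(cand, v)
  }
  blobs <- data.frame(
    row = cand[, 1] - 1L, col = cand[, 2] - 1L,
    sigma = dog$scales[cand[, 3]],
    response = v[cand],
    scale_index = cand[, 3]
  )
  blobs <- blobs[order(blobs$scale_index, blobs$row, blobs$col), ,
                 drop = FALSE]
  rownames(blobs) <- NULL
  class(blobs) <- c("blob_set", "data.frame")
  blobs
}

# Keep one representative (lexicographically smallest in (scale,row,col))
# per 26-connected equal-valued plateau of candidate maxima.
resolve_plateaus <- function(cand, v) {
  n <- nrow(cand)
  if (n <= 1) return(cand)
  keep <- rep(TRUE, n)
  key <- paste(cand[, 1], cand[, 2], cand[, 3])
  edges <- integer(0)
  idx <- stats::setNames(seq_len(n), key)
  for (i in seq_len(n)) {
    for (dr in -1:1) for (dc in -1:1) for (dn in -1:1) {
      if (dr == 0 && dc == 0 && dn == 0) next
      k2 <- paste(cand[i, 1] + dr, cand[i, 2] + dc, cand[i, 3] + dn)
      j <- idx[k2]
      if (!is.na(j) && j > i && v[matrix(cand[i, ], 1)] ==
            v[matrix(cand[j, ], 1)])
        edges <- c(edges, i, j)
    }
  }
  if (length(edges)) {
    g <- igraph::make_graph(edges, n = n, directed = FALSE)
    comp <- igraph::components(g)$membership
    ord <- order(cand[, 3], cand[, 1], cand[, 2])
    seen <- logical(max(comp))
    keep <- rep(FALSE, n)
    for (i in ord) {
      if (!seen[comp[i]]) { seen[comp[i]] <- TRUE; keep[i] <- TRUE }
    }
  }
  cand[keep, , drop = FALSE]
}

#' Prune overlapping blobs
#'
#' Blobs are treated as discs of radius `sqrt(2) * sigma`. For a pair whose
#' intersection area, as a fraction of the smaller disc's area, strictly
#' exceeds `O_dog`, the smaller-sigma blob is eliminated (at equal sigma,
#' the lower response). Pairs are visited in descending response order. The
#' default `O_dog = 1` never satisfies the strict inequality and therefore
#' disables pruning.
#'
#' @param blobs A `blob_set`.
#' @param O_dog Overlap fraction threshold in `[0, 1]`.
#' @return The pruned `blob_set`.
#' @export
prune_overlapping_blobs <- function(blobs, O_dog = 1) {
  if (O_dog < 0 || O_dog > 1) stop("O_dog must lie in [0, 1]")
  if (nrow(blobs) <= 1) return(blobs)
  ord <- order(-blobs$response)
  alive <- rep(TRUE, nrow(blobs))
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    if (!alive[i]) next
    for (jj in seq_along(ord)) {
      if (jj <= ii) next
      j <- ord[jj]
      if (!alive[j]) next
      frac <- disc_overlap_fraction(blobs$row[i], blobs$col[i], blobs$sigma[i],
                                    blobs$row[j], blobs$col[j], blobs$sigma[j])
      if (frac > O_dog) {
        # eliminate the smaller-sigma blob; ties: lower response (j)
        if (blobs$sigma[j] < blobs$sigma[i] ||
            (blobs$sigma[j] == blobs$sigma[i])) alive[j] <- FALSE
        else { alive[i] <- FALSE; break }
      }
    }
    if (!alive[i]) next
  }
  out <- blobs[alive, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Intersection area of two discs (radius sqrt(2)*sigma) over the smaller
# disc's area.
disc_overlap_fraction <- function(r1, c1, s1, r2, c2, s2) {
  R1 <- sqrt(2) * s1; R2 <- sqrt(2) * s2
  d <- sqrt((r1 - r2)^2 + (c1 - c2)^2)
  if (d >= R1 + R2) return(0)
  rmin <- min(R1, R2); rmax <- max(R1, R2)
  if (d <= rmax - rmin) return(1)  # smaller disc fully contained
  # circular lens area
  a1 <- R1^2 * acos((d^2 + R1^2 - R2^2) / (2 * d * R1))
  a2 <- R2^2 * acos((d^2 + R2^2 - R1^2) / (2 * d * R2))
  a3 <- 0.5 * sqrt(pmax(0, (-d + R1 + R2) * (d + R1 - R2) *
                          (d - R1 + R2) * (d + R1 + R2)))
  (a1 + a2 - a3) / (pi * rmin^2)
}

#' @export
print.blob_set <- function(x, ...) {
  cat(sprintf("blob_set: %d blob(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}
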