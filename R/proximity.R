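#' Exponential proximity kernel
#'
#' `g(r) = (exp(alpha * (1 - r/xi)) - 1) / (exp(alpha) - 1)` for `r <= xi`,
#' 0 beyond. `g(0) = 1`, `g(xi) = 0`; as `alpha -> 0` it approaches the
#' linear ramp `1 - r/xi`. Not defined at `alpha = 0`.
#'
#' @param r Euclidean distance(s) in px.
#' @param xi Characteristic distance (px), > 0.
#' @param alpha Decay rate, non-zero.
#' @return Values in `[0, 1]`.
#' @export
proximity_kernel <- function(r, xi, alpha) {
  if (alpha == 0) stop("proximity kernel is not well defined when alpha = 0")
  if (xi <= 0) stop("xi must be > 0")
  ifelse(r <= xi, (exp(alpha * (1 - r / xi)) - 1) / (exp(alpha) - 1), 0)
}

#' Proximity map of an annotation mask
#'
#' `P(x, y) = max_i g(x, y, x_i, y_i)` over annotated pixels, computed via
#' the exact Euclidean distance transform: the maximum of a decreasing
#' kernel over sources is the kernel at the nearest source. Annotated
#' pixels (including contour interiors) get `P = 1`; the decay extends `xi`
#' beyond the foreground.
#'
#' @param mask Binary matrix (`M(x, y)` in 0/1).
#' @param xi Characteristic distance (px).
#' @param alpha Decay rate (non-zero).
#' @return A list of class `proximity_map`: `values` (matrix in `[0, 1]`),
#'   `xi`, `alpha`.
#' @export
proximity_map <- function(mask, xi = 10, alpha = 1) {
  if (alpha == 0) stop("proximity map is not well defined when alpha = 0")
  mask <- (as.matrix(mask) != 0) + 0
  if (!any(mask > 0)) {
    values <- matrix(0, nrow(mask), ncol(mask))
  } else {
    # distmap(y): distance of each non-zero pixel of y to nearest zero.
    # y = 1 - mask gives every background pixel its distance to the mask.
    r <- EBImage::distmap(1 - mask, metric = "euclidean")
    values <- matrix(proximity_kernel(as.numeric(r), xi, alpha),
                     nrow(mask), ncol(mask))
  }
  structure(list(values = values, xi = xi, alpha = alpha),
            class = "proximity_map")
}

#' @export
print.proximity_map <- function(x, ...) {
  cat(sprintf("proximity_map: %d x %d, xi = %g px, alpha = %g, max = %.3f\n",
              nrow(x$values), ncol(x$values), x$xi, x$alpha, max(x$values)))
  invisible(x)
}

as_map_values <- function(x) {
  if (inherits(x, "proximity_map")) x$values else as.matrix(x)
}

#' Soft Dice loss
#'
#' `L = 1 - (2 * sum(P * Phat) + eps) / (sum(P + Phat) + eps)` with `eps`
#' for numerical stability (two empty maps give loss 0). Symmetric in its
#' arguments; lies in `[0, 1)`.
#'
#' @param pred,target Matrices (or `proximity_map`s) of equal shape with
#'   values in `[0, 1]`.
#' @param eps Stabilizer, default 1.
#' @return Scalar loss.
#' @export
soft_dice_loss <- function(pred, target, eps = 1) {
  p <- as_map_values(pred); t <- as_map_values(target)
  if (!all(dim(p) == dim(t))) stop("shape mismatch between pred and target")
  1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

#' Threshold a proximity map
#'
#' Foreground where `Phat >= p_thr`.
#'
#' @param pred Matrix or `proximity_map`.
#' @param p_thr Cut-off in `[0, 1]`.
#' @return Binary integer matrix.
#' @export
threshold_map <- function(pred, p_thr) {
  if (p_thr < 0 || p_thr > 1) stop("p_thr must lie in [0, 1]")
  m <- (as_map_values(pred) >= p_thr)
  mode(m) <- "integer"
  m
}
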