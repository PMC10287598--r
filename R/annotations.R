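#' Mixed point/contour annotation set
#'
#' Reference annotations for one image: small microcalcifications marked by a
#' single pixel each, larger ones delineated by closed polygon contours.
#'
#' @param points Integer matrix with columns `row`, `col` (0-based), or
#'   `NULL`/empty for none.
#' @param contours List of closed polygons; each a numeric matrix with
#'   columns `row`, `col` (vertices in order, not repeated at the end).
#' @param image_shape Integer vector `c(rows, cols)`.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(points = NULL, contours = list(),
                           image_shape) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 1))
  image_shape <- as.integer(image_shape)
  if (is.null(points) || NROW(points) == 0) {
    points <- matrix(integer(0), ncol = 2,
                     dimnames = list(NULL, c("row", "col")))
  } else {
    points <- matrix(as.integer(round(points)), ncol = 2,
                     dimnames = list(NULL, c("row", "col")))
  }
  check_inside <- function(rc, what) {
    if (NROW(rc) && (any(rc[, 1] < 0) || any(rc[, 1] > image_shape[1] - 1) ||
                     any(rc[, 2] < 0) || any(rc[, 2] > image_shape[2] - 1)))
      stop(what, " coordinates fall outside the image")
  }
  check_inside(points, "point")
  contours <- lapply(contours, function(p) {
    p <- matrix(as.numeric(p), ncol = 2, dimnames = list(NULL, c("row", "col")))
    if (nrow(p) < 3) stop("a contour needs at least 3 vertices")
    check_inside(p, "contour vertex")
    p
  })
  structure(list(points = points, contours = contours,
                 image_shape = image_shape),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d point(s), %d contour(s) on %d x %d\n",
              nrow(x$points), length(x$contours),
              x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Rasterize annotations to a binary mask
#'
#' Point annotations set single pixels; contour interiors are filled with a
#' boundary-inclusive convention (a pixel on a vertex or edge is foreground).
#' The result is the union over all objects, `M(x, y) in {0, 1}`.
#'
#' @param ann An [annotation_set()].
#' @return Binary integer matrix of the annotation's `image_shape`.
#' @export
rasterize_annotations <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  m <- matrix(0L, ann$image_shape[1], ann$image_shape[2])
  if (nrow(ann$points))
    m[cbind(ann$points[, 1] + 1L, ann$points[, 2] + 1L)] <- 1L
  for (poly in ann$contours) m <- m | rasterize_polygon(poly, dim(m))
  mode(m) <- "integer"
  m
}

# Boundary-inclusive polygon fill: interior by even-odd point-in-polygon at
# pixel centers, boundary by dense sampling along each edge.
rasterize_polygon <- function(poly, shape) {
  m <- matrix(0L, shape[1], shape[2])
  r0 <- max(0L, floor(min(poly[, 1]))); r1 <- min(shape[1] - 1L, ceiling(max(poly[, 1])))
  c0 <- max(0L, floor(min(poly[, 2]))); c1 <- min(shape[2] - 1L, ceiling(max(poly[, 2])))
  if (r1 >= r0 && c1 >= c0) {
    grid <- as.matrix(expand.grid(row = r0:r1, col = c0:c1))
    inside <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]),
                           grid + 0.0)
    hit <- grid[inside, , drop = FALSE]
    if (nrow(hit)) m[cbind(hit[, 1] + 1L, hit[, 2] + 1L)] <- 1L
  }
  # edges, sampled at quarter-pixel steps
  n <- nrow(poly)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    steps <- max(2L, ceiling(4 * max(abs(b - a))) + 1L)
    t <- seq(0, 1, length.out = steps)
    rr <- round(a[1] + t * (b[1] - a[1])); cc <- round(a[2] + t * (b[2] - a[2]))
    keep <- rr >= 0 & rr <= shape[1] - 1 & cc >= 0 & cc <= shape[2] - 1
    if (any(keep)) m[cbind(rr[keep] + 1L, cc[keep] + 1L)] <- 1L
  }
  m
}

#' Read/write annotation files
#'
#' Points travel as a two-column CSV (`row,col`); contours as a JSON list of
#' polygons (each an array of `[row, col]` vertices). These dialects are
#' minimal and lossless.
#'
#' @param points_csv,contours_json File paths; either may be `NULL`.
#' @param image_shape Integer `c(rows, cols)` for validation.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(points_csv = NULL, contours_json = NULL,
                             image_shape) {
  pts <- NULL
  if (!is.null(points_csv) && file.exists(points_csv)) {
    df <- utils::read.csv(points_csv)
    if (nrow(df)) pts <- as.matrix(df[, c("row", "col")])
  }
  contours <- list()
  if (!is.null(contours_json) && file.exists(contours_json)) {
    raw <- jsonlite::fromJSON(contours_json, simplifyVector = FALSE)
    contours <- lapply(raw, function(p)
      do.call(rbind, lapply(p, function(v) as.numeric(unlist(v)))))
  }
  annotation_set(points = pts, contours = contours, image_shape = image_shape)
}

#' @rdname read_annotations
#' @param ann An [annotation_set()] to serialize.
#' @export
write_annotations <- function(ann, points_csv, contours_json) {
  utils::write.csv(as.data.frame(ann$points), points_csv, row.names = FALSE)
  jsonlite::write_json(lapply(ann$contours, unname), contours_json,
                       digits = NA)
  invisible(NULL)
}

#' Write a binary mask as PNG (0/255)
#' @param mask Binary matrix.
#' @param path Output `.png` path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}
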