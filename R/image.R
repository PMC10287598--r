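#' Mammogram image container
#'
#' A 2-D grayscale intensity grid together with the physical pixel spacing
#' and the detector bit depth. Raw images hold integer intensities in
#' `[0, 2^bit_depth - 1]`; after [normalize_intensity()] intensities lie in
#' `[0, 1]` and the object is flagged as normalized.
#'
#' Coordinates throughout the package are `(row, col)`, 0-based, with pixel
#' centers at integer coordinates; scales and distances are in pixels unless
#' suffixed `_mm`.
#'
#' @param pixels Numeric matrix of non-negative intensities.
#' @param spacing_mm Pixel spacing in millimetres (> 0).
#' @param bit_depth Integer bit depth (12 or 14 typical). Ignored when
#'   `normalized = TRUE`.
#' @param normalized Logical; `TRUE` when `pixels` are already on `[0, 1]`.
#' @return An object of class `mammogram_image`.
#' @export
mammogram_image <- function(pixels, spacing_mm = 0.070, bit_depth = NULL,
                            normalized = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (any(pixels < 0)) stop("intensities must be non-negative")
  if (!is.numeric(spacing_mm) || spacing_mm <= 0)
    stop("spacing_mm must be > 0")
  if (normalized) {
    if (max(pixels) > 1 + 1e-9) stop("normalized image exceeds 1")
    bit_depth <- NA_integer_
  } else {
    if (is.null(bit_depth)) bit_depth <- infer_bit_depth(max(pixels))
    if (max(pixels) > 2^bit_depth - 1)
      stop("intensities exceed the declared bit depth")
  }
  structure(list(pixels = pixels, spacing_mm = spacing_mm,
                 bit_depth = as.integer(bit_depth), normalized = normalized),
            class = "mammogram_image")
}

# Smallest common depth (8/12/14/16) covering the observed maximum.
infer_bit_depth <- function(maxval) {
  for (b in c(8L, 12L, 14L, 16L)) if (maxval <= 2^b - 1) return(b)
  stop("intensity range exceeds 16-bit")
}

#' @export
print.mammogram_image <- function(x, ...) {
  cat(sprintf("mammogram_image: %d x %d px, %.3f mm/px, %s\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm,
              if (x$normalized) "normalized [0,1]"
              else sprintf("%d-bit", x$bit_depth)))
  invisible(x)
}

#' Normalize image intensities to `[0, 1]`
#'
#' Divides the pixel grid by `2^bit_depth - 1`. Refuses to run twice: a
#' normalized image is flagged and re-normalization would silently rescale.
#'
#' @param img A [mammogram_image()].
#' @return The normalized `mammogram_image`.
#' @export
normalize_intensity <- function(img) {
  stopifnot(inherits(img, "mammogram_image"))
  if (isTRUE(img$normalized))
    stop("image is already normalized; refusing to normalize twice")
  if (is.na(img$bit_depth)) stop("bit depth unknown")
  img$pixels <- img$pixels / (2^img$bit_depth - 1)
  img$normalized <- TRUE
  img
}

#' Load a mammogram from PNG, TIFF, or DICOM
#'
#' PNG/TIFF carry no spacing metadata, so `spacing_override` (or the
#' `default_spacing` fallback, if non-`NULL`) is required. DICOM spacing is
#' read from PixelSpacing unless overridden. Pixel values are returned
#' unchanged (PNG/TIFF fractions are rescaled back to integer counts using
#' the file bit depth).
#'
#' @param path Path to a `.png`, `.tif(f)`, or `.dcm` file.
#' @param spacing_override Optional spacing in mm overriding any metadata.
#' @param default_spacing Fallback spacing for formats without metadata;
#'   `NULL` (default) makes missing spacing an error.
#' @param bit_depth Optional bit depth; inferred from file metadata or the
#'   maximum pixel value when absent.
#' @return A [mammogram_image()].
#' @export
load_image <- function(path, spacing_override = NULL, default_spacing = NULL,
                       bit_depth = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  spacing <- spacing_override
  if (ext == "png" || ext %in% c("tif", "tiff")) {
    if (ext == "png") {
      raw <- png::readPNG(path)
      file_bits <- attr(raw, "bit.depth")
      if (is.null(file_bits)) file_bits <- 16L
    } else {
      raw <- tiff::readTIFF(path)
      file_bits <- 16L
    }
    if (length(dim(raw)) == 3) raw <- raw[, , 1]
    pixels <- round(raw * (2^file_bits - 1))
    if (is.null(spacing)) spacing <- default_spacing
    if (is.null(spacing))
      stop("no pixel spacing metadata in ", ext,
           " file and no override given")
    if (is.null(bit_depth)) bit_depth <- infer_bit_depth(max(pixels))
  } else if (ext == "dcm" || ext == "dicom") {
    dcm <- read_dicom(path)
    pixels <- dcm$pixels
    if (is.null(spacing)) spacing <- dcm$spacing_mm
    if (is.null(spacing))
      stop("DICOM file carries no PixelSpacing and no override given")
    if (is.null(bit_depth))
      bit_depth <- if (!is.null(dcm$bits_stored)) dcm$bits_stored
                   else infer_bit_depth(max(pixels))
  } else stop("unsupported image format: .", ext)
  mammogram_image(pixels, spacing_mm = spacing, bit_depth = bit_depth)
}

#' Write a 16-bit grayscale image
#'
#' Writes integer intensities losslessly to 16-bit PNG or TIFF. Raw images
#' are stored as counts scaled by the file's 16-bit range; reading back with
#' [load_image()] restores them bit-exactly.
#'
#' @param img A [mammogram_image()] (raw, not normalized).
#' @param path Output path ending in `.png` or `.tif(f)`.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "mammogram_image"))
  if (isTRUE(img$normalized))
    stop("write_image stores raw integer intensities; denormalize first")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") write_png16(round(img$pixels), path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(img$pixels / 65535, path, bits.per.sample = 16L)
  else stop("unsupported output format: .", ext)
  invisible(path)
}

#' Write a proximity map as 32-bit float TIFF
#' @param values Numeric matrix in `[0, 1]`.
#' @param path Output `.tif(f)` path.
#' @export
write_float_map <- function(values, path) {
  tiff::writeTIFF(values, path, bits.per.sample = 32L)
  invisible(path)
}
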