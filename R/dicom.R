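#' Minimal DICOM reader
#'
#' Reads uncompressed little-endian DICOM (explicit or implicit VR), which
#' covers for-processing mammography exports. Parsed fields: Rows, Columns,
#' BitsStored, PixelSpacing, and the unencapsulated 8/16-bit PixelData.
#' Sequences with undefined length and compressed transfer syntaxes are not
#' supported.
#'
#' @param path Path to a `.dcm` file.
#' @return A list with `pixels` (integer matrix, row-major as displayed),
#'   `spacing_mm` (row spacing, or `NULL` when absent), and `bits_stored`.
#' @export
read_dicom <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", n = file.size(path))
  if (length(bytes) < 132 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM magic): ", path)
  pos <- 133L  # first byte after the magic, 1-based

  u16 <- function(i) as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1L])
  u32 <- function(i) {
    v <- as.numeric(bytes[i]) + 256 * as.numeric(bytes[i + 1L]) +
      65536 * as.numeric(bytes[i + 2L]) + 16777216 * as.numeric(bytes[i + 3L])
    v
  }
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")

  read_element <- function(pos, explicit) {
    group <- u16(pos); elem <- u16(pos + 2L)
    if (explicit) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_; len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM element unsupported")
    list(group = group, elem = elem, vr = vr,
         value_at = pos + hdr, len = len, next_at = pos + hdr + len)
  }

  # File meta group (0002,xxxx) is always explicit little endian.
  transfer_syntax <- "1.2.840.10008.1.2.1"
  while (pos <= length(bytes)) {
    el <- read_element(pos, explicit = TRUE)
    if (el$group != 2L) break
    if (el$elem == 0x0010) {
      v <- bytes[el$value_at:(el$value_at + el$len - 1L)]
      transfer_syntax <- trimws(rawToChar(v[v != as.raw(0)]))
    }
    pos <- el$next_at
  }
  explicit <- switch(transfer_syntax,
    "1.2.840.10008.1.2"   = FALSE,
    "1.2.840.10008.1.2.1" = TRUE,
    stop("unsupported DICOM transfer syntax: ", transfer_syntax))

  rows <- cols <- bits_alloc <- bits_stored <- NULL
  spacing <- NULL; pixel_raw <- NULL
  while (pos + 7L <= length(bytes)) {
    el <- read_element(pos, explicit)
    val <- if (el$len > 0) bytes[el$value_at:(el$value_at + el$len - 1L)]
           else raw(0)
    if (el$group == 0x0028) {
      if (el$elem == 0x0010) rows <- u16(el$value_at)
      if (el$elem == 0x0011) cols <- u16(el$value_at)
      if (el$elem == 0x0100) bits_alloc <- u16(el$value_at)
      if (el$elem == 0x0101) bits_stored <- u16(el$value_at)
      if (el$elem == 0x0030) {
        txt <- rawToChar(val[val != as.raw(0)])
        s <- strsplit(gsub(" ", "", txt), "\\\\")[[1]]
        spacing <- as.numeric(s[1])
      }
    }
    if (el$group == 0x7FE0 && el$elem == 0x0010) pixel_raw <- val
    pos <- el$next_at
  }
  if (is.null(rows) || is.null(cols) || is.null(pixel_raw))
    stop("DICOM file lacks Rows/Columns/PixelData")
  if (is.null(bits_alloc)) bits_alloc <- 16L
  vals <- if (bits_alloc <= 8) as.integer(pixel_raw)
          else readBin(pixel_raw, "integer", n = rows * cols, size = 2L,
                       signed = FALSE, endian = "little")
  pixels <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  list(pixels = pixels, spacing_mm = spacing, bits_stored = bits_stored)
}
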