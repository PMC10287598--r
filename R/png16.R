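# Minimal 16-bit grayscale PNG encoder. The installed PNG bindings write
# 8 bits per sample only, which would truncate 12/14/16-bit mammography
# intensities; this encoder emits a grayscale PNG (bit depth 16, color
# type 0) with a zlib stream built from R's deflate. Readable by any
# standard PNG reader. 32-bit quantities are carried as doubles; XOR runs
# on 16-bit halves.

xor32 <- function(a, b) {
  bitwXor(a %% 65536, b %% 65536) +
    bitwXor(a %/% 65536, b %/% 65536) * 65536
}

crc32_table <- local({
  tab <- numeric(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (c %% 2 == 1) xor32(3988292384, c %/% 2) else c %/% 2
    }
    tab[n + 1] <- c
  }
  tab
})

# CRC-32 over a raw vector, as 4 big-endian raw bytes.
crc32_raw <- function(bytes) {
  crc <- 4294967295
  ints <- as.integer(bytes)
  tab <- crc32_table
  for (b in ints) {
    crc <- xor32(crc %/% 256, tab[bitwXor(crc %% 256, b) + 1])
  }
  u32_be(xor32(crc, 4294967295))
}

u32_be <- function(v) {
  as.raw(c(v %/% 2^24, (v %/% 2^16) %% 256, (v %/% 256) %% 256, v %% 256))
}

png_chunk <- function(type, data) {
  c(u32_be(length(data)), charToRaw(type), data,
    crc32_raw(c(charToRaw(type), data)))
}

# pixels: integer matrix in [0, 65535]
write_png16 <- function(pixels, path) {
  h <- nrow(pixels); w <- ncol(pixels)
  ihdr <- c(u32_be(w), u32_be(h), as.raw(c(16, 0, 0, 0, 0)))
  # scanlines: filter byte 0 + big-endian uint16 samples, row-major
  v <- as.vector(t(pixels))
  samp <- as.raw(rbind(as.raw(v %/% 256), as.raw(v %% 256)))
  dim(samp) <- NULL
  rows <- matrix(samp, nrow = 2 * w)
  scan <- as.raw(rbind(matrix(as.raw(0), 1, h), rows))
  dim(scan) <- NULL
  # memCompress("gzip") emits an RFC 1950 zlib stream, which is exactly
  # what IDAT requires
  idat <- memCompress(scan, type = "gzip")
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
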