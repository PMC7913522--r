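# Minimal 16-bit grayscale PNG encoder.
#
# The CRAN png package decodes 16-bit grayscale PNG but only encodes 8-bit,
# so the encoder is implemented here: zlib deflate via memCompress() and a
# table-driven CRC-32. Greyscale, bit depth 16, no interlacing, filter 0.

crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(-306674912L, bitwShiftR(c, 1L))  # 0xEDB88320
      else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   crc32_table[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

uint32_be <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data = raw(0)) {
  body <- c(charToRaw(type), data)
  crc <- crc32(body)
  crc_u <- if (crc < 0) as.numeric(crc) + 4294967296 else as.numeric(crc)
  c(uint32_be(length(data)), body, uint32_be(crc_u))
}

# px: integer matrix (rows = scanlines) with values in [0, 65535].
write_png16 <- function(px, path) {
  h <- nrow(px); w <- ncol(px)
  ihdr <- c(uint32_be(w), uint32_be(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, greyscale
  v <- as.integer(t(px))                     # row-major pixel order
  inter <- as.raw(rbind(v %/% 256L, v %% 256L))  # big-endian 16-bit
  scan <- rbind(as.raw(0L), matrix(inter, nrow = 2L * w))  # filter byte 0
  idat <- memCompress(as.raw(scan), type = "gzip")         # zlib stream
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND"))
  writeBin(out, path)
  invisible(path)
}
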