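# Minimal 16-bit grayscale PNG encoder. Density maps need more than
# 8 bits of dynamic range on disk; no installed writer emits 16-bit
# PNG, so the few required chunks are assembled here. Reading goes
# through png::readPNG, which handles 16-bit natively and serves as the
# round-trip check in the test suite.

# CRC-32 (polynomial 0xEDB88320), table-driven, on 32-bit values held
# as doubles; XOR is done on 16-bit halves to stay in integer range.
crc32_table <- local({
  tab <- numeric(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      odd <- c %% 2
      c <- floor(c / 2)
      if (odd == 1) {
        lo <- bitwXor(c %% 65536, 0x8320)
        hi <- bitwXor(floor(c / 65536), 0xEDB8)
        c <- hi * 65536 + lo
      }
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- 4294967295 # 0xFFFFFFFF
  for (b in bytes) {
    idx <- bitwXor(crc %% 256, b)
    t <- crc32_table[idx + 1]
    s <- floor(crc / 256)
    lo <- bitwXor(t %% 65536, s %% 65536)
    hi <- bitwXor(floor(t / 65536), floor(s / 65536))
    crc <- hi * 65536 + lo
  }
  lo <- bitwXor(crc %% 65536, 65535)
  hi <- bitwXor(floor(crc / 65536), 65535)
  hi * 65536 + lo
}

u32_bytes <- function(v) {
  as.raw(c(floor(v / 16777216) %% 256, floor(v / 65536) %% 256,
           floor(v / 256) %% 256, v %% 256))
}

png_chunk <- function(type, data) {
  payload <- c(charToRaw(type), data)
  c(u32_bytes(length(data)), payload, u32_bytes(crc32(as.integer(payload))))
}

# memCompress(type = "gzip") emits a zlib stream (0x78 header + Adler32
# trailer), which is exactly the IDAT payload format.
zlib_compress <- function(bytes) {
  memCompress(bytes, type = "gzip")
}

# Write matrix `m` (values in [0, 1], H x W) as 16-bit grayscale PNG.
write_png16 <- function(m, path) {
  h <- nrow(m); w <- ncol(m)
  v <- round(pmin(pmax(m, 0), 1) * 65535)
  # scanlines: filter byte 0, then big-endian 16-bit samples, row-major
  row_bytes <- matrix(0, h, 2 * w + 1)
  row_bytes[, seq(2, 2 * w, by = 2)] <- floor(v / 256)
  row_bytes[, seq(3, 2 * w + 1, by = 2)] <- v %% 256
  raw_data <- as.raw(as.vector(t(row_bytes)))
  ihdr <- c(u32_bytes(w), u32_bytes(h),
            as.raw(c(16, 0, 0, 0, 0))) # depth 16, gray, deflate, filter 0, no interlace
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_compress(raw_data)),
           png_chunk("IEND", raw()))
  writeBin(out, path)
  invisible(path)
}
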