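# Depth-map I/O. Registered Kinect-style depth is conventionally stored as a
# 16-bit grayscale PNG holding millimetres. The installed PNG bindings only
# write 8-bit images, so writing goes through a minimal deterministic PNG
# encoder (zlib stream with stored deflate blocks); reading uses png::readPNG,
# which handles 16-bit natively.

u32be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(.crc32(body)))
}

# zlib-wrap a raw payload using stored (uncompressed) deflate blocks.
zlib_stored <- function(payload) {
  n <- length(payload)
  starts <- seq.int(1L, max(n, 1L), by = 65535L)
  blocks <- lapply(seq_along(starts), function(i) {
    from <- starts[i]
    to <- min(from + 65534L, n)
    len <- if (n == 0L) 0L else to - from + 1L
    hdr <- as.raw(c(if (i == length(starts)) 1L else 0L,
                    len %% 256L, len %/% 256L,
                    255L - len %% 256L, 255L - len %/% 256L))
    c(hdr, if (len > 0L) payload[from:to])
  })
  c(as.raw(c(0x78, 0x01)), unlist(blocks), u32be(.adler32(payload)))
}

#' Write a depth map as a 16-bit grayscale PNG
#'
#' Values are stored verbatim as 16-bit unsigned integers (the package
#' convention is millimetres), clamped to `[0, 65535]`.
#'
#' @param depth Numeric H x W matrix of depths in millimetres.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_depth_png <- function(depth, path) {
  if (!is.matrix(depth)) stop("depth must be a matrix")
  v <- round(pmin(pmax(depth, 0), 65535))
  h <- nrow(v); w <- ncol(v)
  # scanlines: filter byte 0, then big-endian 16-bit samples, row by row
  m <- t(v)                               # row-major traversal
  hi <- as.raw(m %/% 256); lo <- as.raw(m %% 256)
  samp <- as.raw(rbind(hi, lo))           # interleave high/low bytes
  dim(samp) <- c(2L * w, h)
  scan <- as.raw(rbind(raw(h), samp))     # prepend filter byte per row
  ihdr <- c(u32be(w), u32be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", zlib_stored(as.vector(scan))), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

#' Read a 16-bit grayscale depth PNG back into millimetres
#'
#' @param path PNG file path.
#' @return Numeric H x W matrix of depths in millimetres.
#' @export
read_depth_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  round(img * 65535)
}
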