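# Minimal baseline-TIFF codec: uncompressed, little-endian, single-strip,
# grayscale, 8- or 16-bit unsigned. This is the only image format the
# pipeline exchanges with the outside world; arbitrary third-party TIFFs
# (tiled, compressed, RGB) are out of scope and rejected with an error.

#' Write a matrix as an uncompressed grayscale TIFF
#'
#' Pixel values are rounded and clamped to the unsigned range of the chosen
#' bit depth. Rows of the matrix are image rows (row 1 = top of the image).
#'
#' @param image numeric matrix.
#' @param path output file path.
#' @param bits bits per sample, 8 or 16 (default 16, matching the sCMOS
#'   acquisition depth the pipeline assumes).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(image, path, bits = 16L) {
  stopifnot(is.matrix(image), bits %in% c(8L, 16L))
  h <- nrow(image); w <- ncol(image)
  maxval <- 2^bits - 1
  px <- round(t(image))            # row-major pixel order
  px[px < 0] <- 0; px[px > maxval] <- maxval
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)                       # little-endian
  writeBin(42L, con, size = 2, endian = "little")      # magic
  writeBin(8L, con, size = 4, endian = "little")       # IFD offset
  n_entries <- 8L
  data_offset <- 8L + 2L + n_entries * 12L + 4L
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L && count == 1L) {                   # SHORT packed left
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(n_entries, con, size = 2, endian = "little")
  entry(256L, 3L, 1L, w)                               # ImageWidth
  entry(257L, 3L, 1L, h)                               # ImageLength
  entry(258L, 3L, 1L, bits)                            # BitsPerSample
  entry(259L, 3L, 1L, 1L)                              # Compression: none
  entry(262L, 3L, 1L, 1L)                              # BlackIsZero
  entry(273L, 4L, 1L, data_offset)                     # StripOffsets
  entry(278L, 3L, 1L, h)                               # RowsPerStrip
  entry(279L, 4L, 1L, h * w * (bits %/% 8L))           # StripByteCounts
  writeBin(0L, con, size = 4, endian = "little")       # next IFD: none
  storage <- as.integer(px)
  if (bits == 16L) {
    writeBin(storage, con, size = 2, endian = "little")
  } else {
    writeBin(as.raw(storage), con)
  }
  invisible(path)
}

#' Read an uncompressed grayscale TIFF written by this package
#'
#' Supports uncompressed little- or big-endian baseline TIFF, one sample per
#' pixel, 8 or 16 bits, any strip layout.
#'
#' @param path file path.
#' @return numeric matrix (rows = image rows).
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop("not a TIFF file: ", path)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                               size = 2, endian = endian, signed = FALSE)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer",
                               size = 4, endian = endian)
  if (u16(2) != 42L) stop("not a TIFF file: ", path)
  ifd <- u32(4)
  n <- u16(ifd)
  tags <- list()
  for (i in seq_len(n)) {
    base <- ifd + 2 + (i - 1) * 12
    tag <- u16(base); type <- u16(base + 2); count <- u32(base + 4)
    read_vals <- function(off) {
      if (type == 3L) vapply(seq_len(count) - 1L, function(k) u16(off + 2 * k), 0L)
      else vapply(seq_len(count) - 1L, function(k) u32(off + 4 * k), 0L)
    }
    sz <- if (type == 3L) 2L else 4L
    vals <- if (count * sz <= 4L) read_vals(base + 8) else read_vals(u32(base + 8))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) { if (is.null(default)) stop("TIFF tag ", tag, " missing in ", path); default }
    else v
  }
  w <- need(256)[1]; h <- need(257)[1]
  bits <- need(258, 1L)[1]
  comp <- need(259, 1L)[1]
  if (comp != 1L) stop("unsupported TIFF compression (", comp, ") in ", path)
  if (!bits %in% c(8L, 16L)) stop("unsupported bit depth ", bits, " in ", path)
  offsets <- need(273); counts <- need(279, h * w * (bits %/% 8L))
  bytes <- unlist(lapply(seq_along(offsets), function(i)
    raw[(offsets[i] + 1):(offsets[i] + counts[i])]), use.names = FALSE)
  vals <- if (bits == 16L) {
    readBin(bytes, "integer", n = h * w, size = 2, endian = endian, signed = FALSE)
  } else {
    as.integer(bytes)
  }
  matrix(as.numeric(vals), nrow = h, ncol = w, byrow = TRUE)
}
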