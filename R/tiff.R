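#' Read and write single-channel grayscale TIFF images
#'
#' Minimal baseline-TIFF codec used for channel images. `write_tiff()` writes
#' an uncompressed single-strip 8-bit grayscale file (little-endian).
#' `read_tiff()` reads uncompressed grayscale baseline TIFFs in either byte
#' order, with one or more strips; 16-bit files are accepted only with
#' `convert = TRUE`, in which case intensities are rescaled to 0--255 with a
#' warning. No R package in the supported stack provides TIFF I/O, hence this
#' self-contained implementation; a round-trip test validates it against an
#' independent reader.
#'
#' @param image integer matrix with values in 0--255 (rows = image rows).
#' @param path file path.
#' @param convert logical; rescale 16-bit data to 8-bit instead of erroring.
#' @return `read_tiff()` returns an integer matrix in 0--255;
#'   `write_tiff()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tif")
#' img <- matrix(0:255, 16, 16)
#' write_tiff(img, f)
#' identical(read_tiff(f), img)
#' @export
write_tiff <- function(image, path) {
  if (!is.matrix(image) || !is.numeric(image))
    stop_param("image must be a numeric matrix")
  if (any(is.na(image)) || any(image < 0) || any(image > 255) ||
      any(image != round(image)))
    stop_param("image values must be integers in [0, 255]")
  .write_tiff_impl(image, path, bits = 8L)
}

# bits = 16 is internal-only (test fixture generation for down-conversion)
.write_tiff_impl <- function(image, path, bits = 8L) {
  h <- nrow(image)
  w <- ncol(image)
  bytes_px <- bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  # header: little-endian, magic 42, IFD follows the pixel data
  data_len <- h * w * bytes_px
  ifd_offset <- 8L + data_len
  if (data_len %% 2L == 1L) ifd_offset <- ifd_offset + 1L
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_offset), con, size = 4, endian = "little")
  # pixel data: scanlines in row-major order, single strip at offset 8
  writeBin(as.integer(t(image)), con, size = bytes_px, endian = "little")
  if (data_len %% 2L == 1L) writeBin(0L, con, size = 1)
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT: left-justified in the 4-byte value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(9L, con, size = 2, endian = "little")  # entry count
  entry(256L, 4L, 1L, w)            # ImageWidth
  entry(257L, 4L, 1L, h)            # ImageLength
  entry(258L, 3L, 1L, bits)         # BitsPerSample
  entry(259L, 3L, 1L, 1L)           # Compression = none
  entry(262L, 3L, 1L, 1L)           # Photometric = BlackIsZero
  entry(273L, 4L, 1L, 8L)           # StripOffsets
  entry(277L, 3L, 1L, 1L)           # SamplesPerPixel
  entry(278L, 4L, 1L, h)            # RowsPerStrip
  entry(279L, 4L, 1L, data_len)     # StripByteCounts
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  invisible(path)
}

#' @rdname write_tiff
#' @export
read_tiff <- function(path, convert = FALSE) {
  if (!file.exists(path)) stop_param("file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop_param("not a TIFF file: ", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop_param("not a TIFF file (bad byte-order mark): ", path)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                               size = 2, signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
    if (v < 0) v <- v + 4294967296
    v
  }
  if (u16(2L) != 42L) stop_param("not a TIFF file (bad magic): ", path)
  ifd <- u32(4L)
  n_entries <- u16(ifd)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2L + (i - 1L) * 12L
    tag <- u16(off)
    type <- u16(off + 2L)
    count <- u32(off + 4L)
    size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)[as.character(type)]
    if (is.na(size)) next
    total <- size * count
    voff <- if (total <= 4L) off + 8L else u32(off + 8L)
    vals <- vapply(seq_len(count), function(k) {
      o <- voff + (k - 1L) * size
      if (size == 2L) u16(o) else if (size == 4L) u32(o)
      else as.integer(raw[o + 1L])
    }, numeric(1))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop_param("TIFF missing required tag ", tag)
      default
    } else v
  }
  w <- need(256L)
  h <- need(257L)
  bits <- need(258L, 8L)[1]
  compression <- need(259L, 1L)
  spp <- need(277L, 1L)
  if (compression != 1L)
    stop_param("unsupported TIFF: compressed data (compression=", compression, ")")
  if (spp != 1L)
    stop_param("unsupported TIFF: ", spp, " samples per pixel (grayscale required)")
  if (!bits %in% c(8L, 16L))
    stop_param("unsupported TIFF bit depth: ", bits)
  if (bits == 16L && !convert)
    stop_param("16-bit TIFF: pass convert = TRUE to rescale to 8-bit")
  offsets <- need(273L)
  counts <- need(279L, h * w * bits / 8L)
  px <- integer(0)
  for (s in seq_along(offsets)) {
    seg <- raw[(offsets[s] + 1):(offsets[s] + counts[s])]
    px <- c(px, if (bits == 8L) {
      as.integer(seg)
    } else {
      readBin(seg, "integer", n = counts[s] / 2L, size = 2,
              signed = FALSE, endian = endian)
    })
  }
  if (length(px) != h * w)
    stop_param("TIFF pixel data length mismatch (", length(px),
               " pixels for ", h, "x", w, ")")
  m <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
  if (bits == 16L) {
    warning("16-bit TIFF rescaled to 8-bit (divided by 257)")
    m <- clamp8(m / 257)
  }
  storage.mode(m) <- "integer"
  m
}
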