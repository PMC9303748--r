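#' Multi-channel image stack
#'
#' A `channel_stack` holds one field's registered channel images (named
#' integer matrices in 0--255, identical dimensions) together with the pixel
#' scale and the provenance labels (coating, day, well, field) used throughout
#' the pipeline. Channel names follow the convention `dapi` (nuclear stain,
#' required for segmentation), `green`, `red` (immunofluorescence markers)
#' and `myhc` (cytoplasmic myotube stain).
#'
#' @param channels named list of integer matrices with values in 0--255.
#' @param pixel_size_um physical size of one pixel in micrometers.
#' @param provenance named list of condition labels (coating, day, well, field).
#' @return an object of class `channel_stack`.
#' @export
channel_stack <- function(channels, pixel_size_um = 1, provenance = list()) {
  if (!is.list(channels) || length(channels) == 0 || is.null(names(channels)) ||
      any(names(channels) == ""))
    stop_param("channels must be a non-empty named list of matrices")
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_param("all channels must share identical height x width")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch))
      stop_param("channel '", nm, "' is not a numeric matrix")
    if (any(is.na(ch)) || any(ch < 0) || any(ch > 255))
      stop_param("channel '", nm, "' has values outside [0, 255]")
    storage.mode(channels[[nm]]) <- "integer"
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      pixel_size_um <= 0)
    stop_param("pixel_size_um must be a positive scalar")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 provenance = provenance),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<channel_stack> ", d[1], "x", d[2], " px, ",
      length(x$channels), " channel(s): ",
      paste(names(x$channels), collapse = ", "),
      " [", x$pixel_size_um, " um/px]\n", sep = "")
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), unlist(x$provenance),
                               sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$channels[[1]])

#' Read a channel stack from per-channel grayscale TIFF files
#'
#' Channel names are resolved either from an explicit named `paths` vector or
#' from the `*_<channel>.tif` suffix of each file name. A `dapi` channel is
#' required. All planes must share the same shape; 16-bit inputs are
#' down-converted (with a warning) only when `convert = TRUE`.
#'
#' @param paths character vector of TIFF paths, optionally named by channel.
#' @param pixel_size_um pixel scale to record on the stack.
#' @param provenance provenance labels to record on the stack.
#' @param convert allow 16-bit inputs to be rescaled to 8-bit.
#' @return a [channel_stack].
#' @export
read_stack <- function(paths, pixel_size_um = 1, provenance = list(),
                       convert = FALSE) {
  nms <- names(paths)
  if (is.null(nms) || any(nms == "")) {
    nms <- sub("\\.tiff?$", "", basename(paths), ignore.case = TRUE)
    nms <- sub("^.*_", "", nms)
  }
  if (anyDuplicated(nms))
    stop_param("duplicate channel names resolved from paths: ",
               paste(nms[duplicated(nms)], collapse = ", "))
  channels <- lapply(paths, read_tiff, convert = convert)
  names(channels) <- nms
  if (!"dapi" %in% nms)
    stop_param("required 'dapi' channel missing (got: ",
               paste(nms, collapse = ", "), ")")
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_param("channel shape mismatch: ",
               paste(apply(dims, 2, paste, collapse = "x"), collapse = " vs "))
  channel_stack(channels, pixel_size_um = pixel_size_um,
                provenance = provenance)
}

#' Write a channel stack as per-channel grayscale TIFF files
#'
#' Files are named `<prefix>_<channel>.tif`.
#'
#' @param stack a [channel_stack].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (typically `<coating>_<day>_w<well>_f<field>`).
#' @return named character vector of written paths, invisibly.
#' @export
write_stack <- function(stack, dir, prefix) {
  stopifnot(inherits(stack, "channel_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(stack$channels), function(nm) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".tif"))
    write_tiff(stack$channels[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Split a stack into its independent single-channel images
#'
#' Each antibody is processed independently, so the first pipeline step
#' separates the multi-channel image into per-channel grayscale images.
#' Pixels are not modified.
#'
#' @param stack a [channel_stack].
#' @return named list of integer matrices, pixel-identical to the stack's
#'   channels.
#' @export
split_channels <- function(stack) {
  stopifnot(inherits(stack, "channel_stack"))
  stack$channels
}

#' Crop the five standardized fields from a whole-well image
#'
#' Reproduces the five-spot sampling convention: one field at the well
#' center and one each above, below, left and right of it, offset from the
#' center by exactly one field size. Crops are square (`field_size` px),
#' pairwise disjoint, and deterministic given the image size.
#'
#' @param well_stack a [channel_stack] covering the whole well.
#' @param field_size side length of each square field, in pixels.
#' @return list of five [channel_stack]s named `center`, `north`, `south`,
#'   `west`, `east`; each carries a `field` provenance label.
#' @export
sample_fields <- function(well_stack, field_size) {
  stopifnot(inherits(well_stack, "channel_stack"))
  d <- dim(well_stack)
  f <- as.integer(field_size)
  if (f <= 0) stop_param("field_size must be positive")
  if (d[1] < 3L * f || d[2] < 3L * f)
    stop_param("well image (", d[1], "x", d[2], ") too small for three ",
               "non-overlapping fields of ", f, " px per dimension")
  cr <- d[1] %/% 2L  # 0-based center
  cc <- d[2] %/% 2L
  centers <- list(center = c(cr, cc),
                  north  = c(cr - f, cc),
                  south  = c(cr + f, cc),
                  west   = c(cr, cc - f),
                  east   = c(cr, cc + f))
  lapply(setNames(names(centers), names(centers)), function(nm) {
    ctr <- centers[[nm]]
    r0 <- ctr[1] - f %/% 2L  # 0-based, half-open [r0, r0 + f)
    c0 <- ctr[2] - f %/% 2L
    channels <- lapply(well_stack$channels,
                       function(ch) ch[r0 + seq_len(f), c0 + seq_len(f),
                                       drop = FALSE])
    prov <- well_stack$provenance
    prov$field <- nm
    channel_stack(channels, pixel_size_um = well_stack$pixel_size_um,
                  provenance = prov)
  })
}
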