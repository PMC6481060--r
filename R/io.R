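# Core raster types and image/mask I/O.
#
# Working currency of the pipeline: a `bf_image` is a 2-D intensity matrix
# (rows = y, columns = x) with an explicit bit depth (8 or 16) and an
# optional pixel calibration in nm/pixel. Binary results are `bf_mask`
# objects (logical matrix + calibration). Masks are written to disk as
# 8-bit rasters with foreground = 255, background = 0, the ImageJ binary
# convention.

#' Construct a brightfield image object
#'
#' A `bf_image` holds a 2-D matrix of non-negative integer intensities
#' (rows = y, columns = x), its bit depth, and an optional pixel
#' calibration in nm/pixel. All pipeline stages operate on this type.
#'
#' @param pixels Numeric or integer matrix of intensities, all values in
#'   `[0, 2^bit_depth - 1]`.
#' @param bit_depth Either 8 or 16.
#' @param nm_per_pixel Optional physical pixel size in nm/pixel
#'   (strictly positive), required by [select_parameters()].
#' @return An object of class `bf_image`.
#' @seealso [read_image()], [to_8bit()], [bf_mask()]
#' @export
bf_image <- function(pixels, bit_depth = 8L, nm_per_pixel = NULL) {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("'pixels' must be a matrix with at least one row and one column")
  if (!bit_depth %in% c(8L, 16L))
    stop("'bit_depth' must be 8 or 16")
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 2^bit_depth - 1))
    stop("pixel values must lie in [0, 2^bit_depth - 1] with no NA")
  check_calibration(nm_per_pixel)
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         nm_per_pixel = nm_per_pixel),
    class = "bf_image")
}

#' Construct a binary mask object
#'
#' @param pixels Logical matrix; `TRUE` is foreground.
#' @param nm_per_pixel Optional pixel calibration in nm/pixel, usually
#'   inherited from the image the mask was derived from.
#' @return An object of class `bf_mask`.
#' @export
bf_mask <- function(pixels, nm_per_pixel = NULL) {
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("'pixels' must be a logical matrix")
  if (anyNA(pixels)) stop("mask pixels must not contain NA")
  check_calibration(nm_per_pixel)
  structure(list(pixels = pixels, nm_per_pixel = nm_per_pixel),
            class = "bf_mask")
}

check_calibration <- function(nm_per_pixel) {
  if (!is.null(nm_per_pixel) &&
      (!is.numeric(nm_per_pixel) || length(nm_per_pixel) != 1L ||
       is.na(nm_per_pixel) || nm_per_pixel <= 0))
    stop("'nm_per_pixel' must be a single strictly positive number")
  invisible(nm_per_pixel)
}

#' @export
print.bf_image <- function(x, ...) {
  cat(sprintf("<bf_image> %d x %d, %d-bit%s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              if (is.null(x$nm_per_pixel)) ", uncalibrated"
              else sprintf(", %g nm/pixel", x$nm_per_pixel)))
  invisible(x)
}

#' @export
print.bf_mask <- function(x, ...) {
  cat(sprintf("<bf_mask> %d x %d, %d foreground px (%.1f%%)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels)))
  invisible(x)
}

# Accept a bf_image or a bare matrix; return the intensity matrix.
as_pixels <- function(img) {
  if (inherits(img, "bf_image")) img$pixels
  else if (is.matrix(img)) img
  else stop("expected a 'bf_image' or a matrix")
}

# Accept a bf_mask or a bare logical matrix; return the logical matrix.
as_mask_pixels <- function(mask) {
  if (inherits(mask, "bf_mask")) mask$pixels
  else if (is.matrix(mask) && is.logical(mask)) mask
  else stop("expected a 'bf_mask' or a logical matrix")
}

# ITU-R 601 luminance weights, the default RGB -> grayscale conversion of
# the reference brightfield workflow. Fixed, not configurable.
LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)

#' Read a grayscale image from TIFF or PNG
#'
#' Reads an 8- or 16-bit TIFF or PNG file. RGB(A) input is converted to
#' luminance with ITU-R 601 weights (0.299, 0.587, 0.114), rounded to the
#' nearest integer; the alpha channel, if present, is ignored. The native
#' bit depth is preserved.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param nm_per_pixel Optional pixel calibration to attach to the result.
#' @return A [bf_image()].
#' @export
read_image <- function(path, nm_per_pixel = NULL) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: file '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                    error = function(e)
                      stop(sprintf("cannot read TIFF '%s': %s",
                                   path, conditionMessage(e))))
    bits <- if (max(raw) > 255 || attr_bits(path) == 16L) 16L else 8L
    dat <- raw
  } else if (ext == "png") {
    raw <- tryCatch(png::readPNG(path),
                    error = function(e)
                      stop(sprintf("cannot read PNG '%s': %s",
                                   path, conditionMessage(e))))
    # png::readPNG rescales to [0,1]; 16-bit files carry 65535 levels
    bits <- png_bit_depth(path)
    dat <- raw * (2^bits - 1)
  } else {
    stop(sprintf("unsupported image format '.%s' (expected TIFF or PNG)", ext))
  }
  px <- collapse_channels(dat)
  px <- round(px)
  storage.mode(px) <- "integer"
  bf_image(px, bit_depth = bits, nm_per_pixel = nm_per_pixel)
}

# Bits per sample of a TIFF file (readTIFF drops it with as.is for 8-bit,
# so probe the normalized read).
attr_bits <- function(path) {
  info <- tryCatch(tiff::readTIFF(path, payload = FALSE), error = function(e) NULL)
  if (!is.null(info) && !is.null(info$bits.per.sample))
    as.integer(info$bits.per.sample) else 8L
}

# PNG bit depth: png::readPNG gives no metadata; sniff byte 24 of the file
# (IHDR bit-depth field of the PNG header).
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  depth <- as.integer(hdr[25L])
  if (depth == 16L) 16L else 8L
}

collapse_channels <- function(dat) {
  if (length(dim(dat)) == 2L) return(dat)
  if (length(dim(dat)) == 3L) {
    nch <- dim(dat)[3L]
    if (nch >= 3L) {
      return(LUMA_WEIGHTS[1] * dat[, , 1L] +
             LUMA_WEIGHTS[2] * dat[, , 2L] +
             LUMA_WEIGHTS[3] * dat[, , 3L])
    }
    if (nch %in% c(1L, 2L)) return(dat[, , 1L])  # gray or gray+alpha
  }
  stop("unsupported sample format: expected grayscale or RGB(A) raster")
}

#' Write a binary mask to disk
#'
#' Encodes foreground as 255 and background as 0 in a single-channel
#' 8-bit TIFF or PNG, so masks open directly as ImageJ-style binaries.
#'
#' @param mask A [bf_mask()] or logical matrix.
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @export
write_mask <- function(mask, path) {
  px <- as_mask_pixels(mask)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("cannot write mask: directory '%s' does not exist", dir))
  ext <- tolower(tools::file_ext(path))
  norm <- matrix(ifelse(px, 1, 0), nrow(px), ncol(px))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(norm, path)
  } else {
    stop(sprintf("unsupported mask format '.%s' (expected TIFF or PNG)", ext))
  }
  invisible(path)
}

#' Convert an image to 8-bit
#'
#' 16-bit input is rescaled linearly from its own `[min, max]` intensity
#' range onto `[0, 255]` (display-range scaling); a constant 16-bit image
#' maps to 0. 8-bit input is returned unchanged. Pixel ordering is always
#' preserved.
#'
#' @param img A [bf_image()].
#' @return An 8-bit [bf_image()].
#' @export
to_8bit <- function(img) {
  stopifnot(inherits(img, "bf_image"))
  if (img$bit_depth == 8L) return(img)
  px <- img$pixels
  lo <- min(px); hi <- max(px)
  out <- if (hi == lo) matrix(0L, nrow(px), ncol(px))
         else {
           scaled <- round((px - lo) * (255 / (hi - lo)))
           storage.mode(scaled) <- "integer"
           scaled
         }
  bf_image(out, bit_depth = 8L, nm_per_pixel = img$nm_per_pixel)
}
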