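# End-to-end segmentation pipeline: resolution-dependent parameter
# selection, the six processing stages, outline overlay and mask-based
# fluorescence quantification.
#
# Stage order (fixed): to_8bit -> equalize_histogram -> canny ->
# maximum_filter -> binary_close -> binary_open -> optional count_erode.
# The final erosion compensates the systematic dilation introduced by
# the maximum filter.

# Resolution bands (nm/pixel, half-open [lo, hi)) and the smoothing /
# maximum-filter radii recommended for each. Values below the first band
# clamp to it with a warning.
PARAM_TABLE <- data.frame(
  lo = c(90, 180, 270, 360),
  hi = c(180, 270, 360, Inf),
  gaussian_kernel_radius = c(1.75, 1.5, 1.25, 1),
  max_filter_radius = c(5, 2.5, 1.67, 1.25)
)

#' Resolution-dependent filter radii
#'
#' Looks up the recommended Gaussian kernel radius (Canny smoothing
#' sigma) and maximum-filter radius for a given pixel calibration. Bands
#' are half-open `[lo, hi)` in nm/pixel — 90-180, 180-270, 270-360 and
#' 360+ — with a shared boundary belonging to the upper band. Values
#' below 90 nm/pixel clamp to the first band with a warning.
#'
#' @param nm_per_pixel Physical pixel size in nm/pixel, positive.
#' @return Named list with `gaussian_kernel_radius` and
#'   `max_filter_radius` (both in pixels).
#' @examples
#' select_parameters(110)  # 63x water objective: radii 1.75 and 5
#' select_parameters(400)  # 5x objective: radii 1 and 1.25
#' @export
select_parameters <- function(nm_per_pixel) {
  check_calibration(nm_per_pixel)
  if (is.null(nm_per_pixel)) stop("'nm_per_pixel' is required")
  if (nm_per_pixel < PARAM_TABLE$lo[1L]) {
    warning(sprintf(
      "pixel size %g nm/pixel is below the calibrated range; clamping to the %g-%g band",
      nm_per_pixel, PARAM_TABLE$lo[1L], PARAM_TABLE$hi[1L]))
    nm_per_pixel <- PARAM_TABLE$lo[1L]
  }
  row <- which(nm_per_pixel >= PARAM_TABLE$lo & nm_per_pixel < PARAM_TABLE$hi)
  list(gaussian_kernel_radius = PARAM_TABLE$gaussian_kernel_radius[row],
       max_filter_radius = PARAM_TABLE$max_filter_radius[row])
}

#' Pipeline configuration
#'
#' Bundles every tunable of the segmentation procedure. Usually built by
#' [default_config()]; construct directly only for full manual control.
#'
#' @param canny A [canny_params()] object.
#' @param max_filter_radius Maximum-filter radius in pixels, positive.
#' @param close,open [morph_options()] for the closing and opening
#'   stages.
#' @param erode [morph_options()] for the optional final erosion, or
#'   `NULL` to skip it.
#' @param classic_equalize Use classic CDF equalization instead of the
#'   square-root-weighted default.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(canny = canny_params(),
                            max_filter_radius = 5,
                            close = morph_options(10L, 3L, pad = TRUE),
                            open = morph_options(10L, 3L, pad = FALSE),
                            erode = morph_options(2L, 3L, pad = TRUE),
                            classic_equalize = FALSE) {
  stopifnot(inherits(canny, "canny_params"),
            inherits(close, "morph_options"),
            inherits(open, "morph_options"),
            is.null(erode) || inherits(erode, "morph_options"))
  if (!is.numeric(max_filter_radius) || max_filter_radius <= 0)
    stop("'max_filter_radius' must be positive")
  structure(list(canny = canny, max_filter_radius = max_filter_radius,
                 close = close, open = open, erode = erode,
                 classic_equalize = isTRUE(classic_equalize)),
            class = "pipeline_config")
}

#' Default pipeline configuration for a pixel calibration
#'
#' Injects the resolution-dependent radii from [select_parameters()]
#' into one of two presets:
#'
#' * `"high_mag"` — objectives of about 40x and above: Canny low 0.1 /
#'   high 8.0, closing 10 iterations (count 3, pad), opening 10
#'   iterations (count 3), final erosion 2 iterations (count 3, pad).
#' * `"low_mag"` — objectives below about 20x, where single cells span
#'   far fewer pixels: Canny high threshold raised to 9, closing reduced
#'   to 2 iterations, opening 10 iterations.
#'
#' @param nm_per_pixel Pixel calibration in nm/pixel.
#' @param preset `"high_mag"` (default) or `"low_mag"`.
#' @return A [pipeline_config()].
#' @export
default_config <- function(nm_per_pixel, preset = c("high_mag", "low_mag")) {
  if (length(preset) > 1L) preset <- preset[1L]
  if (!preset %in% c("high_mag", "low_mag"))
    stop(sprintf("unknown preset '%s'; available presets: high_mag, low_mag",
                 preset))
  radii <- select_parameters(nm_per_pixel)
  if (preset == "high_mag") {
    pipeline_config(
      canny = canny_params(radii$gaussian_kernel_radius, 0.1, 8.0),
      max_filter_radius = radii$max_filter_radius,
      close = morph_options(10L, 3L, pad = TRUE),
      open = morph_options(10L, 3L, pad = FALSE),
      erode = morph_options(2L, 3L, pad = TRUE))
  } else {
    pipeline_config(
      canny = canny_params(radii$gaussian_kernel_radius, 0.1, 9.0),
      max_filter_radius = radii$max_filter_radius,
      close = morph_options(2L, 3L, pad = TRUE),
      open = morph_options(10L, 3L, pad = FALSE),
      erode = morph_options(2L, 3L, pad = TRUE))
  }
}

#' Segment the total cell area of a brightfield image
#'
#' Runs the full pipeline: conversion to 8-bit, histogram equalization,
#' Canny edge detection, circular maximum filtering, binary closing
#' (fills holes inside cells), binary opening (removes debris), and an
#' optional final erosion. The result is a single foreground mask of the
#' total area occupied by cells — not per-cell instances.
#'
#' @param img A [bf_image()].
#' @param config A [pipeline_config()]; built from the image calibration
#'   by default.
#' @param keep_intermediates Record each stage's output in the result's
#'   `intermediate` list (names: equalized, edges, maxfiltered, closed,
#'   opened, eroded).
#' @return A `segmentation_result`: list with `mask` ([bf_mask()]),
#'   `config_used`, and `intermediate`.
#' @export
segment <- function(img,
                    config = default_config(img$nm_per_pixel),
                    keep_intermediates = FALSE) {
  stopifnot(inherits(img, "bf_image"), inherits(config, "pipeline_config"))
  inter <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e))))
  }
  img8 <- stage("to_8bit", to_8bit(img))
  eq <- stage("equalize", equalize_histogram(img8, classic = config$classic_equalize))
  if (keep_intermediates) inter$equalized <- eq
  edges <- stage("canny", canny(eq, config$canny))
  if (keep_intermediates) inter$edges <- edges
  # binary edge map as 0/255 so the rank filter acts as circular dilation
  edge255 <- matrix(ifelse(edges$pixels, 255L, 0L), nrow(edges$pixels))
  mf <- stage("maximum_filter", maximum_filter(edge255, config$max_filter_radius))
  m <- mf > 0
  if (keep_intermediates) inter$maxfiltered <- bf_mask(m, img$nm_per_pixel)
  m <- stage("close", binary_close(m, config$close))
  if (keep_intermediates) inter$closed <- bf_mask(m, img$nm_per_pixel)
  m <- stage("open", binary_open(m, config$open))
  if (keep_intermediates) inter$opened <- bf_mask(m, img$nm_per_pixel)
  if (!is.null(config$erode)) {
    m <- stage("erode", count_erode(m, config$erode))
    if (keep_intermediates) inter$eroded <- bf_mask(m, img$nm_per_pixel)
  }
  structure(list(mask = bf_mask(m, img$nm_per_pixel),
                 config_used = config,
                 intermediate = inter),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result>\n  ")
  print(x$mask)
  invisible(x)
}

#' Overlay the mask outline on the original image
#'
#' Paints the 1-pixel outline of the segmented area (mask minus its
#' single-iteration count-1 erosion) in a saturated color over the
#' grayscale original, for visual checking of segmentation precision.
#'
#' @param img A [bf_image()].
#' @param mask A [bf_mask()] of the same shape.
#' @param color Length-3 RGB vector in `[0, 1]`; default magenta.
#' @return An `height x width x 3` numeric array in `[0, 1]`.
#' @export
overlay_outline <- function(img, mask, color = c(1, 0, 1)) {
  stopifnot(inherits(img, "bf_image"))
  mpx <- as_mask_pixels(mask)
  if (!all(dim(img$pixels) == dim(mpx)))
    stop(sprintf("image shape %dx%d does not match mask shape %dx%d",
                 nrow(img$pixels), ncol(img$pixels), nrow(mpx), ncol(mpx)))
  outline <- mpx & !count_erode(mpx, morph_options(1L, 1L, pad = FALSE))
  gray <- img$pixels / (2^img$bit_depth - 1)
  out <- array(rep(gray, 3L), dim = c(dim(gray), 3L))
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[outline] <- color[ch]
    out[, , ch] <- plane
  }
  out
}

#' Quantify fluorescence under a segmentation mask
#'
#' Computes foreground area and fluorescence statistics of a
#' co-registered fluorescence channel over the segmented cell area:
#' pixel count, physical area (when calibrated), mean intensity, and
#' integrated density (sum of intensities; equals mean x area).
#'
#' For an empty mask the mean intensity is undefined and reported as
#' `NA` (never 0), while area and integrated density are 0.
#'
#' @param mask A [bf_mask()] or logical matrix.
#' @param fluor A [bf_image()] of identical shape (the fluorescence
#'   channel, which must share the spatial calibration of the
#'   brightfield channel).
#' @return A data frame with one row: `area_px`, `area_um2` (`NA` if
#'   uncalibrated), `mean_intensity`, `integrated_density`.
#' @export
quantify_fluorescence <- function(mask, fluor) {
  stopifnot(inherits(fluor, "bf_image"))
  mpx <- as_mask_pixels(mask)
  if (!all(dim(mpx) == dim(fluor$pixels)))
    stop(sprintf("mask shape %dx%d does not match fluorescence shape %dx%d",
                 nrow(mpx), ncol(mpx), nrow(fluor$pixels), ncol(fluor$pixels)))
  cal <- if (inherits(mask, "bf_mask") && !is.null(mask$nm_per_pixel))
    mask$nm_per_pixel else fluor$nm_per_pixel
  area_px <- sum(mpx)
  vals <- fluor$pixels[mpx]
  data.frame(
    area_px = area_px,
    area_um2 = if (is.null(cal)) NA_real_ else area_px * (cal / 1000)^2,
    mean_intensity = if (area_px == 0L) NA_real_ else mean(vals),
    integrated_density = if (area_px == 0L) 0 else sum(as.numeric(vals)))
}

# ---- config serialization -------------------------------------------------

# Flat key=value format whose keys mirror the macro parameter names of
# the original protocol (gaussian, low, high, radius, *_iterations,
# *_count, *_pad) for 1:1 traceability.

#' Write a pipeline configuration to a key=value text file
#'
#' @param config A [pipeline_config()].
#' @param path Output file path.
#' @seealso [read_config()]
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  kv <- c(
    gaussian = config$canny$gaussian_kernel_radius,
    low = config$canny$low_threshold,
    high = config$canny$high_threshold,
    radius = config$max_filter_radius,
    close_iterations = config$close$iterations,
    close_count = config$close$count,
    close_pad = as.integer(config$close$pad),
    open_iterations = config$open$iterations,
    open_count = config$open$count,
    open_pad = as.integer(config$open$pad),
    erode_enabled = as.integer(!is.null(config$erode)),
    erode_iterations = if (is.null(config$erode)) 0L else config$erode$iterations,
    erode_count = if (is.null(config$erode)) 3L else config$erode$count,
    erode_pad = if (is.null(config$erode)) 1L else as.integer(config$erode$pad),
    classic_equalize = as.integer(config$classic_equalize))
  writeLines(sprintf("%s=%s", names(kv),
                     vapply(kv, format, character(1), trim = TRUE, digits = 15)),
             path)
  invisible(path)
}

#' Read a pipeline configuration from a key=value text file
#'
#' @param path File written by [write_config()] (or hand-edited in the
#'   same flat format).
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path))
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  parts <- strsplit(lines, "=", fixed = TRUE)
  kv <- stats::setNames(
    vapply(parts, function(p) as.numeric(trimws(p[2L])), numeric(1)),
    vapply(parts, function(p) trimws(p[1L]), character(1)))
  need <- c("gaussian", "low", "high", "radius",
            "close_iterations", "close_count", "close_pad",
            "open_iterations", "open_count", "open_pad",
            "erode_enabled", "erode_iterations", "erode_count", "erode_pad",
            "classic_equalize")
  missing <- setdiff(need, names(kv))
  if (length(missing) > 0L)
    stop(sprintf("config file '%s' is missing keys: %s",
                 path, paste(missing, collapse = ", ")))
  pipeline_config(
    canny = canny_params(kv[["gaussian"]], kv[["low"]], kv[["high"]]),
    max_filter_radius = kv[["radius"]],
    close = morph_options(kv[["close_iterations"]], kv[["close_count"]],
                          pad = kv[["close_pad"]] != 0),
    open = morph_options(kv[["open_iterations"]], kv[["open_count"]],
                         pad = kv[["open_pad"]] != 0),
    erode = if (kv[["erode_enabled"]] != 0)
      morph_options(kv[["erode_iterations"]], kv[["erode_count"]],
                    pad = kv[["erode_pad"]] != 0),
    classic_equalize = kv[["classic_equalize"]] != 0)
}
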