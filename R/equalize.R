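# Histogram equalization, first stage of the segmentation pipeline.
#
# Two variants are provided. The default follows the ImageJ "equalize"
# behavior this tool emulates: histogram counts are replaced by their
# square roots before the cumulative mapping is built, which softens the
# influence of dominant bins (typically the background mode) and
# amplifies cell texture less aggressively than classic equalization.
# classic = TRUE uses the raw counts (textbook CDF equalization).

#' Equalize the histogram of an 8-bit image
#'
#' Builds a monotone intensity mapping from the cumulative image
#' histogram and applies it. With `classic = FALSE` (default) histogram
#' counts are square-root weighted before accumulation, matching the
#' default behavior of the ImageJ "equalize" option. The cumulative sum
#' is taken up to and including each bin, scaled by `255 / total`, and
#' rounded half-up; a constant image is returned unchanged.
#'
#' The `saturated_percent` argument is accepted for interface parity with
#' the contrast-enhancement call this stage reproduces (which ignores the
#' saturation setting whenever equalization is requested); it is
#' validated and otherwise unused.
#'
#' @param img An 8-bit [bf_image()].
#' @param classic Use raw histogram counts instead of square-root
#'   weighted counts.
#' @param saturated_percent Fraction of pixels allowed to saturate, in
#'   `[0, 100]`. Accepted and ignored, see Details.
#' @return An 8-bit [bf_image()] with the same dimensions.
#' @export
equalize_histogram <- function(img, classic = FALSE, saturated_percent = 0) {
  stopifnot(inherits(img, "bf_image"))
  if (img$bit_depth != 8L)
    stop("equalize_histogram() requires an 8-bit image; convert with to_8bit()")
  if (!is.numeric(saturated_percent) || length(saturated_percent) != 1L ||
      is.na(saturated_percent) || saturated_percent < 0 || saturated_percent > 100)
    stop("'saturated_percent' must be a single number in [0, 100]")
  px <- img$pixels
  lut <- equalize_lut(tabulate(as.integer(px) + 1L, nbins = 256L), classic)
  out <- matrix(lut[as.integer(px) + 1L], nrow(px), ncol(px))
  bf_image(out, bit_depth = 8L, nm_per_pixel = img$nm_per_pixel)
}

# 256-entry lookup table from a 256-bin histogram. Counts are sqrt-
# weighted unless classic; mapping is round_half_up(255 * cum / total)
# with cum inclusive of the current bin. Single-occupied-bin histograms
# yield the identity so constant images pass through unchanged.
equalize_lut <- function(counts, classic = FALSE) {
  w <- if (classic) as.numeric(counts) else sqrt(as.numeric(counts))
  total <- sum(w)
  if (sum(counts > 0) <= 1L || total == 0) return(0:255)
  cum <- cumsum(w)
  lut <- floor(255 * cum / total + 0.5)  # round half-up
  as.integer(pmin(255, pmax(0, lut)))
}
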