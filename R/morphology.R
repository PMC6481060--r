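# Circular maximum (rank) filter and count-parameterized binary
# morphology, matching the ImageJ semantics the segmentation protocol
# depends on:
#
# * the rank-filter neighborhood for radius r contains every offset with
#   dy^2 + dx^2 <= r^2 + 1, which reproduces the reference kernels for
#   the fractional radii (2.5, 1.67, 1.25) of the calibration table;
# * binary erode/dilate flip a pixel only when at least `count` of its 8
#   neighbors differ (background neighbors for erode, foreground for
#   dilate), repeated `iterations` times;
# * `pad` protects image borders during erosion by treating out-of-image
#   neighbors as foreground; without it they count as background.
#   Out-of-image neighbors always count as background for dilation.

#' Options for count-based binary morphology
#'
#' @param iterations Number of times the elementary operation is
#'   repeated; at least 1.
#' @param count Neighbor threshold in 1..8: a pixel flips only when at
#'   least this many of its 8 neighbors differ from it.
#' @param pad If `TRUE`, out-of-image neighbors count as foreground
#'   during erosion, protecting structures touching the border.
#' @return An object of class `morph_options`.
#' @export
morph_options <- function(iterations = 1L, count = 1L, pad = FALSE) {
  if (!is.numeric(iterations) || iterations < 1 || iterations != round(iterations))
    stop("'iterations' must be a whole number >= 1")
  if (!is.numeric(count) || count < 1 || count > 8 || count != round(count))
    stop("'count' must be a whole number in 1..8")
  structure(list(iterations = as.integer(iterations),
                 count = as.integer(count), pad = isTRUE(pad)),
            class = "morph_options")
}

#' Circular rank-filter kernel
#'
#' Enumerates the integer offsets of the circular neighborhood used by
#' the maximum filter: all `(dy, dx)` with `dy^2 + dx^2 <= radius^2 + 1`.
#' This inclusion rule reproduces the reference rank-filter kernels for
#' fractional radii such as 2.5, 1.67 and 1.25.
#'
#' @param radius Kernel radius in pixels, positive.
#' @return A list with `radius` and an integer matrix `offsets` (one row
#'   per offset, columns `dy`, `dx`), always containing `(0, 0)` and
#'   symmetric under negation.
#' @export
make_circular_kernel <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) || radius <= 0)
    stop("'radius' must be a single positive number")
  r_int <- as.integer(ceiling(radius))
  d <- (-r_int):r_int
  grid <- expand.grid(dy = d, dx = d)
  keep <- grid$dy^2 + grid$dx^2 <= radius^2 + 1
  offsets <- as.matrix(grid[keep, , drop = FALSE])
  dimnames(offsets) <- list(NULL, c("dy", "dx"))
  list(radius = radius, offsets = offsets)
}

#' Circular maximum filter
#'
#' Replaces each pixel with the maximum of the input over the circular
#' kernel centered there. At image borders the window shrinks:
#' out-of-image positions are ignored rather than padded. Applied to a
#' binary 0/255 edge image this acts as a dilation with the circular
#' kernel and fills most of the intracellular space between detected
#' edges.
#'
#' @param img A [bf_image()] or numeric matrix.
#' @param radius Kernel radius in pixels (see [make_circular_kernel()]).
#' @return Same type as the input (`bf_image` in, `bf_image` out).
#' @export
maximum_filter <- function(img, radius) {
  kern <- make_circular_kernel(radius)
  m <- as_pixels(img)
  was_int <- is.integer(m)
  storage.mode(m) <- "double"
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (i in seq_len(nrow(kern$offsets))) {
    out <- pmax(out, shift_mat(m, kern$offsets[i, 1L], kern$offsets[i, 2L],
                               fill = -Inf))
  }
  if (was_int) storage.mode(out) <- "integer"
  if (inherits(img, "bf_image"))
    bf_image(out, bit_depth = img$bit_depth, nm_per_pixel = img$nm_per_pixel)
  else out
}

# Number of foreground 8-neighbors of every pixel; out-of-image
# neighbors contribute `pad_value` (0 or 1).
neighbor_count <- function(m01, pad_value) {
  h <- nrow(m01); w <- ncol(m01)
  p <- matrix(pad_value, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m01
  p[1:h, 1:w] + p[1:h, 2:(w + 1L)] + p[1:h, 3:(w + 2L)] +
    p[2:(h + 1L), 1:w] + p[2:(h + 1L), 3:(w + 2L)] +
    p[3:(h + 2L), 1:w] + p[3:(h + 2L), 2:(w + 1L)] + p[3:(h + 2L), 3:(w + 2L)]
}

#' Count-based binary erosion
#'
#' One iteration removes a foreground pixel iff at least `count` of its
#' 8 neighbors are background. With `pad = TRUE` out-of-image neighbors
#' count as foreground (border-protected erosion); with `pad = FALSE`
#' they count as background.
#'
#' @param mask A [bf_mask()] or logical matrix.
#' @param opts A [morph_options()] object.
#' @return Same type as the input.
#' @export
count_erode <- function(mask, opts = morph_options()) {
  apply_count_morph(mask, opts, erode = TRUE)
}

#' Count-based binary dilation
#'
#' One iteration adds a background pixel iff at least `count` of its 8
#' neighbors are foreground; out-of-image neighbors count as background.
#'
#' @inheritParams count_erode
#' @return Same type as the input.
#' @export
count_dilate <- function(mask, opts = morph_options()) {
  apply_count_morph(mask, opts, erode = FALSE)
}

apply_count_morph <- function(mask, opts, erode) {
  stopifnot(inherits(opts, "morph_options"))
  px <- as_mask_pixels(mask)
  m <- px * 1  # numeric 0/1
  for (i in seq_len(opts$iterations)) {
    if (erode) {
      # background neighbors = 8 - foreground neighbors, with the pad
      # flag deciding how out-of-image neighbors are counted
      bg <- neighbor_count(1 - m, pad_value = if (opts$pad) 0 else 1)
      m <- m * (bg < opts$count)
    } else {
      fg <- neighbor_count(m, pad_value = 0)
      m <- pmax(m, (fg >= opts$count) * 1)
    }
  }
  out <- m > 0
  if (inherits(mask, "bf_mask")) bf_mask(out, mask$nm_per_pixel) else out
}

#' Binary closing (dilate then erode)
#'
#' `iterations` dilations followed by the same number of erosions, with
#' one `count`/`pad` setting for both phases. Fills small holes left
#' inside cells after the maximum filter.
#'
#' @inheritParams count_erode
#' @return Same type as the input.
#' @export
binary_close <- function(mask, opts = morph_options(iterations = 10L, count = 3L, pad = TRUE)) {
  count_erode(count_dilate(mask, opts), opts)
}

#' Binary opening (erode then dilate)
#'
#' `iterations` erosions followed by the same number of dilations.
#' Eliminates small structures (debris and noise specks) outside the
#' cells.
#'
#' @inheritParams count_erode
#' @return Same type as the input.
#' @export
binary_open <- function(mask, opts = morph_options(iterations = 10L, count = 3L, pad = FALSE)) {
  count_dilate(count_erode(mask, opts), opts)
}
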