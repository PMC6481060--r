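# Canny edge detection with the parameter semantics of the ImageJ-style
# detector the segmentation protocol calls: Gaussian-radius smoothing
# (sigma = "Gaussian kernel radius"), gradient magnitude, non-maximum
# suppression interpolated along the gradient direction, and
# dual-threshold hysteresis with 8-connected linking.
#
# Threshold units: the low/high thresholds are compared against gradient
# magnitude multiplied by MAGNITUDE_SCALE. The constant is frozen at
# 100/255 relative to raw 8-bit gradient units so that the protocol's
# default thresholds (low 0.1, high 8.0) sit well below/within the
# gradient range produced by cell texture on equalized 8-bit input while
# staying above smooth-background response.

#' @rdname canny
#' @export
MAGNITUDE_SCALE <- 100 / 255

#' Canny detector parameters
#'
#' @param gaussian_kernel_radius Smoothing scale in pixels (the sigma of
#'   the Gaussian derivative filters); must be positive. Selected from
#'   the pixel calibration by [select_parameters()].
#' @param low_threshold,high_threshold Hysteresis thresholds on scaled
#'   gradient magnitude; `0 < low <= high`. The high threshold is the
#'   single most influential setting of the whole pipeline.
#' @return An object of class `canny_params`.
#' @export
canny_params <- function(gaussian_kernel_radius = 1.75,
                         low_threshold = 0.1,
                         high_threshold = 8.0) {
  if (!is.numeric(gaussian_kernel_radius) || gaussian_kernel_radius <= 0)
    stop("'gaussian_kernel_radius' must be positive")
  if (!is.numeric(low_threshold) || !is.numeric(high_threshold) ||
      low_threshold <= 0 || low_threshold > high_threshold)
    stop("thresholds must satisfy 0 < low_threshold <= high_threshold")
  structure(list(gaussian_kernel_radius = gaussian_kernel_radius,
                 low_threshold = low_threshold,
                 high_threshold = high_threshold),
            class = "canny_params")
}

# Replicate-pad then correlate along x (columns) with a 1-D kernel of
# half-width hw: out[y, x] = sum_o k[o + hw + 1] * m[y, x + o].
conv_x <- function(m, k) {
  hw <- (length(k) - 1L) %/% 2L
  w <- ncol(m)
  p <- m[, c(rep(1L, hw), seq_len(w), rep(w, hw)), drop = FALSE]
  out <- matrix(0, nrow(m), w)
  for (i in seq_along(k))
    out <- out + k[i] * p[, i:(i + w - 1L), drop = FALSE]
  out
}

conv_y <- function(m, k) t(conv_x(t(m), k))

# Gaussian and derivative-of-Gaussian taps, half-width ceil(4*sigma),
# truncated tails renormalized (smoothing taps sum to 1; derivative taps
# are the analytic derivative of the renormalized Gaussian).
gauss_kernels <- function(sigma) {
  hw <- ceiling(4 * sigma)
  x <- (-hw):hw
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  dg <- -x / sigma^2 * g
  list(g = g, dg = dg, hw = hw)
}

#' Gaussian-derivative image gradient
#'
#' Separable convolution with a Gaussian of sigma = `radius` and its
#' first derivative (kernel half-width `ceil(4*radius)`, truncated tails
#' renormalized, borders replicated). Returns the two gradient
#' components and the Euclidean magnitude.
#'
#' @param img A [bf_image()] or numeric matrix.
#' @param radius Gaussian sigma in pixels, positive.
#' @return A list with numeric matrices `gx`, `gy`, `magnitude`.
#' @export
gaussian_gradient <- function(img, radius) {
  if (!is.numeric(radius) || radius <= 0) stop("'radius' must be positive")
  m <- as_pixels(img)
  storage.mode(m) <- "double"
  k <- gauss_kernels(radius)
  gx <- conv_y(conv_x(m, k$dg), k$g)
  gy <- conv_x(conv_y(m, k$dg), k$g)
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2))
}

# Shift a matrix by (dy, dx), filling vacated cells with `fill`:
# out[y, x] = m[y + dy, x + dx] where defined.
shift_mat <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1L, 1L - dy):min(h, h - dy)
  xs <- max(1L, 1L - dx):min(w, w - dx)
  if (length(ys) > 0L && length(xs) > 0L)
    out[ys, xs] <- m[ys + dy, xs + dx]
  out
}

# Per-pixel selector: a where cond, b elsewhere.
sel_mat <- function(cond, a, b) { r <- b; r[cond] <- a[cond]; r }

#' Non-maximum suppression along the gradient direction
#'
#' Thins the gradient magnitude to single-pixel ridges. Each pixel is
#' compared with the magnitude interpolated at its two neighbors along
#' the gradient direction (bilinear between the nearest axis and
#' diagonal neighbor); it survives when it is `>=` the forward
#' (down-gradient-sign) neighbor and strictly `>` the backward one, so a
#' two-pixel plateau straddling an ideal step keeps exactly one pixel.
#' Out-of-image neighbors count as magnitude 0.
#'
#' @param gx,gy,magnitude Matrices of one shape, as produced by
#'   [gaussian_gradient()].
#' @return Matrix of the same shape with suppressed pixels set to 0.
#' @export
non_maximum_suppression <- function(gx, gy, magnitude) {
  if (!all(dim(gx) == dim(gy)) || !all(dim(gx) == dim(magnitude)))
    stop("gx, gy and magnitude must share one shape")
  M <- magnitude
  ax <- abs(gx); ay <- abs(gy)
  sxp <- gx >= 0; syp <- gy >= 0
  horiz <- ax >= ay

  M_E <- shift_mat(M, 0L, 1L);  M_W <- shift_mat(M, 0L, -1L)
  M_S <- shift_mat(M, 1L, 0L);  M_N <- shift_mat(M, -1L, 0L)
  M_SE <- shift_mat(M, 1L, 1L); M_NW <- shift_mat(M, -1L, -1L)
  M_NE <- shift_mat(M, -1L, 1L); M_SW <- shift_mat(M, 1L, -1L)

  # diagonal neighbor in the (sign(gy), sign(gx)) direction and its mirror
  d_f <- sel_mat(sxp & syp, M_SE,
                 sel_mat(sxp & !syp, M_NE,
                         sel_mat(!sxp & syp, M_SW, M_NW)))
  d_b <- sel_mat(sxp & syp, M_NW,
                 sel_mat(sxp & !syp, M_SW,
                         sel_mat(!sxp & syp, M_NE, M_SE)))

  ax_safe <- ifelse(ax == 0, 1, ax)
  ay_safe <- ifelse(ay == 0, 1, ay)
  t_h <- ay / ax_safe
  t_v <- ax / ay_safe

  nf_h <- (1 - t_h) * sel_mat(sxp, M_E, M_W) + t_h * d_f
  nb_h <- (1 - t_h) * sel_mat(sxp, M_W, M_E) + t_h * d_b
  nf_v <- (1 - t_v) * sel_mat(syp, M_S, M_N) + t_v * d_f
  nb_v <- (1 - t_v) * sel_mat(syp, M_N, M_S) + t_v * d_b

  n_f <- sel_mat(horiz, nf_h, nf_v)
  n_b <- sel_mat(horiz, nb_h, nb_v)

  keep <- (M > 0) & (M >= n_f) & (M > n_b)
  out <- M
  out[!keep] <- 0
  out
}

#' Dual-threshold hysteresis linking
#'
#' Pixels with value `>= high` seed edges; pixels `>= low` that are
#' 8-connected (transitively) to a seed are included; everything else is
#' excluded.
#'
#' @param thinned Thinned magnitude matrix (from
#'   [non_maximum_suppression()]).
#' @param low,high Thresholds with `low <= high`.
#' @param nm_per_pixel Optional calibration forwarded to the mask.
#' @return A [bf_mask()].
#' @export
hysteresis <- function(thinned, low, high, nm_per_pixel = NULL) {
  if (low > high) stop("'low' must not exceed 'high'")
  lowm <- thinned >= low
  seeds <- thinned >= high
  h <- nrow(thinned); w <- ncol(thinned)
  if (!any(seeds))
    return(bf_mask(matrix(FALSE, h, w), nm_per_pixel))
  pos <- which(lowm)
  idmap <- matrix(0L, h, w)
  idmap[pos] <- seq_along(pos)
  edges <- integer(0)
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    dy <- off[1L]; dx <- off[2L]
    if (max(1L, 1L - dy) > min(h, h - dy) ||
        max(1L, 1L - dx) > min(w, w - dx)) next
    ys <- max(1L, 1L - dy):min(h, h - dy)
    xs <- max(1L, 1L - dx):min(w, w - dx)
    both <- lowm[ys, xs, drop = FALSE] & lowm[ys + dy, xs + dx, drop = FALSE]
    if (any(both)) {
      a <- idmap[ys, xs, drop = FALSE][both]
      b <- idmap[ys + dy, xs + dx, drop = FALSE][both]
      edges <- c(edges, rbind(a, b))
    }
  }
  g <- igraph::make_empty_graph(n = length(pos), directed = FALSE)
  if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  keep_comp <- unique(comp[idmap[seeds & lowm]])
  out <- matrix(FALSE, h, w)
  out[pos[comp %in% keep_comp]] <- TRUE
  bf_mask(out, nm_per_pixel)
}

#' Canny edge detection
#'
#' Composition of [gaussian_gradient()], [non_maximum_suppression()] and
#' [hysteresis()]. Before thresholding, the thinned gradient magnitude is
#' multiplied by the fixed `MAGNITUDE_SCALE` constant (100/255 relative
#' to raw 8-bit gradient units) so that the protocol's default threshold
#' values (low 0.1, high 8.0) apply directly to 8-bit input.
#'
#' @param img An 8-bit [bf_image()] (or numeric matrix treated as 8-bit).
#' @param params A [canny_params()] object.
#' @return A [bf_mask()] of edge pixels.
#' @export
canny <- function(img, params = canny_params()) {
  stopifnot(inherits(params, "canny_params"))
  if (inherits(img, "bf_image") && img$bit_depth != 8L)
    stop("canny() requires an 8-bit image; convert with to_8bit()")
  cal <- if (inherits(img, "bf_image")) img$nm_per_pixel else NULL
  gg <- gaussian_gradient(img, params$gaussian_kernel_radius)
  thinned <- non_maximum_suppression(gg$gx, gg$gy, gg$magnitude)
  hysteresis(thinned * MAGNITUDE_SCALE,
             params$low_threshold, params$high_threshold,
             nm_per_pixel = cal)
}
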