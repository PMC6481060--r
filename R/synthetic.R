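# Synthetic brightfield scene generator with ground truth.
#
# Emulates the imaging situation the pipeline is designed for: cell
# bodies appear as textured elliptical regions with a darker rim on a
# smoothly varying, mildly noisy background; small high-contrast debris
# blobs may litter the background. The interior texture is modeled as
# organelle-scale blobs (1-3 px) of alternating contrast plus fine
# noise, which produces the dense intracellular edge response the edge
# detector relies on. Ground truth is the union of the cell ellipses;
# debris is deliberately excluded from the truth, mirroring the way
# contrasting impurities inflate automated area estimates relative to a
# human annotator.

#' Parameters of a synthetic brightfield scene
#'
#' Defaults describe a well-acquired high-magnification field of view:
#' several cell bodies tens of pixels across, clear rim contrast, strong
#' organelle texture, a gentle illumination gradient and low sensor
#' noise, with a couple of small debris particles.
#'
#' @param width,height Frame size in pixels.
#' @param n_cells Number of cell bodies (random ellipses).
#' @param cell_radius_range Semi-axis range in pixels, length 2.
#' @param interior_texture_amp Amplitude (8-bit intensity units) of
#'   organelle-scale intensity fluctuations inside cells.
#' @param border_contrast Intensity drop of the ~2 px cell rim relative
#'   to the cell body.
#' @param background_level Mean background intensity (8-bit units).
#' @param background_noise_sd Gaussian sensor noise SD on the
#'   background.
#' @param illumination_gradient_amp Peak-to-peak amplitude of a linear
#'   illumination gradient across the frame.
#' @param n_debris Number of small high-contrast debris discs (excluded
#'   from ground truth).
#' @param debris_radius_range Debris disc radius range in pixels.
#' @param nm_per_pixel Calibration attached to the generated image
#'   (default 110, a typical 63x water-objective sampling).
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(width = 256L, height = 256L,
                         n_cells = 5L,
                         cell_radius_range = c(18, 32),
                         interior_texture_amp = 50,
                         border_contrast = 60,
                         background_level = 180,
                         background_noise_sd = 3,
                         illumination_gradient_amp = 12,
                         n_debris = 2L,
                         debris_radius_range = c(2, 4),
                         nm_per_pixel = 110) {
  stopifnot(width >= 8, height >= 8, n_cells >= 0, n_debris >= 0,
            length(cell_radius_range) == 2L, all(cell_radius_range > 0),
            length(debris_radius_range) == 2L, all(debris_radius_range > 0),
            interior_texture_amp >= 0, border_contrast >= 0,
            background_noise_sd >= 0, illumination_gradient_amp >= 0,
            background_level >= 0, background_level <= 255)
  structure(as.list(environment()), class = "scene_params")
}

# Evaluate an expression with a private, named RNG stream (Mersenne-
# Twister + inversion), restoring the caller's RNG state afterwards so
# scene generation is reproducible and side-effect free.
with_scene_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Generate a synthetic brightfield scene with ground truth
#'
#' Deterministic for a fixed `(params, seed)` pair: the generator uses a
#' named portable RNG (Mersenne-Twister with inversion normals) and
#' restores the caller's RNG state on exit.
#'
#' @param params A [scene_params()] object.
#' @param seed Integer seed.
#' @return An object of class `synthetic_scene`: list with `image`
#'   ([bf_image()], 8-bit), `truth` ([bf_mask()]), `params`, `seed`.
#' @export
generate_scene <- function(params = scene_params(), seed = 1L) {
  stopifnot(inherits(params, "scene_params"))
  with_scene_rng(seed, {
    h <- as.integer(params$height); w <- as.integer(params$width)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)

    # background: level + linear gradient of given peak-to-peak + noise
    theta <- stats::runif(1, 0, 2 * pi)
    proj <- (cos(theta) * (xx - 1) / max(1, w - 1) +
             sin(theta) * (yy - 1) / max(1, h - 1))
    rng <- range(proj)
    grad <- if (diff(rng) > 0)
      (proj - rng[1L]) / diff(rng) * params$illumination_gradient_amp -
        params$illumination_gradient_amp / 2
    else 0
    img <- params$background_level + grad
    if (params$background_noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, params$background_noise_sd), h, w)

    truth <- matrix(FALSE, h, w)
    rmax <- max(params$cell_radius_range)
    if (params$n_cells > 0 && (w <= 2 * rmax || h <= 2 * rmax))
      stop("frame too small to place cells of the requested radius")
    for (i in seq_len(params$n_cells)) {
      a <- stats::runif(1, params$cell_radius_range[1L], params$cell_radius_range[2L])
      b <- stats::runif(1, params$cell_radius_range[1L], params$cell_radius_range[2L])
      phi <- stats::runif(1, 0, pi)
      # overlap between cells is allowed, as in culture; only the frame
      # margin constrains placement (checked above)
      cx <- stats::runif(1, rmax + 1, w - rmax)
      cy <- stats::runif(1, rmax + 1, h - rmax)
      dx <- xx - cx; dy <- yy - cy
      u <- (dx * cos(phi) + dy * sin(phi)) / a
      v <- (-dx * sin(phi) + dy * cos(phi)) / b
      rho2 <- u^2 + v^2
      inside <- rho2 <= 1
      rim_frac <- 1 - 2 / min(a, b)           # ~2 px wide rim
      rim <- inside & rho2 > rim_frac^2
      body <- inside & !rim

      # interior: organelle-scale blobs + fine noise
      img[rim] <- img[rim] - params$border_contrast
      if (params$interior_texture_amp > 0) {
        area <- sum(body)
        n_blob <- max(1L, round(area * 0.02))
        bidx <- which(body)
        centers <- sample(bidx, min(n_blob, length(bidx)))
        for (ci in centers) {
          by <- (ci - 1L) %% h + 1L; bx <- (ci - 1L) %/% h + 1L
          br <- stats::runif(1, 1, 3)
          amp <- sample(c(-1, 1), 1L) * params$interior_texture_amp
          sely <- max(1L, by - 3L):min(h, by + 3L)
          selx <- max(1L, bx - 3L):min(w, bx + 3L)
          sub <- (yy[sely, selx] - by)^2 + (xx[sely, selx] - bx)^2 <= br^2
          blk <- img[sely, selx]
          blk[sub & body[sely, selx]] <- blk[sub & body[sely, selx]] + amp
          img[sely, selx] <- blk
        }
        img[body] <- img[body] +
          stats::rnorm(sum(body), 0, params$interior_texture_amp / 5)
      }
      truth <- truth | inside
    }

    # debris: small dark high-contrast discs on the background,
    # excluded from ground truth
    for (i in seq_len(params$n_debris)) {
      r <- stats::runif(1, params$debris_radius_range[1L],
                        params$debris_radius_range[2L])
      cx <- stats::runif(1, r + 1, w - r)
      cy <- stats::runif(1, r + 1, h - r)
      disc <- (xx - cx)^2 + (yy - cy)^2 <= r^2
      img[disc & !truth] <- img[disc & !truth] - 90
    }

    px <- round(img)
    px[px < 0] <- 0; px[px > 255] <- 255
    storage.mode(px) <- "integer"
    structure(list(
      image = bf_image(px, bit_depth = 8L, nm_per_pixel = params$nm_per_pixel),
      truth = bf_mask(truth, params$nm_per_pixel),
      params = params, seed = as.integer(seed)),
      class = "synthetic_scene")
  })
}
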