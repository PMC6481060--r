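# Independent brute-force oracles used to check the vectorized
# implementation. These deliberately take the slow scalar route
# (per-pixel loops, explicit neighbor enumeration, queue flood fill,
# dense convolution) so they share no code path with the package.

# Count-based morphology: per-pixel 8-neighbor loop.
oracle_count_morph <- function(mask, op = c("erode", "dilate"),
                               count, pad = FALSE, iterations = 1L) {
  op <- match.arg(op)
  h <- nrow(mask); w <- ncol(mask)
  cur <- mask
  for (it in seq_len(iterations)) {
    nxt <- cur
    for (y in seq_len(h)) for (x in seq_len(w)) {
      n_bg <- 0L; n_fg <- 0L
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0L && dx == 0L) next
        yy <- y + dy; xx <- x + dx
        if (yy < 1L || yy > h || xx < 1L || xx > w) {
          # out-of-image: foreground for padded erosion, else background
          if (op == "erode" && pad) n_fg <- n_fg + 1L else n_bg <- n_bg + 1L
        } else if (cur[yy, xx]) n_fg <- n_fg + 1L else n_bg <- n_bg + 1L
      }
      if (op == "erode") {
        if (cur[y, x] && n_bg >= count) nxt[y, x] <- FALSE
      } else {
        if (!cur[y, x] && n_fg >= count) nxt[y, x] <- TRUE
      }
    }
    cur <- nxt
  }
  cur
}

# All 65,536 4x4 masks at once, via an explicit 16x16 adjacency matrix
# (columns of the mask matrix are the flattened 4x4 rasters).
oracle_morph_batch_4x4 <- function(masks01, op, count, pad = FALSE) {
  stopifnot(nrow(masks01) == 16L)
  idx <- function(y, x) (x - 1L) * 4L + y
  A <- matrix(0, 16L, 16L)
  deg <- integer(16L)
  for (y in 1:4) for (x in 1:4) {
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      yy <- y + dy; xx <- x + dx
      if (yy >= 1L && yy <= 4L && xx >= 1L && xx <= 4L) {
        A[idx(y, x), idx(yy, xx)] <- 1
        deg[idx(y, x)] <- deg[idx(y, x)] + 1L
      }
    }
  }
  fg <- A %*% masks01                       # in-image foreground neighbors
  out_of_image <- 8L - deg
  if (op == "erode") {
    bg <- (deg - fg) + if (pad) 0L else out_of_image
    masks01 * (bg < count)
  } else {
    (masks01 + (1 - masks01) * (fg >= count) > 0) * 1
  }
}

# Maximum filter: per-pixel loop over explicitly enumerated circular
# offsets (shrinking window at borders).
oracle_max_filter <- function(m, radius) {
  r_int <- ceiling(radius)
  offs <- list()
  for (dy in -r_int:r_int) for (dx in -r_int:r_int)
    if (dy^2 + dx^2 <= radius^2 + 1) offs[[length(offs) + 1L]] <- c(dy, dx)
  h <- nrow(m); w <- ncol(m)
  out <- m
  for (y in seq_len(h)) for (x in seq_len(w)) {
    best <- -Inf
    for (o in offs) {
      yy <- y + o[1L]; xx <- x + o[2L]
      if (yy >= 1L && yy <= h && xx >= 1L && xx <= w && m[yy, xx] > best)
        best <- m[yy, xx]
    }
    out[y, x] <- best
  }
  out
}

# Dense 2-D correlation with replicate padding (for checking the
# separable Gaussian-derivative convolution).
oracle_conv2_replicate <- function(m, kx, ky) {
  hwx <- (length(kx) - 1L) %/% 2L
  hwy <- (length(ky) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    acc <- 0
    for (oy in -hwy:hwy) for (ox in -hwx:hwx) {
      yy <- min(max(y + oy, 1L), h)
      xx <- min(max(x + ox, 1L), w)
      acc <- acc + ky[oy + hwy + 1L] * kx[ox + hwx + 1L] * m[yy, xx]
    }
    out[y, x] <- acc
  }
  out
}

# Scalar non-maximum suppression with the same directional rule
# (>= forward, > backward), written as naive per-pixel code.
oracle_nms <- function(gx, gy, mag) {
  h <- nrow(mag); w <- ncol(mag)
  at <- function(y, x) if (y < 1 || y > h || x < 1 || x > w) 0 else mag[y, x]
  out <- mag
  for (y in seq_len(h)) for (x in seq_len(w)) {
    m <- mag[y, x]
    if (m <= 0) { out[y, x] <- 0; next }
    ax <- abs(gx[y, x]); ay <- abs(gy[y, x])
    sx <- if (gx[y, x] >= 0) 1L else -1L
    sy <- if (gy[y, x] >= 0) 1L else -1L
    if (ax >= ay) {
      t <- if (ax == 0) 0 else ay / ax
      nf <- (1 - t) * at(y, x + sx) + t * at(y + sy, x + sx)
      nb <- (1 - t) * at(y, x - sx) + t * at(y - sy, x - sx)
    } else {
      t <- ax / ay
      nf <- (1 - t) * at(y + sy, x) + t * at(y + sy, x + sx)
      nb <- (1 - t) * at(y - sy, x) + t * at(y - sy, x - sx)
    }
    if (!(m >= nf && m > nb)) out[y, x] <- 0
  }
  out
}

# Hysteresis: queue-based 8-connected flood fill from the seed pixels.
oracle_hysteresis <- function(thinned, low, high) {
  h <- nrow(thinned); w <- ncol(thinned)
  lowm <- thinned >= low
  out <- matrix(FALSE, h, w)
  queue <- which(thinned >= high)
  out[queue] <- TRUE
  while (length(queue) > 0L) {
    i <- queue[1L]; queue <- queue[-1L]
    y <- (i - 1L) %% h + 1L; x <- (i - 1L) %/% h + 1L
    for (dy in -1:1) for (dx in -1:1) {
      yy <- y + dy; xx <- x + dx
      if (yy >= 1L && yy <= h && xx >= 1L && xx <= w &&
          lowm[yy, xx] && !out[yy, xx]) {
        out[yy, xx] <- TRUE
        queue <- c(queue, (xx - 1L) * h + yy)
      }
    }
  }
  out
}

# Random logical mask with reproducible content.
random_mask <- function(h, w, p = 0.5, seed = 1L) {
  withr::with_seed(seed, matrix(stats::runif(h * w) < p, h, w))
}

# Random 8-bit image matrix.
random_image8 <- function(h, w, seed = 1L) {
  withr::with_seed(seed,
    matrix(sample.int(256L, h * w, replace = TRUE) - 1L, h, w))
}
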