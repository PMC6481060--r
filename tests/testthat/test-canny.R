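step_image <- function(h = 32, w = 32, at = 16) {
  cbind(matrix(0, h, at), matrix(255, h, w - at))
}

test_that("gaussian_gradient is zero on constant images and matches dense convolution", {
  gg <- gaussian_gradient(matrix(100, 16, 16), radius = 1.75)
  expect_true(all(abs(gg$magnitude) < 1e-9))

  # small random image vs brute-force dense correlation with the same taps
  m <- random_image8(12, 14, seed = 21)
  sigma <- 1.75
  hw <- ceiling(4 * sigma)
  x <- (-hw):hw
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  dg <- -x / sigma^2 * g
  gg <- gaussian_gradient(m, sigma)
  expect_equal(gg$gx, oracle_conv2_replicate(m, kx = dg, ky = g),
               tolerance = 1e-10)
  expect_equal(gg$gy, oracle_conv2_replicate(m, kx = g, ky = dg),
               tolerance = 1e-10)
})

test_that("gradient of a vertical step peaks at the step and has zero gy", {
  m <- step_image()
  gg <- gaussian_gradient(m, 1.75)
  expect_true(all(abs(gg$gy) < 1e-9))
  peak_cols <- apply(gg$magnitude, 1, which.max)
  expect_true(all(peak_cols %in% c(16L, 17L)))
  # transposition swaps the gradient components
  ggt <- gaussian_gradient(t(m), 1.75)
  expect_equal(ggt$gx, t(gg$gy), tolerance = 1e-12)
  expect_equal(ggt$gy, t(gg$gx), tolerance = 1e-12)
  expect_equal(ggt$magnitude, t(gg$magnitude), tolerance = 1e-12)
})

test_that("non-maximum suppression matches the per-pixel oracle", {
  for (seed in 1:4) {
    m <- random_image8(18, 18, seed = seed)
    gg <- gaussian_gradient(m, 1.5)
    expect_equal(non_maximum_suppression(gg$gx, gg$gy, gg$magnitude),
                 oracle_nms(gg$gx, gg$gy, gg$magnitude),
                 tolerance = 1e-12)
  }
})

test_that("NMS keeps isolated peaks, zeroes flat fields, thins step ridges to 1 px", {
  z <- matrix(0, 7, 7)
  gx <- z; gy <- z; mag <- z
  mag[4, 4] <- 5; gx[4, 4] <- 5
  expect_equal(non_maximum_suppression(gx, gy, mag)[4, 4], 5)
  expect_true(all(non_maximum_suppression(z, z, z) == 0))

  gg <- gaussian_gradient(step_image(), 1.75)
  thin <- non_maximum_suppression(gg$gx, gg$gy, gg$magnitude)
  ridge_width <- rowSums(thin > max(thin) / 2)
  expect_true(all(ridge_width == 1))
})

test_that("hysteresis links weak pixels through seeds, 8-connected", {
  chain <- matrix(c(9, 5, 5, 0.05), 1, 4)
  out <- hysteresis(chain, low = 0.1, high = 8)$pixels
  expect_equal(as.vector(out), c(TRUE, TRUE, TRUE, FALSE))

  # diagonal-only contact still links (8-connectivity)
  diagm <- matrix(0, 3, 3); diagm[1, 1] <- 9; diagm[2, 2] <- 1; diagm[3, 3] <- 1
  expect_equal(sum(hysteresis(diagm, 0.5, 8)$pixels), 3L)

  # no seed -> empty; low == high collapses to a simple threshold
  expect_equal(sum(hysteresis(chain, 0.1, 100)$pixels), 0L)
  expect_equal(hysteresis(chain, 8, 8)$pixels, chain >= 8, ignore_attr = TRUE)
})

test_that("hysteresis matches the flood-fill oracle on random fields", {
  for (seed in 1:5) {
    thinned <- withr::with_seed(seed,
      matrix(ifelse(stats::runif(576) < 0.3, stats::runif(576, 0, 12), 0), 24, 24))
    expect_equal(hysteresis(thinned, 0.5, 8)$pixels,
                 oracle_hysteresis(thinned, 0.5, 8),
                 ignore_attr = TRUE)
  }
})

test_that("canny finds a connected single-pixel boundary on a two-region image", {
  img <- bf_image(step_image(32, 32, 16))
  mask <- canny(img, canny_params(1.75, 0.1, 8))$pixels
  expect_true(all(rowSums(mask) == 1))          # one pixel per row
  cols <- apply(mask, 1, which)
  expect_true(all(abs(diff(cols)) <= 1))        # 8-connected curve
  expect_true(all(cols %in% 15:18))             # localized at the step
})

test_that("canny degenerate cases give empty masks", {
  expect_equal(sum(canny(bf_image(matrix(128L, 20, 20)))$pixels), 0L)
  img <- bf_image(step_image())
  expect_equal(sum(canny(img, canny_params(1.75, 0.1, 1e9))$pixels), 0L)
})

test_that("raising either threshold never adds edge pixels", {
  for (seed in 1:6) {
    img <- random_image8(24, 24, seed = 100 + seed)
    base <- canny(img, canny_params(1.5, 0.5, 4))$pixels
    hi <- canny(img, canny_params(1.5, 0.5, 6))$pixels
    lo <- canny(img, canny_params(1.5, 1.5, 4))$pixels
    expect_true(all(base | !hi))   # hi subset of base
    expect_true(all(base | !lo))
  }
})

test_that("edge mask is a subset of the NMS support and survives contrast gain", {
  img <- random_image8(24, 24, seed = 42)
  gg <- gaussian_gradient(img, 1.75)
  thin <- non_maximum_suppression(gg$gx, gg$gy, gg$magnitude)
  mask <- canny(img, canny_params(1.75, 0.1, 8))$pixels
  expect_true(all(thin[mask] > 0))

  # gain > 1 scales all magnitudes up: the seed set can only grow
  seeds1 <- non_maximum_suppression(gg$gx, gg$gy, gg$magnitude) * MAGNITUDE_SCALE >= 8
  gg2 <- gaussian_gradient(img * 1.5, 1.75)
  seeds2 <- non_maximum_suppression(gg2$gx, gg2$gy, gg2$magnitude) * MAGNITUDE_SCALE >= 8
  expect_true(all(seeds2 | !seeds1))
})

test_that("canny_params validates its invariants", {
  expect_error(canny_params(0, 0.1, 8), "positive")
  expect_error(canny_params(1.75, 0, 8), "threshold")
  expect_error(canny_params(1.75, 9, 8), "threshold")
})
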