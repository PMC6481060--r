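test_that("circular kernels follow the rank-filter inclusion rule", {
  # dy^2 + dx^2 <= r^2 + 1; reproduces the reference kernels for the
  # fractional radii of the calibration table
  expect_equal(nrow(make_circular_kernel(1)$offsets), 9L)     # full 3x3
  expect_equal(nrow(make_circular_kernel(1.25)$offsets), 9L)  # full 3x3
  expect_equal(nrow(make_circular_kernel(1.67)$offsets), 9L)  # still 3x3 (4 > 3.79)
  expect_equal(nrow(make_circular_kernel(2.5)$offsets), 21L)  # 5x5 minus corners
  k5 <- make_circular_kernel(5)$offsets
  expect_true(all(k5[, "dy"]^2 + k5[, "dx"]^2 <= 26))
  # contains origin, symmetric under negation
  for (r in c(1, 1.25, 1.67, 2.5, 5)) {
    off <- make_circular_kernel(r)$offsets
    expect_true(any(off[, 1] == 0 & off[, 2] == 0))
    key <- paste(off[, 1], off[, 2])
    expect_setequal(key, paste(-off[, 1], -off[, 2]))
  }
  expect_error(make_circular_kernel(0), "positive")
})

test_that("maximum_filter matches the per-pixel kernel oracle", {
  for (r in c(1, 1.25, 1.67, 2.5, 5)) {
    m <- random_image8(16, 16, seed = round(100 * r))
    expect_equal(maximum_filter(m, r), oracle_max_filter(m, r),
                 ignore_attr = TRUE)
  }
})

test_that("maximum_filter basics: identity on constants, disc from a point, dominates input", {
  const <- matrix(7, 9, 9)
  expect_equal(maximum_filter(const, 5), const)
  # a single bright pixel spreads to exactly the kernel footprint
  m <- matrix(0, 21, 21); m[11, 11] <- 1
  out <- maximum_filter(m, 5)
  expect_equal(sum(out), nrow(make_circular_kernel(5)$offsets))
  img <- random_image8(12, 12, seed = 9)
  expect_true(all(maximum_filter(img, 2.5) >= img))
})

test_that("maximum_filter on binary input equals circular count-1 dilation", {
  m <- random_mask(20, 20, p = 0.1, seed = 8)
  out <- maximum_filter(m * 1, 2.5) > 0
  # independent route: union of kernel-shifted copies
  off <- make_circular_kernel(2.5)$offsets
  ref <- matrix(FALSE, 20, 20)
  for (i in seq_len(nrow(off))) {
    for (y in 1:20) for (x in 1:20) {
      yy <- y + off[i, 1]; xx <- x + off[i, 2]
      if (yy >= 1 && yy <= 20 && xx >= 1 && xx <= 20 && m[yy, xx])
        ref[y, x] <- TRUE
    }
  }
  expect_equal(out, ref)
})

test_that("count_erode and count_dilate match the 8-neighbor oracle", {
  for (seed in 1:4) for (count in c(1L, 3L, 8L)) {
    m <- random_mask(9, 9, p = 0.5, seed = seed)
    for (pad in c(TRUE, FALSE)) {
      expect_equal(count_erode(m, morph_options(1L, count, pad)),
                   oracle_count_morph(m, "erode", count, pad))
    }
    expect_equal(count_dilate(m, morph_options(1L, count)),
                 oracle_count_morph(m, "dilate", count))
    # multi-iteration agreement
    expect_equal(count_erode(m, morph_options(3L, count, pad = TRUE)),
                 oracle_count_morph(m, "erode", count, pad = TRUE, iterations = 3L))
  }
})

test_that("morphology limit cases behave as documented", {
  empty <- matrix(FALSE, 8, 8)
  full <- matrix(TRUE, 8, 8)
  o <- morph_options(5L, 3L, pad = TRUE)
  expect_equal(count_erode(empty, o), empty)
  expect_equal(count_dilate(empty, o), empty)
  # padded erosion never eats a full mask (borders protected)
  expect_equal(count_erode(full, o), full)
  # unpadded erosion does shrink it from the borders
  expect_lt(sum(count_erode(full, morph_options(1L, 3L, pad = FALSE))), 64L)
  # count=1 dilation of a point gives the full 3x3 block
  pt <- matrix(FALSE, 5, 5); pt[3, 3] <- TRUE
  expect_equal(sum(count_dilate(pt, morph_options(1L, 1L))), 9L)
  # dilation is extensive, erosion anti-extensive
  m <- random_mask(12, 12, p = 0.5, seed = 2)
  expect_true(all(count_dilate(m, morph_options(2L, 3L)) | !m))
  expect_true(all(m | !count_erode(m, morph_options(2L, 3L, pad = TRUE))))
})

test_that("interior duality and monotonicity hold", {
  for (seed in 1:3) {
    m <- random_mask(32, 32, p = 0.5, seed = 40 + seed)
    er <- count_erode(m, morph_options(1L, 3L, pad = FALSE))
    di <- !count_dilate(!m, morph_options(1L, 3L))
    interior <- matrix(FALSE, 32, 32); interior[2:31, 2:31] <- TRUE
    expect_equal(er[interior], di[interior])
    # m1 subset m2 => erode(m1) subset erode(m2), same for dilate
    m2 <- m | random_mask(32, 32, p = 0.2, seed = 80 + seed)
    expect_true(all(count_erode(m2, morph_options(1L, 3L, pad = TRUE)) |
                      !count_erode(m, morph_options(1L, 3L, pad = TRUE))))
    expect_true(all(count_dilate(m2, morph_options(1L, 3L)) |
                      !count_dilate(m, morph_options(1L, 3L))))
  }
})

test_that("closing fills small holes; opening removes small specks", {
  # solid disc with a 2 px hole
  m <- matrix(FALSE, 41, 41)
  yy <- row(m); xx <- col(m)
  m[(yy - 21)^2 + (xx - 21)^2 <= 15^2] <- TRUE
  holed <- m
  holed[21, 20:21] <- FALSE
  closed <- binary_close(holed, morph_options(10L, 3L, pad = TRUE))
  expect_true(all(closed[(yy - 21)^2 + (xx - 21)^2 <= 13^2]))  # hole gone
  # closing is locally bounded: compare against the oracle composition
  ref <- holed
  for (i in 1:10) ref <- oracle_count_morph(ref, "dilate", 3L)
  for (i in 1:10) ref <- oracle_count_morph(ref, "erode", 3L, pad = TRUE)
  expect_equal(closed, ref)

  # isolated 2x2 speck has >= 5 background neighbors everywhere: opened away
  speck <- matrix(FALSE, 15, 15); speck[7:8, 7:8] <- TRUE
  expect_equal(sum(binary_open(speck, morph_options(1L, 3L))), 0L)
  # a large blob survives opening with bounded change
  blob <- (yy - 21)^2 + (xx - 21)^2 <= 12^2
  opened <- binary_open(blob, morph_options(10L, 3L))
  oref <- blob
  for (i in 1:10) oref <- oracle_count_morph(oref, "erode", 3L)
  for (i in 1:10) oref <- oracle_count_morph(oref, "dilate", 3L)
  expect_equal(opened, oref)
  # count-3 opening rounds a disc this size toward a diamond; the blob
  # survives but loses substantial boundary area (exact shape pinned by
  # the oracle equality above)
  expect_gt(sum(opened), 0.35 * sum(blob))
})

test_that("morph_options validates its invariants", {
  expect_error(morph_options(0, 3), "iterations")
  expect_error(morph_options(1, 0), "count")
  expect_error(morph_options(1, 9), "count")
  expect_error(morph_options(1.5, 3), "iterations")
})
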