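test_that("blur score matches a naive double-loop oracle and its conventions", {
  expect_identical(crete_blur_score(matrix(0.5, 10, 10)), 1)
  # 0/1 checkerboard: high-frequency content, low blur score
  cb <- outer(1:32, 1:28, function(i, j) (i + j) %% 2)
  expect_identical(crete_blur_score(cb), naive_crete(cb))
  expect_lt(crete_blur_score(cb), 0.4)
  sp <- make_speckle(24, 24, seed = 8)
  expect_equal(crete_blur_score(sp), naive_crete(sp), tolerance = 1e-12)
  expect_error(crete_blur_score(matrix(1, 2, 2)), "3x3")
})

test_that("blur score increases monotonically with Gaussian blur width", {
  img <- make_speckle(32, 28, seed = 5)
  s05 <- crete_blur_score(gauss_blur(img, 0.5))
  s1 <- crete_blur_score(gauss_blur(img, 1))
  s2 <- crete_blur_score(gauss_blur(img, 2))
  expect_true(s05 <= s1 && s1 <= s2)
  expect_true(all(c(s05, s1, s2) >= 0 & c(s05, s1, s2) <= 1))
})

test_that("blur map tiles the image and equals the per-tile score", {
  set.seed(2)
  img <- matrix(runif(64 * 112), 64, 112)
  bm <- compute_blur_map(img, c(4L, 8L))
  expect_equal(dim(bm$values), c(4L, 8L))
  # oracle: direct double loop over tiles
  for (i in 1:4) for (j in 1:8) {
    tile <- img[((i - 1) * 16 + 1):(i * 16), ((j - 1) * 14 + 1):(j * 14)]
    expect_identical(bm$values[i, j], crete_blur_score(tile))
  }
  expect_error(compute_blur_map(img, c(5L, 8L)), "height")
  expect_error(compute_blur_map(img, c(4L, 9L)), "width")
})

test_that("blur map of the full-size grid is 8x16 and uniform blur is flat", {
  img <- matrix(rep(sin(seq(0, 8 * pi, length.out = 28 * 2)), length.out = 256 * 448),
                256, 448)
  # tile the same texture into every 32x28 tile so all tiles are identical
  tile <- make_speckle(32, 28, seed = 7)
  img <- tile[rep(1:32, 8), rep(1:28, 16)]
  bm <- compute_blur_map(img, c(8L, 16L))
  expect_equal(dim(bm$values), c(8L, 16L))
  expect_lt(diff(range(bm$values)), 1e-6)
})

test_that("blur map resolves a sharp/blurred left-right contrast", {
  img <- make_speckle(32, 112, seed = 9, density = 0.08)
  img[, 1:56] <- gauss_blur(img, 2.5)[, 1:56]   # blur the left half
  bm <- compute_blur_map(img, c(2L, 8L))
  expect_gt(mean(bm$values[, 1:4]), mean(bm$values[, 5:8]))
})

test_that("blur-value embedding is the sinusoidal encoding of the quantized value", {
  bm <- structure(list(values = matrix(0, 2, 4), grid_hw = c(2L, 4L)),
                  class = "blur_map")
  e0 <- embed_blur_map(bm, 8L)
  expect_equal(dim(e0), c(8L, 8L))
  expect_true(all(e0[, c(1, 3, 5, 7)] == 0))   # sin parts at index 0
  expect_true(all(e0[, c(2, 4, 6, 8)] == 1))   # cos parts at index 0
  # equal blur values embed identically; shape follows Np x C
  set.seed(1)
  v <- matrix(runif(8), 2, 4); v[2, 3] <- v[1, 1]
  bm2 <- structure(list(values = v, grid_hw = c(2L, 4L)), class = "blur_map")
  e <- embed_blur_map(bm2, 16L)
  expect_equal(dim(e), c(8L, 16L))
  # row-major flatten: grid (i,j) -> row (i-1)*w + j
  expect_equal(e[2 * 4 - 4 + 3, ], e[1, ])
  expect_warning(embed_blur_map(structure(list(values = matrix(1.2, 1, 4),
                                               grid_hw = c(1L, 4L)),
                                          class = "blur_map"), 8L), "clipped")
})

test_that("full-size embedded blur map is 128 x 192", {
  set.seed(3)
  bm <- structure(list(values = matrix(runif(128), 8, 16),
                       grid_hw = c(8L, 16L)), class = "blur_map")
  expect_equal(dim(embed_blur_map(bm, 192L)), c(128L, 192L))
})

test_that("focus metrics behave on degenerate and blurred inputs", {
  flat <- matrix(0.3, 24, 24)
  expect_equal(focus_metric(flat, "LAPV"), 0)
  expect_equal(focus_metric(flat, "H-FFT"), 0)
  img <- make_speckle(32, 32, seed = 4)
  blurred <- gauss_blur(img, 2)
  expect_gt(focus_metric(img, "LAPV"), focus_metric(blurred, "LAPV"))
  expect_gt(focus_metric(img, "H-FFT"), focus_metric(blurred, "H-FFT"))
  expect_gt(focus_metric(img, "GEDR"), focus_metric(blurred, "GEDR"))
  expect_lt(focus_metric(img, "NFBM"), focus_metric(blurred, "NFBM"))
  expect_error(focus_metric(img, "VOLL"), "valid names")
})

test_that("focus metrics are offset-invariant except MoI", {
  img <- make_speckle(24, 24, seed = 6) * 0.8
  shifted <- img + 0.1
  for (nm in c("NFBM", "H-FFT", "LAPV", "GEDR"))
    expect_equal(focus_metric(shifted, nm), focus_metric(img, nm),
                 tolerance = 1e-8, label = nm)
  expect_false(isTRUE(all.equal(focus_metric(shifted, "MoI"),
                                focus_metric(img, "MoI"))))
})

test_that("distortion rates follow their definition and locate the flat band", {
  # constant series: no distortion anywhere, full span is usable
  ds <- distortion_study(seq(-5, 5), rep(2, 11))
  expect_true(all(ds$rates$rate_pct == 0))
  expect_equal(ds$working_range, c(-5, 5))
  # the definition: 100 * |adjacent difference| / mean magnitude
  ang <- seq(-2, 2)
  v <- abs(ang)
  ds2 <- distortion_study(ang, v)
  expect_equal(ds2$rates$rate_pct, 100 * abs(diff(v)) / mean(abs(v)),
               tolerance = 1e-12)
  # a sawtooth of unit mean and unit adjacent difference: every rate 100%
  ds2b <- distortion_study(0:5, rep(c(0.5, 1.5), 3))
  expect_equal(ds2b$rates$rate_pct, rep(100, 5), tolerance = 1e-12)
  # flat inside [-1.5, 1.5], steep outside
  ang3 <- seq(-5, 5, by = 0.5)
  val3 <- ifelse(abs(ang3) <= 1.5, 1, 1 + 4 * (abs(ang3) - 1.5))
  ds3 <- distortion_study(ang3, val3)
  expect_equal(ds3$working_range, c(-1.5, 1.5), tolerance = 0.3)
  expect_true(all(ds3$rates$rate_pct >= 0))
  expect_error(distortion_study(c(0, 1), c(1, 2)), "at least 3")
  expect_error(distortion_study(c(0, 1, 1), c(1, 2, 3)), "increasing")
})
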