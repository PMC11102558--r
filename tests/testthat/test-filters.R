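# Operator-level behavior of the junction-map chain.

test_that("rolling-ball background subtraction flattens backgrounds and preserves small features", {
  # flat background is removed entirely
  flat <- image_channel(matrix(57L, 64, 64))
  expect_true(all(subtract_background(flat, 20)$pixels == 0L))

  # subtraction never raises a pixel
  set.seed(31)
  noisy <- image_channel(matrix(sample(0:255, 64 * 64, TRUE), 64, 64))
  expect_true(all(subtract_background(noisy, 10)$pixels <= noisy$pixels))

  # a bright disk smaller than the ball survives; agrees with the direct
  # ball-opening oracle
  img <- matrix(0, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    if ((i - 32)^2 + (j - 32)^2 <= 4^2) img[i, j] <- 200
  }
  got <- subtract_background(image_channel(clip8(img)), 10)$pixels
  oracle <- clip8(img - pmax(naive_ball_opening(img, 10), 0))
  expect_true(max(abs(got - oracle)) <= 1)
  expect_true(all(abs(got[img == 200] - 200) <= 1))

  expect_error(subtract_background(flat, 0), "radius")
})

test_that("gaussian blur preserves mass and composes across passes", {
  flat <- image_channel(matrix(120L, 48, 48))
  expect_identical(gaussian_blur(flat, 2, 1)$pixels, flat$pixels)

  # reflective boundary keeps total intensity (up to quantization)
  set.seed(7)
  img <- image_channel(matrix(sample(40:200, 48 * 48, TRUE), 48, 48))
  one <- gaussian_blur(img, 2, 1)
  expect_lt(abs(sum(one$pixels) - sum(img$pixels)) / sum(img$pixels), 1e-3)

  # two passes at sigma equal one pass at sigma * sqrt(2) within 1 unit
  point <- matrix(0L, 65, 65); point[33, 33] <- 255L
  double_pass <- gaussian_blur(image_channel(point), 2.0, 2)$pixels
  single_wide <- gaussian_blur(image_channel(point), 2.0 * sqrt(2), 1)$pixels
  expect_true(max(abs(double_pass - single_wide)) <= 1)

  expect_error(gaussian_blur(img, -1), "sigma")
  expect_error(gaussian_blur(img, 2, 0), "passes")
})

test_that("sharpen applies the fixed 3x3 kernel with clipping", {
  flat <- image_channel(matrix(88L, 32, 32))
  expect_identical(sharpen(flat)$pixels, flat$pixels)

  point <- matrix(0L, 21, 21); point[11, 11] <- 40L
  sh <- sharpen(image_channel(point))$pixels
  expect_identical(sh[11, 11], 120L)  # 40 * 12 / 4
  expect_identical(sh[11, 12], 0L)    # negative response clipped

  # agrees with a direct convolution oracle on a random image
  set.seed(12)
  img <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  kernel <- matrix(-1, 3, 3); kernel[2, 2] <- 12
  oracle <- clip8(pmin(pmax(naive_conv3(img, kernel) / 4, 0), 255))
  expect_identical(sharpen(image_channel(img))$pixels, oracle)

  # checkerboard contrast is not decreased anywhere
  cb <- clip8(255 * outer(1:16, 1:16, function(i, j) (i + j) %% 2))
  shc <- sharpen(image_channel(cb))$pixels
  expect_true(all(shc[cb == 255L] == 255L) && all(shc[cb == 0L] == 0L))
})

test_that("huang threshold minimizes the fuzziness criterion", {
  # symmetric bimodal image: classes split exactly at the threshold
  bi <- image_channel(matrix(rep(c(0L, 255L), each = 128), 16, 16))
  t0 <- huang_threshold(bi)
  expect_true(t0 >= 0 && t0 < 255)
  b <- binarize(bi, t0)
  expect_identical(sum(b), 128L)                    # the 255 class
  expect_true(all(bi$pixels[b] == 255L))

  # 50 random histograms: equals exhaustive-scan minimization
  set.seed(88)
  for (k in 1:50) {
    n_levels <- sample(5:40, 1)
    levels <- sort(sample(0:255, n_levels))
    counts <- sample(1:50, n_levels, TRUE)
    h <- integer(256); h[levels + 1] <- counts
    vals <- rep(levels, counts)
    pad <- 16 - length(vals) %% 16
    vals <- c(vals, rep(vals[1], pad))
    img <- image_channel(matrix(as.integer(vals), ncol = 16))
    hh <- tabulate(as.vector(img$pixels) + 1L, 256L)
    expect_identical(huang_threshold(img), as.integer(huang_brute_force(hh)))
  }

  expect_error(huang_threshold(image_channel(matrix(9L, 8, 8))), "threshold")
})

test_that("binarize uses the strict greater-than convention", {
  img <- image_channel(matrix(c(0L, 10L), 8, 8))
  expect_false(any(binarize(img, 255)))
  expect_identical(binarize(img, 0), img$pixels == 10L)
  b <- binarize(img, 5)
  rebin <- binarize(image_channel(clip8(255 * b)), 128)
  expect_identical(rebin, b)
})

test_that("binary dilation uses the full 3x3 element and is extensive", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  d1 <- dilate_binary(m, 1)
  expect_identical(sum(d1), 9L)
  expect_true(all(d1[4:6, 4:6]))
  expect_identical(dilate_binary(m, 0), m)
  set.seed(5)
  r <- matrix(runif(400) > 0.8, 20, 20)
  expect_gte(sum(dilate_binary(r, 2)), sum(r))
  expect_true(all(r[dilate_binary(r, 2) == FALSE] == FALSE))
})

test_that("close_gaps repairs breaks but leaves closed loops alone", {
  # two collinear segments with a 4-px break become one component
  m <- matrix(FALSE, 21, 41)
  m[11, 3:17] <- TRUE
  m[11, 22:39] <- TRUE
  expect_identical(count_components8(m), 2L)
  bridged <- close_gaps(m, 10)
  expect_identical(count_components8(bridged), 1L)
  expect_true(all(m[bridged == FALSE] == FALSE))  # output contains input

  expect_identical(close_gaps(m, 0), m)

  # a closed loop has no endpoints and passes through unchanged
  loop <- matrix(FALSE, 30, 30)
  loop[10, 10:20] <- TRUE; loop[20, 10:20] <- TRUE
  loop[10:20, 10] <- TRUE; loop[10:20, 20] <- TRUE
  expect_identical(close_gaps(loop, 10), loop)
})

test_that("skeletonize thins to centered 1-px curves and is idempotent", {
  # filled 5x50 rectangle reduces to a single horizontal centerline
  m <- matrix(FALSE, 20, 70)
  m[8:12, 11:60] <- TRUE
  sk <- skeletonize(m)$skeleton_mask
  px <- which(sk, arr.ind = TRUE)
  expect_identical(count_components8(sk), 1L)
  expect_true(all(px[, 1] %in% 9:12))            # centered (ends may hook 1-2 px)
  expect_gte(mean(px[, 1] == 10), 0.9)           # overwhelmingly the center row
  expect_true(all(table(px[, 2]) == 1))          # 1 px wide
  expect_true(nrow(px) >= 42 && nrow(px) <= 52)  # ~46 px line

  expect_false(any(skeletonize(matrix(FALSE, 10, 10))$skeleton_mask))

  # idempotence on a realistic junction skeleton
  sim <- generate_monolayer(quick_config(noise_sigma = 0,
                                         illumination_amplitude = 0))
  tr <- trace_cell_outlines(sim$image)
  sk1 <- tr$skeleton$skeleton_mask
  expect_identical(skeletonize(sk1)$skeleton_mask, sk1)
})

test_that("provenance records every applied operator in order", {
  img <- image_channel(matrix(50L, 128, 128), "prov")
  out <- sharpen(gaussian_blur(subtract_background(img, 20), 2, 2))
  expect_match(out$provenance[1], "subtract_background")
  expect_match(out$provenance[2], "gaussian_blur")
  expect_match(out$provenance[3], "sharpen")
})
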