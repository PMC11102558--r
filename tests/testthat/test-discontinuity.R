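# The discontinuity statistic and its two-track construction.

test_that("the fixed-threshold junction mask composes subtraction and range thresholding", {
  zero <- image_channel(matrix(0L, 64, 64), "z")
  expect_true(all(junction_binary_mask(zero)$pixels == 0L))

  # flat value 21: background subtraction removes it before thresholding
  flat <- image_channel(matrix(21L, 64, 64))
  expect_true(all(junction_binary_mask(flat)$pixels == 0L))

  # a narrow bright ridge on black background maps to 255 on the ridge
  img <- matrix(0L, 64, 64)
  img[, 31:33] <- 200L
  jm <- junction_binary_mask(image_channel(clip8(img)))
  expect_true(all(jm$pixels[, 32] == 255L))
  expect_true(all(jm$pixels[, c(1:20, 45:64)] == 0L))
  expect_identical(sort(unique(as.vector(jm$pixels))), c(0L, 255L))
  expect_identical(jm$threshold_low, 21L)
})

test_that("plot profiles read each outline pixel exactly once, in order", {
  path <- rect_loop_path(10, 10, 12, 28)  # 76 px loop
  o <- cell_outline(1, path, "img")
  mk_mask <- function(px) {
    structure(list(pixels = px, source_image_id = "img",
                   threshold_low = 21L, threshold_high = 255L),
              class = "binary_junction_mask")
  }
  all255 <- mk_mask(matrix(255L, 50, 50))
  prof <- profile_outline(all255, o)
  expect_identical(prof, rep(255L, nrow(path)))

  all0 <- mk_mask(matrix(0L, 50, 50))
  expect_identical(profile_outline(all0, o), rep(0L, nrow(path)))

  # a 10-pixel gap crossing the outline shows as one maximal zero run
  px <- matrix(255L, 50, 50)
  px[path[21:30, , drop = FALSE]] <- 0L
  runs <- rle(profile_outline(mk_mask(px), o) == 0L)
  zero_runs <- runs$lengths[runs$values]
  expect_identical(zero_runs, 10L)

  out_of_bounds <- cell_outline(2, rect_loop_path(40, 40, 15, 15), "img")
  expect_error(profile_outline(mk_mask(matrix(255L, 50, 50)), out_of_bounds),
               "outside")
})

test_that("discontinuity ratio is the exact zero-pixel percentage", {
  expect_identical(discontinuity_ratio(c(rep(0, 50), rep(255, 150))), 25)
  expect_identical(discontinuity_ratio(rep(255, 200)), 0)
  expect_identical(discontinuity_ratio(rep(0, 200)), 100)
  expect_error(discontinuity_ratio(numeric()), "empty")
})

test_that("the ratio is invariant to outline starting pixel and direction", {
  sim <- generate_monolayer(quick_config(gap_fraction = 0.3, rng_seed = 9))
  tr <- trace_cell_outlines(sim$image)
  mask <- junction_binary_mask(tr$background_subtracted, subtract = FALSE)
  o <- Filter(function(o) !o$touches_border, tr$outlines)[[1]]
  base <- discontinuity_ratio(profile_outline(mask, o))
  n <- nrow(o$path)
  rotated <- cell_outline(o$cell_id, o$path[c(15:n, 1:14), ], o$image_id)
  reversed <- cell_outline(o$cell_id, o$path[n:1, ], o$image_id)
  expect_identical(discontinuity_ratio(profile_outline(mask, rotated)), base)
  expect_identical(discontinuity_ratio(profile_outline(mask, reversed)), base)
})

test_that("score_image emits one record per outline with image identity", {
  sim <- generate_monolayer(quick_config(gap_fraction = 0, rng_seed = 21),
                            image_id = "syn1", group_label = "ctrl")
  tr <- trace_cell_outlines(sim$image)
  sel <- suppressWarnings(select_outlines(tr$outlines, k = 4, rng_seed = 4))
  rec <- score_image(sim$image, sel)
  expect_identical(nrow(rec), length(sel))  # one record per outline
  expect_gte(nrow(rec), 3L)
  expect_true(all(rec$image_id == "syn1"))
  expect_true(all(rec$group_label == "ctrl"))
  expect_true(all(rec$ratio_percent ==
                    100 * rec$zero_pixels / rec$outline_pixels))
  # gap-free noiseless image: essentially no discontinuity
  expect_true(all(rec$ratio_percent <= 5))

  # an all-zero channel saturates the statistic at 100% for every cell
  zero <- image_channel(matrix(0L, 256, 256), "blank")
  rec0 <- score_image(zero, sel)
  expect_true(all(rec0$ratio_percent == 100))

  expect_identical(nrow(score_image(sim$image, list())), 0L)
})
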