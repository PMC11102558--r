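# The synthetic monolayer generator: configuration contracts, rendering
# invariants, ground-truth bookkeeping, determinism.

test_that("configuration invariants are enforced with the offending field named", {
  expect_error(simulation_config(image_size = c(64, 256)), "image_size")
  expect_error(simulation_config(n_cells = 3), "n_cells")
  expect_error(simulation_config(gap_fraction = 1), "gap_fraction")
  expect_error(simulation_config(gap_fraction = -0.1), "gap_fraction")
  expect_error(simulation_config(junction_width_sigma = 0), "junction_width_sigma")
  expect_error(simulation_config(junction_peak_intensity = 240,
                                 illumination_amplitude = 40),
               "illumination_amplitude")
  expect_error(simulation_config(noise_sigma = -1), "noise_sigma")
  expect_error(simulation_config(gap_length_pixels = 0), "gap_length_pixels")
})

test_that("zero-gap configs render the full junction with an empty gap mask", {
  sim <- generate_monolayer(quick_config(gap_fraction = 0))
  expect_false(any(sim$truth$gap_mask))
  expect_gt(sum(sim$truth$junction_mask), 0)
  expect_identical(sim$truth$realized_gap_fraction, 0)
})

test_that("noiseless rendering is exact: peak at junction centers, zero far away", {
  cfg <- quick_config(gap_fraction = 0, noise_sigma = 0,
                      illumination_amplitude = 0)
  sim <- generate_monolayer(cfg)
  px <- sim$image$pixels
  jm <- sim$truth$junction_mask
  expect_true(all(px[jm] == cfg$junction_peak_intensity))
  d <- matrix(as.numeric(EBImage::distmap(matrix(as.numeric(!jm), nrow(jm),
                                                 ncol(jm)))), nrow(jm), ncol(jm))
  far <- d > 4 * cfg$junction_width_sigma
  expect_true(all(px[far] == 0L))
})

test_that("the realized gap fraction hits the requested value by construction", {
  cfg <- simulation_config(image_size = c(512, 512), n_cells = 25,
                           gap_fraction = 0.30, rng_seed = 7)
  sim <- generate_monolayer(cfg)
  realized <- sum(sim$truth$gap_mask) / sum(sim$truth$junction_mask)
  expect_gte(realized, 0.25)
  expect_lte(realized, 0.35)
  # across the supported range, within +/- 0.05
  for (gf in c(0.1, 0.5, 0.8)) {
    s <- generate_monolayer(quick_config(gap_fraction = gf, rng_seed = 13))
    expect_lt(abs(s$truth$realized_gap_fraction - gf), 0.05)
  }
})

test_that("ground truth is internally consistent", {
  sim <- generate_monolayer(quick_config(gap_fraction = 0.3, rng_seed = 5))
  tru <- sim$truth
  expect_true(all(tru$junction_mask[tru$gap_mask]))        # gap subset of junction
  expect_true(all(tru$cell_label_map >= 1))
  expect_true(all(tru$cell_label_map <= 16))
  pc <- tru$per_cell_gap_fraction
  expect_true(all(pc[!is.na(pc)] >= 0 & pc[!is.na(pc)] <= 1))
  # no cell's border is entirely gap below gap_fraction 1
  s2 <- generate_monolayer(quick_config(gap_fraction = 0.7, rng_seed = 6))
  pc2 <- s2$truth$per_cell_gap_fraction
  expect_true(all(pc2[!is.na(pc2)] < 1))
})

test_that("identical configs reproduce images bit-exactly", {
  a <- generate_monolayer(quick_config(gap_fraction = 0.2))
  b <- generate_monolayer(quick_config(gap_fraction = 0.2))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$gap_mask, b$truth$gap_mask)
  c_ <- generate_monolayer(quick_config(gap_fraction = 0.2, rng_seed = 403L))
  expect_false(identical(a$image$pixels, c_$image$pixels))
})

test_that("realized gap fraction is strictly monotone in the request at fixed seed", {
  realized <- sapply(c(0, 0.1, 0.2, 0.4), function(gf) {
    generate_monolayer(quick_config(gap_fraction = gf,
                                    rng_seed = 77L))$truth$realized_gap_fraction
  })
  expect_true(all(diff(realized) > 0))
})

test_that("condition panels are deterministic with per-replicate seeds recorded", {
  base <- quick_config()
  panel <- generate_condition_panel(base, c(A = 0, B = 0.2, C = 0.3, D = 0.4),
                                    images_per_group = 2)
  expect_length(panel, 8)
  seeds <- attr(panel, "seeds")
  expect_length(unique(seeds), 8)
  panel2 <- generate_condition_panel(base, c(A = 0, B = 0.2, C = 0.3, D = 0.4),
                                     images_per_group = 2)
  expect_identical(panel[[5]]$image$pixels, panel2[[5]]$image$pixels)

  pAB <- generate_condition_panel(base, c(A = 0, B = 0.4), images_per_group = 2)
  mean_gap <- tapply(sapply(pAB, function(e) e$truth$realized_gap_fraction),
                     sapply(pAB, `[[`, "group"), mean)
  expect_gt(mean_gap["B"], mean_gap["A"])

  expect_error(generate_condition_panel(base, numeric()), "empty")
  expect_error(generate_condition_panel(base, c(A = 0), images_per_group = 0),
               "images_per_group")
})

test_that("panels round-trip through TIFF images and JSON truth files", {
  td <- withr::local_tempdir()
  base <- quick_config()
  panel <- generate_condition_panel(base, c(lo = 0, hi = 0.3),
                                    images_per_group = 2)
  manifest_path <- write_panel(panel, td)
  manifest <- read.csv(manifest_path)
  expect_identical(nrow(manifest), 4L)
  expect_true(all(file.exists(manifest$image_path)))
  expect_true(all(file.exists(manifest$truth_path)))

  img <- read_image_channel(manifest$image_path[1])
  expect_identical(img$pixels, panel[[1]]$image$pixels)

  tru <- read_truth_json(manifest$truth_path[3])
  expect_identical(tru$junction_mask, panel[[3]]$truth$junction_mask)
  expect_identical(tru$cell_label_map, panel[[3]]$truth$cell_label_map)
  expect_equal(tru$realized_gap_fraction, panel[[3]]$truth$realized_gap_fraction)
})
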