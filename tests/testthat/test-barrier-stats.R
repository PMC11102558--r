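# Group statistics and the TEER utility.

test_that("kruskal_wallis matches hand rank arithmetic and handles ties", {
  groups <- list(a = c(1, 2, 3), b = c(10, 11, 12))
  cmp <- kruskal_wallis(groups)
  expect_equal(cmp$H_statistic, kw_H_by_hand(groups), tolerance = 1e-12)
  expect_equal(cmp$H_statistic, 3.857142857, tolerance = 1e-6)
  expect_identical(cmp$df, 1L)

  tied <- list(a = c(1, 1, 2, 5), b = c(2, 2, 7, 7), c = c(1, 5, 5, 9))
  expect_equal(kruskal_wallis(tied)$H_statistic, kw_H_by_hand(tied),
               tolerance = 1e-12)

  same <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_identical(same$H_statistic, 0)
  expect_identical(same$p_value, 1)

  # degenerate: all values identical in both groups
  const <- kruskal_wallis(list(a = c(4, 4), b = c(4, 4, 4)))
  expect_identical(const$H_statistic, 0)
  expect_identical(const$p_value, 1)

  expect_error(kruskal_wallis(list(a = 1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, 4:6)), "named")
})

test_that("kruskal_wallis is invariant under strictly monotone transforms", {
  set.seed(42)
  g <- list(x = runif(12), y = runif(10) + 0.2, z = runif(8))
  h1 <- kruskal_wallis(g)$H_statistic
  h2 <- kruskal_wallis(lapply(g, function(v) exp(3 * v) - 1))$H_statistic
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("group summaries report box-plot quartiles with min/max whiskers", {
  v <- c(2, 9, 4, 7, 1, 5, 5, 8)
  cmp <- kruskal_wallis(list(g1 = v, g2 = v + 100))
  s <- cmp$group_summaries[cmp$group_summaries$group == "g1", ]
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  expect_identical(s$n, 8L)
  expect_equal(c(s$q1, s$median, s$q3), q)
  expect_identical(c(s$min, s$max), range(v))
})

test_that("type-I error of the chi-squared approximation is near nominal", {
  set.seed(1234)
  reject <- logical(1000)
  for (i in 1:1000) {
    g <- list(a = rnorm(25), b = rnorm(25), c = rnorm(25))
    reject[i] <- kruskal_wallis(g)$p_value < 0.05
  }
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("chi-squared p agrees with the exact permutation null for small groups", {
  # The permutation null of H is discrete with sizable atoms at these
  # sample sizes; the continuous chi-squared approximation estimates its
  # mid-p (atom split in half), which is the standard comparator between
  # a discrete exact test and a continuous approximation.
  set.seed(99)
  for (rep in 1:20) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- round(rnorm(n1 + n2, 50, 12), 1)
    g <- list(a = x[1:n1], b = x[(n1 + 1):(n1 + n2)])
    cmp <- kruskal_wallis(g)
    # exact permutation distribution of H over all assignments
    idx <- combn(n1 + n2, n1)
    hs <- apply(idx, 2, function(sel) {
      kw_H_by_hand(list(a = x[sel], b = x[-sel]))
    })
    p_exact <- mean(hs > cmp$H_statistic + 1e-12) +
      0.5 * mean(abs(hs - cmp$H_statistic) <= 1e-12)
    expect_lt(abs(cmp$p_value - p_exact), 0.05)
  }
})

test_that("TEER follows the blank-corrected area-normalized formula", {
  expect_equal(compute_teer(100, 10), 28.8)
  expect_identical(compute_teer(100, 100), 0)
  expect_equal(compute_teer(5, 2, area_factor = 1), 3)
  expect_error(compute_teer(5, 7), "blank")
  expect_error(compute_teer(5, -1), "blank")
})

test_that("relative TEER normalizes to the baseline and is scale invariant", {
  s <- teer_series(c(0, 4, 8), c(100, 80, 55), c(10, 10, 10))
  expect_equal(s$teer, c(90, 70, 45) * 0.32)
  r <- relative_teer(s, 0)
  expect_identical(r$relative_teer[1], 1)
  expect_equal(r$relative_teer[3], 0.5)

  const <- relative_teer(teer_series(0:3, rep(80, 4), rep(5, 4)), 0)
  expect_true(all(const$relative_teer == 1))

  scaled <- relative_teer(teer_series(c(0, 4, 8), 3 * c(100, 80, 55),
                                      3 * c(10, 10, 10)), 0)
  expect_equal(scaled$relative_teer, r$relative_teer)

  expect_error(relative_teer(s, 2), "not found")
  z <- teer_series(c(0, 8), c(10, 50), c(10, 10))
  expect_error(relative_teer(z, 0), "baseline")
})

test_that("TEER CSVs round-trip through the reader", {
  td <- withr::local_tempdir()
  f <- file.path(td, "teer.csv")
  write.csv(data.frame(time_h = c(0, 8), resistance_ohm = c(100, 60),
                       blank_ohm = c(10, 10)), f, row.names = FALSE)
  s <- read_teer_csv(f)
  expect_equal(s$teer, c(28.8, 16))
  write.csv(data.frame(time_h = 0, ohms = 1), f, row.names = FALSE)
  expect_error(read_teer_csv(f), "missing columns")
})

test_that("per-image aggregation averages cells within each image", {
  rec <- data.frame(image_id = c("a", "a", "b"), group_label = "g",
                    ratio_percent = c(10, 30, 50))
  s <- summarize_by_image(rec)
  expect_identical(s$n_cells, c(2L, 1L))
  expect_equal(s$mean_ratio_percent, c(20, 50))
})

test_that("box-plot figures are written to disk", {
  cmp <- kruskal_wallis(list(a = rnorm(10), b = rnorm(10) + 1))
  f <- file.path(withr::local_tempdir(), "box.png")
  plot_group_boxplot(cmp, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
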