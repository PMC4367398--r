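test_that("grid validity follows the foreground-fraction threshold", {
  # one 8x8 cell with exactly 13 fg pixels: 13 >= 0.2 * 64 = 12.8 -> valid
  m <- matrix(FALSE, 8, 16)
  m[1:13] <- TRUE
  g <- build_grid(m, cell_px = 8, min_valid_frac = 0.2)
  expect_true(g$valid[1, 1])
  m[13] <- FALSE                               # 12 < 12.8 -> invalid
  m[1, 9] <- TRUE                              # keep the mask non-degenerate
  m[2:8, 9:16] <- TRUE
  g <- build_grid(m, cell_px = 8, min_valid_frac = 0.2)
  expect_false(g$valid[1, 1])
})

test_that("the plant axis of a symmetric mask is the centroid column", {
  m <- matrix(FALSE, 40, 41)
  m[30:40, 11:31] <- TRUE                      # symmetric about col 21
  m[5:29, 21] <- TRUE
  g <- build_grid(m)
  expect_equal(g$axis_col, 21)
  expect_error(build_grid(matrix(FALSE, 10, 10)),
               class = "tomstem_empty_plant")
})

test_that("breadth histogram records farthest-valid distances with zero substitution", {
  g <- grid_with_breadths(c(3, 3, 1, 1, 2, 2))
  expect_identical(breadth_histogram(g)$n, c(3L, 3L, 1L, 1L, 2L, 2L))

  g <- grid_with_breadths(c(3, 0, 2))          # dropout row -> nearest above
  expect_identical(breadth_histogram(g)$n, c(3L, 3L, 2L))

  g <- grid_with_breadths(c(0, 2, 2))          # no row above -> nearest below
  expect_identical(breadth_histogram(g)$n, c(2L, 2L, 2L))
})

test_that("median smoothing runs with replicate edges and recomputes N", {
  expect_identical(median_smooth(new_hist(c(4, 4, 4, 4)), 3)$n, rep(4L, 4))
  sm <- median_smooth(new_hist(c(1, 9, 1, 9, 1)), 3)
  expect_identical(sm$n, c(1L, 1L, 9L, 1L, 1L))
  expect_identical(sm$N, 13L)
  expect_identical(median_smooth(new_hist(c(0, 0, 7, 0, 0)), 3)$n, rep(0L, 5))
  expect_error(median_smooth(new_hist(c(1, 2)), 4),
               class = "tomstem_value_error")
  expect_error(median_smooth(new_hist(c(1, 2, 3)), 7),
               class = "tomstem_degenerate_window")
})

test_that("Otsu threshold matches hand-evaluated between-class variances", {
  o <- otsu_histogram(new_hist(c(6, 1, 3)))
  expect_identical(o$k_star, 1L)
  expect_equal(o$sigma_b2, 0.735)
  expect_equal(o$omega0, 0.6)
  expect_equal(o$mu0, 1)
  expect_equal(o$mu1, 2.75)
  # the invariants typed into the result
  expect_equal(o$omega0 + o$omega1, 1)
  expect_equal(o$sigma_b2, o$omega0 * o$omega1 * (o$mu1 - o$mu0)^2)

  tie <- otsu_histogram(new_hist(c(5, 5, 0, 0, 5, 5)))  # symmetric plateau
  expect_identical(tie$k_star, 2L)                      # smallest k on ties
  expect_equal(tie$sigma_b2, 4)

  expect_error(otsu_histogram(new_hist(c(0, 10, 0))),
               class = "tomstem_degenerate_histogram")
})

test_that("Otsu agrees with the exhaustive oracle and the variance decomposition", {
  set.seed(20)
  for (rep in 1:300) {
    n <- random_histogram(sample(3:64, 1))
    o <- otsu_histogram(new_hist(n))
    b <- brute_otsu(n)
    expect_true(o$k_star %in% b$tie_set)        # smallest-k among argmax ties
    expect_equal(o$sigma_b2, b$sigma_b2)
    k <- sample(seq_len(length(n) - 1), 1)
    vp <- variance_parts(n, k)
    expect_equal(vp$between + vp$within, vp$total)
  }
})

test_that("iterated Otsu keeps one pass on balanced histograms and recurses on imbalance", {
  balanced <- new_hist(c(6, 7, 6, 1, 1, 6, 7, 6))       # equal-mass peaks
  iv <- valley_interval(balanced, balance_ratio = 1.5)
  expect_identical(iv$passes, 1L)
  expect_identical(iv$k_star, brute_otsu(balanced$n)$k_star)

  heavy <- new_hist(c(9, 10, 9, 8, 2, 1, 1, 2, 4, 5, 4))  # canopy ~2.4x pot
  iv <- valley_interval(heavy, balance_ratio = 1.5)
  # frozen two-pass oracle run: first split at 6, re-split of the weak
  # lower side lands the final threshold at 9 with valley [6, 10]
  expect_identical(iv$passes, 2L)
  expect_identical(iv$k1, 6L)
  expect_identical(iv$k_star, 9L)
  expect_gt(iv$k_star, iv$k1)
  expect_identical(c(iv$lo, iv$hi), c(6L, 10L))

  # infinite balance ratio degenerates to plain Otsu
  iv1 <- valley_interval(heavy, balance_ratio = Inf)
  expect_identical(iv1$passes, 1L)
  expect_identical(iv1$k_star, brute_otsu(heavy$n)$k_star)
})

test_that("valley bounds always bracket the threshold", {
  set.seed(8)
  for (rep in 1:50) {
    n <- random_histogram(sample(4:40, 1))
    iv <- valley_interval(new_hist(n))
    expect_lte(iv$lo, iv$k_star)
    expect_gte(iv$hi, iv$k_star)
    expect_gte(iv$lo, 1L)
    expect_lte(iv$hi, length(n))
  }
})

test_that("segment filtering enforces the valley and the pot cross-section rule", {
  # grid: 10 rows x 20 cols, cell 8 px; wide rows near the bottom
  valid <- matrix(FALSE, 10, 20)
  valid[1:3, 5:15] <- TRUE                      # canopy
  valid[4:7, 10] <- TRUE                        # waist
  valid[8:10, 5:12] <- TRUE                     # pot, width 8 cells
  grid <- toy_grid(valid, axis_gc = 10L)
  interval <- structure(list(k_star = 6L, k1 = 4L, sigma0 = 2, sigma1 = 1,
                             lo = 4L, hi = 7L, passes = 2L, L = 10L),
                        class = "stem_interval")

  rowpx <- function(i) (i - 1) * 8 + 4          # centre of grid row i
  canopy_seg <- make_seg(c(80, rowpx(1)), c(80, rowpx(3)), 1L)
  straddle <- make_seg(c(80, rowpx(3)), c(80, rowpx(5)), 2L)
  waist_seg <- make_seg(c(80, rowpx(5)), c(80, rowpx(7)), 3L)
  pot_seg <- make_seg(c(60, rowpx(7)), c(60, rowpx(9)), 4L)  # straddles hi

  segs <- list(canopy_seg, straddle, waist_seg, pot_seg)
  kept <- filter_segments(segs, interval, grid, pot_breadth_max = 4)
  ids <- vapply(kept, `[[`, 0L, "id")
  # canopy removed by the valley rule; the pot straddler's rows average
  # (1 + 8 + 8) / 3 cells wide > 4, so the cross-section rule removes it
  expect_identical(ids, c(2L, 3L))

  # the same pot-region segment over narrow rows is kept
  valid2 <- valid
  valid2[8:10, ] <- FALSE
  valid2[8:10, 9:11] <- TRUE                    # width 3 <= 4
  kept2 <- filter_segments(list(pot_seg), interval, toy_grid(valid2, 10L),
                           pot_breadth_max = 4)
  expect_identical(length(kept2), 1L)

  # filtering returns a subset of its input
  expect_true(all(ids %in% 1:4))
})
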