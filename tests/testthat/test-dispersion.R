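test_that("dispersion of a constant field is identically zero", {
  m <- matrix(55, 30L, 30L)
  dm <- dispersion_map(m, 10L)
  expect_true(all(dm$values[dm$valid] == 0))
  gm <- gradient_map(m, 10L)
  expect_true(all(gm$values[gm$valid] == 0))
})

test_that("windowed std matches the direct population formula", {
  # a 10 x 10 map holding fifty 20 ms and fifty 30 ms pixels: std = 5 exactly
  m <- matrix(c(rep(20, 50), rep(30, 50)), 10L, 10L)
  dm <- dispersion_map(m, 10L)
  centre <- dm$values[5L, 5L]  # window covers the full map
  expect_equal(centre, 5.0, tolerance = 1e-12)
  # general agreement with a per-pixel definition-level loop
  set.seed(20)
  v <- matrix(rnorm(900, 50, 10), 30L, 30L)
  dmv <- dispersion_map(v, 10L)
  for (ij in list(c(8L, 8L), c(15L, 22L), c(25L, 5L))) {
    expect_equal(dmv$values[ij[1L], ij[2L]],
                 window_std_at(v, ij[1L], ij[2L], 10L), tolerance = 1e-12)
  }
})

test_that("gradient map implements max minus min and dominates the std map", {
  m <- matrix(40, 12L, 12L)
  m[6L, 6L] <- 55
  gm <- gradient_map(m, 10L)
  expect_equal(gm$values[6L, 6L], 15)
  set.seed(21)
  v <- matrix(rnorm(400, 50, 8), 20L, 20L)
  gmv <- gradient_map(v, 10L)
  dmv <- dispersion_map(v, 10L)
  expect_true(all(gmv$values[gmv$valid] >= dmv$values[dmv$valid]))
})

test_that("dispersion is shift-invariant and scales linearly", {
  set.seed(22)
  v <- matrix(rnorm(400, 50, 5), 20L, 20L)
  d0 <- dispersion_map(v, 10L)
  d_shift <- dispersion_map(v + 17, 10L)
  d_scale <- dispersion_map(v * 3, 10L)
  expect_equal(d_shift$values, d0$values, tolerance = 1e-9)
  expect_equal(d_scale$values, 3 * d0$values, tolerance = 1e-9)
  expect_error(dispersion_map(v, 25L), "larger")
})

test_that("edge pixels with under half a window of valid neighbours drop out", {
  v <- matrix(rnorm(400, 50, 5), 20L, 20L)
  dm <- dispersion_map(v, 10L)
  expect_false(dm$valid[1L, 1L])   # corner: 6x7 in-bounds < 50 pixels
  expect_true(dm$valid[10L, 10L])
  ref <- brute_force_dispersion(v, window_px = 10L)
  expect_identical(dm$valid, ref$valid)
})

test_that("binarization is strictly greater-than at the threshold", {
  m <- matrix(50, 12L, 12L)
  m[4:9, 4:9] <- 80
  dm <- dispersion_map(m, 4L)
  dm$values[6L, 6L] <- 10.0  # force an exactly-at-threshold pixel
  bm <- binarize(dm, 10)
  expect_false(bm$above[6L, 6L])
  expect_equal(bm$threshold_ms, 10)
  # threshold 0 marks every strictly positive valid pixel
  set.seed(23)
  v <- matrix(rnorm(400, 50, 5), 20L, 20L)
  b0 <- binarize(dispersion_map(v, 10L), 0)
  dmv <- dispersion_map(v, 10L)
  expect_identical(b0$above, dmv$values > 0 & dmv$valid)
})

test_that("area fraction is a percentage of the computable mask", {
  above <- matrix(FALSE, 10L, 10L)
  above[1:37] <- TRUE
  bm <- structure(list(above = above, threshold_ms = 10,
                       source_statistic = "std",
                       valid = matrix(TRUE, 10L, 10L)),
                  class = "binary_dispersion_map")
  expect_equal(area_fraction(bm), 37)
  bm$above[] <- TRUE
  expect_equal(area_fraction(bm), 100)
  expect_error(area_fraction(bm, mask = matrix(FALSE, 10L, 10L)), "mask")
})

test_that("area fraction never increases along a threshold sweep", {
  set.seed(24)
  v <- matrix(rnorm(900, 50, 6), 30L, 30L)
  dm <- dispersion_map(v, 10L)
  fr <- vapply(seq(0, 20, by = 1), function(th) {
    area_fraction(binarize(dm, th))
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("island extraction measures area and respects 8-connectivity", {
  bm <- matrix(FALSE, 30L, 30L)
  bm[11:20, 11:20] <- TRUE
  isl <- extract_islands(bm, pixel_pitch_mm = 0.095)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$n_px, 100L)
  expect_equal(isl$area_mm2, 100 * 0.095^2)  # 0.9025 mm^2
  expect_equal(isl$centroid_row, 15.5)
  # two squares touching only at a corner merge under 8-connectivity
  bm2 <- matrix(FALSE, 20L, 20L)
  bm2[3:6, 3:6] <- TRUE
  bm2[7:10, 7:10] <- TRUE
  expect_equal(nrow(extract_islands(bm2)), 1L)
  # union of islands equals the binary map
  isl2 <- extract_islands(bm2)
  expect_equal(sum(isl2$n_px), sum(bm2))
  expect_equal(nrow(extract_islands(matrix(FALSE, 5L, 5L))), 0L)
})

test_that("compact islands read ovoid, elongated or ragged ones serpiginous", {
  # disc of radius 6
  disc <- matrix(FALSE, 30L, 30L)
  for (i in 1:30) for (j in 1:30) {
    if ((i - 15)^2 + (j - 15)^2 <= 36) disc[i, j] <- TRUE
  }
  expect_equal(extract_islands(disc)$shape_label, "ovoid")
  # thin meandering line
  snake <- matrix(FALSE, 30L, 30L)
  path_r <- c(5:25, rep(25, 10))
  path_c <- c(rep(5, 21), 6:15)
  snake[cbind(path_r, path_c)] <- TRUE
  expect_equal(extract_islands(snake)$shape_label, "serpiginous")
})

test_that("group statistics match the one-sample t formula", {
  gs <- group_stats(c(8, 12), null_value = 0)
  expect_equal(gs$mean, 10)
  expect_equal(gs$sem, 2)
  expect_equal(gs$t, 5)
  expect_equal(gs$df, 1L)
  # cross-check against the stats implementation
  tt <- stats::t.test(c(8, 12), mu = 0)
  expect_equal(gs$t, unname(tt$statistic))
  expect_equal(gs$p, tt$p.value)
  # degenerate cases
  expect_warning(gs0 <- group_stats(c(5, 5, 5), null_value = 5),
                 "degenerate")
  expect_equal(gs0$t, 0)
  expect_equal(gs0$p, 1)
  expect_error(group_stats(4), "n >= 2")
})
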