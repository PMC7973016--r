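test_that("preprocess with filters off is pure per-pixel normalization", {
  sim <- make_paced_sim(grid = c(12L, 12L), pattern = "constant",
                        n_frames = 400L, seed = 2L)
  pp <- preprocess(sim$movie, signal_config())
  x <- sim$movie$data
  dim(x) <- c(400L, 144L)
  lo <- apply(x, 2L, min)
  rng <- apply(x, 2L, max) - lo
  expected <- sweep(sweep(x, 2L, lo), 2L, rng, `/`)
  got <- pp$data
  dim(got) <- c(400L, 144L)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_true(all(pp$valid))
})

test_that("linear drift is removed by detrending", {
  sim <- make_paced_sim(grid = c(12L, 12L), pattern = "constant",
                        n_frames = 600L, seed = 4L)
  clean <- preprocess(sim$movie, signal_config())
  drifted <- sim$movie
  drift <- seq(0, 0.8, length.out = 600L)
  drifted$data <- sweep(drifted$data, 1L, drift, `+`)
  pp <- preprocess(drifted, signal_config(detrend = TRUE))
  cors <- vapply(seq_len(144L), function(p) {
    a <- clean$data
    b <- pp$data
    dim(a) <- dim(b) <- c(600L, 144L)
    stats::cor(a[, p], b[, p])
  }, numeric(1))
  expect_true(all(cors >= 0.99))
})

test_that("flat pixels are invalid, not fatal", {
  sim <- make_paced_sim(grid = c(10L, 10L), pattern = "constant",
                        n_frames = 400L, seed = 2L)
  sim$movie$data[, 3L, 4L] <- 7
  pp <- preprocess(sim$movie)
  expect_false(pp$valid[3L, 4L])
  expect_true(pp$valid[1L, 1L])
  amap <- compute_apd_map(pp)
  expect_false(amap$valid[3L, 4L])
})

test_that("beat detection finds paced upstrokes with a refractory lockout", {
  # 10 clean template beats at 100 ms cycle length
  s <- ((0:999) - 5) %% 100
  s[0:999 < 5] <- -1
  tr <- ap_template(s, 50)
  idx <- detect_beats(tr / max(tr), 1000)
  expect_length(idx, 10L)
  expect_true(all(abs(diff(idx) - 100) <= 1))
  # monotone ramp: at most one activation
  expect_lte(length(detect_beats(seq(0, 1, length.out = 200L), 1000)), 1L)
  # double crossing 5 ms apart: lockout suppresses the second
  tr2 <- rep(0, 100)
  tr2[11:13] <- 1
  tr2[16:60] <- 1
  expect_length(detect_beats(tr2, 1000), 1L)
  expect_length(detect_beats(rep(0.2, 50), 1000), 0L)
})

test_that("APD of an ideal square pulse is its width", {
  tr <- c(rep(0, 20), rep(1, 50), rep(0, 80))
  a <- detect_beats(tr, 1000)
  apd <- compute_apd(tr, a[1L], 90, 1000)
  expect_lt(abs(apd - 50), 0.5)
})

test_that("APD is monotone in repolarization level and affine-invariant", {
  s <- ((0:299) - 5) %% 150
  s[0:299 < 5] <- -1
  tr <- ap_template(s, 80)
  a <- detect_beats(tr / max(tr), 1000)
  apd50 <- compute_apd(tr, a[1L], 50, 1000, next_index = a[2L])
  apd70 <- compute_apd(tr, a[1L], 70, 1000, next_index = a[2L])
  apd90 <- compute_apd(tr, a[1L], 90, 1000, next_index = a[2L])
  expect_true(apd50 <= apd70 && apd70 <= apd90)
  # invariance to affine rescaling of the raw trace
  apd_scaled <- compute_apd(3 * tr + 7, a[1L], 90, 1000,
                            next_index = a[2L])
  expect_equal(apd_scaled, apd90, tolerance = 1e-10)
})

test_that("a truncated final beat is flagged invalid, not mismeasured", {
  s <- ((0:129) - 5) %% 100
  s[0:129 < 5] <- -1
  tr <- ap_template(s, 60)  # second beat cut at 25 ms into its plateau
  a <- detect_beats(tr / max(tr), 1000)
  expect_length(a, 2L)
  expect_true(is.na(compute_apd(tr, a[2L], 90, 1000)))
})

test_that("APD maps recover the ground-truth field", {
  sim <- make_paced_sim(grid = c(40L, 40L), seed = 3L)
  amap <- compute_apd_map(preprocess(sim$movie))
  expect_equal(amap$level_pct, 90)
  err <- abs(amap$values - sim$field$values)[amap$valid]
  expect_lt(max(err), 1)
  # constant field: tight spatial statistics
  simc <- make_paced_sim(grid = c(20L, 20L), pattern = "constant",
                         n_frames = 600L, seed = 2L)
  amc <- compute_apd_map(preprocess(simc$movie))
  v <- amc$values[amc$valid]
  expect_lt(abs(mean(v) - 50), 0.5)
  expect_lt(stats::sd(v), 0.5)
})

test_that("pixels outside the tissue mask never get APD values", {
  f <- generate_apd_field("constant", c(15L, 15L), 50)
  mask <- matrix(TRUE, 15L, 15L)
  mask[1:4, 1:4] <- FALSE
  meta <- acquisition_meta(n_frames = 400L, height = 15L, width = 15L)
  sim <- synthesize_movie(f, meta, mask = mask)
  amap <- compute_apd_map(preprocess(sim$movie))
  expect_true(all(!amap$valid[1:4, 1:4]))
})

test_that("conduction velocity is recovered from a plane wave", {
  simc <- make_paced_sim(grid = c(30L, 30L), pattern = "constant",
                         n_frames = 400L, seed = 2L)
  am <- compute_activation_map(preprocess(simc$movie))
  cv <- estimate_cv_map(am, 0.095, 5L)
  sp <- cv$speed_mm_per_ms[cv$valid]
  expect_gt(length(sp), 100L)
  expect_lt(abs(mean(sp) - 0.3), 0.015)
  # simultaneous activation: zero gradient, invalid everywhere
  flat <- structure(list(times_ms = matrix(5, 20L, 20L),
                         valid = matrix(TRUE, 20L, 20L)),
                    class = "activation_map")
  cv0 <- estimate_cv_map(flat, 0.095, 5L)
  expect_false(any(cv0$valid))
})

test_that("conduction speed is direction-invariant", {
  f <- generate_apd_field("constant", c(30L, 30L), 50)
  meta <- acquisition_meta(n_frames = 400L, height = 30L, width = 30L)
  along_cols <- synthesize_movie(f, meta,
                                 wave = list(direction_deg = 0,
                                             speed_mm_per_ms = 0.3))
  along_rows <- synthesize_movie(f, meta,
                                 wave = list(direction_deg = 90,
                                             speed_mm_per_ms = 0.3))
  cv1 <- estimate_cv_map(compute_activation_map(preprocess(along_cols$movie)),
                         0.095, 5L)
  cv2 <- estimate_cv_map(compute_activation_map(preprocess(along_rows$movie)),
                         0.095, 5L)
  m1 <- mean(cv1$speed_mm_per_ms[cv1$valid])
  m2 <- mean(cv2$speed_mm_per_ms[cv2$valid])
  expect_equal(m1, m2, tolerance = 0.01)
})
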