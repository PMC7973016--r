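test_that("constant fields are flat and infeasible island demands error", {
  f <- generate_apd_field("constant", c(30L, 30L), baseline_apd_ms = 50)
  expect_true(all(f$values == 50))
  expect_equal(stats::sd(f$values), 0)
  expect_error(
    generate_apd_field("random", c(30L, 30L),
                       island_params = list(count = 200, mean_radius_px = 8,
                                            elevation_ms = 25)),
    "infeasible")
})

test_that("generation is deterministic given the seed", {
  f1 <- generate_apd_field("clustered", c(50L, 50L),
                           island_params = list(count = 10,
                                                mean_radius_px = 4,
                                                elevation_ms = 25),
                           seed = 42L)
  f2 <- generate_apd_field("clustered", c(50L, 50L),
                           island_params = list(count = 10,
                                                mean_radius_px = 4,
                                                elevation_ms = 25),
                           seed = 42L)
  expect_identical(f1$values, f2$values)
  expect_identical(f1$centers, f2$centers)
  meta <- acquisition_meta(n_frames = 300L, height = 50L, width = 50L)
  m1 <- synthesize_movie(f1, meta, noise = list(gaussian_sd = 0.05),
                         seed = 7L)
  m2 <- synthesize_movie(f2, meta, noise = list(gaussian_sd = 0.05),
                         seed = 7L)
  expect_identical(m1$movie$data, m2$movie$data)
})

test_that("clustered centroids aggregate: nearest-neighbour oracle gives R < 1", {
  f <- generate_apd_field("clustered", c(100L, 100L),
                          island_params = list(count = 30,
                                               mean_radius_px = 6,
                                               elevation_ms = 25),
                          seed = 5L)
  pts <- as.matrix(f$centers)
  # closed-form Clark-Evans estimator computed directly in the test
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  r_obs <- mean(apply(dm, 1L, min))
  r_exp <- 0.5 / sqrt(nrow(pts) / 1e4)
  expect_lt(r_obs / r_exp, 1)
  # and the package estimator agrees with the direct computation
  ce <- clark_evans(pts, area = 1e4, edge_correction = "none")
  expect_equal(ce$r, r_obs / r_exp, tolerance = 1e-12)
})

test_that("plane-wave activation delays follow distance over speed", {
  f <- generate_apd_field("constant", c(100L, 100L), 50)
  meta <- acquisition_meta(n_frames = 300L, height = 100L, width = 100L)
  sim <- synthesize_movie(f, meta,
                          wave = list(direction_deg = 0,
                                      speed_mm_per_ms = 0.3))
  delays <- sim$truth$activation_field
  expect_equal(max(delays) - min(delays), 99 * 0.095 / 0.3,
               tolerance = 1e-10)
  # columns share delay when the wave travels along columns
  expect_equal(delays[1, ], delays[100, ], tolerance = 1e-12)
})

test_that("10 Hz pacing for 1 s yields exactly 10 upstrokes per pixel", {
  f <- generate_apd_field("constant", c(10L, 10L), 50)
  meta <- acquisition_meta(n_frames = 1000L, height = 10L, width = 10L)
  sim <- synthesize_movie(f, meta,
                          pacing = list(cycle_length_ms = 100), seed = 1L)
  pp <- preprocess(sim$movie)
  x <- pp$data
  dim(x) <- c(1000L, 100L)
  n_up <- vapply(seq_len(100L), function(p) {
    length(detect_beats(x[, p], 1000))
  }, integer(1))
  expect_true(all(n_up == 10L))
})

test_that("fusion of consecutive beats is rejected", {
  f <- generate_apd_field("constant", c(10L, 10L), 90)
  meta <- acquisition_meta(n_frames = 500L, height = 10L, width = 10L)
  expect_error(
    synthesize_movie(f, meta, pacing = list(cycle_length_ms = 100)),
    "cycle length")
})

test_that("spiral movies pin the singularity and its winding at the core", {
  meta <- acquisition_meta(n_frames = 50L, height = 40L, width = 40L)
  sp <- generate_spiral_movie(meta, 10,
                              cores = list(row = 20, col = 20,
                                           chirality = 1L))
  expect_true(all(sp$truth$singularities$row == 20))
  expect_equal(nrow(sp$truth$singularities), 50L)
  # brute-force winding of the analytic phase around the core
  ph <- phase_movie(sp$movie)
  w <- winding_number(matrix(ph$phase[10, , ], 40, 40), 20, 20)
  expect_equal(w, 1L)
  sp_neg <- generate_spiral_movie(meta, 10,
                                  cores = list(row = 20, col = 20,
                                               chirality = -1L))
  ph_neg <- phase_movie(sp_neg$movie)
  expect_equal(winding_number(matrix(ph_neg$phase[10, , ], 40, 40), 20, 20),
               -1L)
  expect_error(generate_spiral_movie(meta, 200), "Nyquist")
  expect_error(
    generate_spiral_movie(meta, 10, cores = list(row = 90, col = 20,
                                                 chirality = 1L)),
    "outside")
})

test_that("figure-of-eight superposition carries two opposite charges", {
  meta <- acquisition_meta(n_frames = 40L, height = 50L, width = 50L)
  sp <- generate_spiral_movie(
    meta, 8,
    cores = list(list(row = 25, col = 14, chirality = 1L),
                 list(row = 25, col = 36, chirality = -1L)))
  expect_equal(sum(sp$truth$singularities$charge), 0L)
  ph <- phase_movie(sp$movie)
  p1 <- matrix(ph$phase[5, , ], 50, 50)
  expect_equal(winding_number(p1, 25, 14), 1L)
  expect_equal(winding_number(p1, 25, 36), -1L)
})

test_that("oracle area fraction is recovered by the movie pipeline at zero noise", {
  sim <- make_paced_sim(grid = c(40L, 40L), seed = 6L)
  amap <- compute_apd_map(preprocess(sim$movie))
  frac <- area_fraction(binarize(dispersion_map(amap, 10L), 10))
  expect_lt(abs(frac - sim$truth$true_area_fraction_pct), 2)
})
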