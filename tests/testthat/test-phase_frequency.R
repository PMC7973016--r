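make_tone_movie <- function(freqs_amps, n_frames = 2000L, grid = c(10L, 10L),
                            fs = 1000) {
  tt <- (seq_len(n_frames) - 1L) / fs
  tr <- Reduce(`+`, lapply(freqs_amps, function(fa) {
    fa[2L] * cos(2 * pi * fa[1L] * tt)
  }))
  arr <- array(rep(tr, prod(grid)), c(n_frames, grid[1L], grid[2L]))
  voltage_movie(arr, acquisition_meta(frame_rate_hz = fs,
                                      n_frames = n_frames,
                                      height = grid[1L], width = grid[2L]))
}

test_that("dominant frequency locks onto the strongest in-band tone", {
  mv <- make_tone_movie(list(c(10, 1)), n_frames = 4000L)
  dfm <- dominant_frequency_map(mv)
  expect_true(all(abs(dfm$freq_hz[dfm$valid] - 10) <= 0.25))
  expect_true(all(dfm$power_fraction[dfm$valid] > 0.5))
  # two-tone: the 8 Hz component dominates the 16 Hz harmonic
  mv2 <- make_tone_movie(list(c(8, 1), c(16, 0.3)))
  dfm2 <- dominant_frequency_map(mv2)
  expect_true(all(abs(dfm2$freq_hz[dfm2$valid] - 8) <= 0.5))
  # flat pixel: invalid
  mv3 <- make_tone_movie(list(c(10, 1)))
  mv3$data[, 2L, 2L] <- 4
  dfm3 <- dominant_frequency_map(mv3)
  expect_false(dfm3$valid[2L, 2L])
  expect_error(dominant_frequency_map(mv3, band_hz = c(1, 600)), "Nyquist")
})

test_that("Hilbert phase advances at the driving frequency, amplitude-free", {
  mv <- make_tone_movie(list(c(5, 1)), n_frames = 1000L, grid = c(4L, 4L))
  ph <- phase_movie(mv)
  tr_phase <- ph$phase[, 2L, 2L]
  unw <- tr_phase
  for (k in 2:length(unw)) {
    while (unw[k] - unw[k - 1L] > pi) unw[k:length(unw)] <- unw[k:length(unw)] - 2 * pi
    while (unw[k] - unw[k - 1L] < -pi) unw[k:length(unw)] <- unw[k:length(unw)] + 2 * pi
  }
  # interior slope (edges suffer Gibbs effects)
  sl <- stats::coef(stats::lm(unw[100:900] ~ seq(100, 900)))[[2L]]
  expect_equal(sl * 1000 / (2 * pi), 5, tolerance = 0.05)
  # amplitude invariance
  mv_big <- mv
  mv_big$data <- mv$data * 40 + 3
  ph_big <- phase_movie(mv_big)
  expect_equal(ph_big$phase[200:800, 2L, 2L], ph$phase[200:800, 2L, 2L],
               tolerance = 1e-6)
})

test_that("spiral phase fields are recovered to within 0.1 rad in the interior", {
  meta <- acquisition_meta(n_frames = 200L, height = 40L, width = 40L)
  sp <- generate_spiral_movie(meta, 10, cores = list(row = 20, col = 20,
                                                     chirality = 1L))
  ph <- phase_movie(sp$movie)
  # analytic phase at frame k: 2 pi f t + theta + 2 pi r / lambda
  k <- 100L
  rows <- matrix(seq_len(40L), 40L, 40L)
  cols <- matrix(seq_len(40L), 40L, 40L, byrow = TRUE)
  theta <- atan2(rows - 20, cols - 20)
  rr <- sqrt((rows - 20)^2 + (cols - 20)^2)
  analytic <- (2 * pi * 10 * (k - 1L) / 1000 + theta + 2 * pi * rr / 40)
  got <- matrix(ph$phase[k, , ], 40L, 40L)
  d <- got - analytic
  d <- -((-d + pi) %% (2 * pi) - pi)
  interior <- rr > 6 & rr < 14
  expect_lt(max(abs(d[interior])), 0.1)
})

test_that("singularity detection finds cores, charges and densities", {
  meta <- acquisition_meta(n_frames = 150L, height = 50L, width = 50L)
  sp <- generate_spiral_movie(meta, 10, cores = list(row = 25, col = 25,
                                                     chirality = 1L))
  ss <- detect_singularities(phase_movie(sp$movie))
  per_frame <- table(ss$events$frame)
  expect_true(all(per_frame == 1L))
  expect_equal(length(per_frame), 150L)
  expect_true(all(ss$events$charge == 1L))
  expect_true(all(abs(ss$events$row - 25) <= 1))
  expect_true(all(abs(ss$events$col - 25) <= 1))
  # SPD map peaks at the core
  ties <- which(ss$spd_map == max(ss$spd_map), arr.ind = TRUE)
  pk <- colMeans(ties)
  expect_true(all(abs(pk - c(25, 25)) <= 5))
  # amplitude rescaling leaves the detection unchanged
  sp_big <- sp
  sp_big$movie$data <- sp$movie$data * 25
  ss_big <- detect_singularities(phase_movie(sp_big$movie))
  expect_equal(nrow(ss_big$events), nrow(ss$events))
})

test_that("plane waves carry no singularities; figure-of-eight carries two", {
  simc <- make_paced_sim(grid = c(25L, 25L), pattern = "constant",
                         n_frames = 400L, seed = 2L)
  ssp <- detect_singularities(phase_movie(preprocess(simc$movie)))
  expect_equal(nrow(ssp$events), 0L)
  meta <- acquisition_meta(n_frames = 100L, height = 50L, width = 50L)
  f8 <- generate_spiral_movie(
    meta, 8,
    cores = list(list(row = 25, col = 14, chirality = 1L),
                 list(row = 25, col = 36, chirality = -1L)))
  ss8 <- detect_singularities(phase_movie(f8$movie))
  per_frame <- tapply(ss8$events$charge, ss8$events$frame, length)
  net <- tapply(ss8$events$charge, ss8$events$frame, sum)
  expect_true(all(per_frame == 2L))
  expect_true(all(net == 0L))
})

test_that("the highest-SPD region comparison contrasts local APD statistics", {
  # uniform APD map: all differences vanish
  amap <- structure(
    list(values = matrix(50, 40L, 40L), level_pct = 90,
         valid = matrix(TRUE, 40L, 40L), meta = acquisition_meta(),
         n_beats_used = matrix(1L, 40L, 40L)),
    class = "apd_map")
  spd <- matrix(0, 40L, 40L)
  spd[20L, 20L] <- 3
  cmp <- compare_spd_region(amap, spd, window_px = 10L)
  expect_equal(cmp$mean_apd_ms[cmp$region == "difference"], 0)
  expect_equal(cmp$std_apd_ms[cmp$region == "difference"], 0)
  # spiral core placed inside a high-dispersion island
  f <- generate_apd_field("clustered", c(60L, 60L),
                          island_params = list(count = 4, mean_radius_px = 6,
                                               elevation_ms = 25),
                          seed = 2L)
  amap2 <- amap
  amap2$values <- f$values
  amap2$valid <- matrix(TRUE, 60L, 60L)
  core <- list(row = round(f$centers$row[1L]),
               col = round(f$centers$col[1L]), chirality = 1L)
  sp <- generate_spiral_movie(
    acquisition_meta(n_frames = 150L, height = 60L, width = 60L),
    10, cores = core)
  ss <- detect_singularities(phase_movie(sp$movie))
  cmp2 <- compare_spd_region(amap2, ss, window_px = 10L)
  expect_gt(cmp2$std_apd_ms[cmp2$region == "highest_spd"],
            cmp2$std_apd_ms[cmp2$region == "neighbor"])
})
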