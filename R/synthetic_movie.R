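# Synthetic voltage-dye movies with exact ground truth.

#' Analytic action potential template
#'
#' Piecewise-smooth normalized waveform parameterized directly by the APD at
#' a chosen repolarization level: tanh upstroke (2 ms foot-to-plateau,
#' midpoint at 1 ms — sharp but still resolved at 1,000 frames/s), brief
#' plateau, exponential repolarization that crosses `(1 - level/100)` of the
#' plateau amplitude exactly `apd_ms` after the upstroke midpoint, then a
#' fast decay back to baseline so diastolic fluorescence returns near zero
#' well before the next beat.
#'
#' @param s_ms time since beat onset (ms); values < 0 yield 0
#' @param apd_ms action potential duration at `level_pct` (> 5 ms)
#' @param level_pct repolarization level (percent, default 90)
#' @return waveform values in `[0, 1]`
#' @export
ap_template <- function(s_ms, apd_ms, level_pct = 90) {
  stopifnot(all(apd_ms > 5), level_pct > 0, level_pct < 100)
  amp <- 0.5 * (1 + tanh(1 / 0.35))            # plateau amplitude
  lev_frac <- 1 - level_pct / 100
  tau <- (apd_ms - 3) / log(1 / lev_frac)       # crossing at s = apd + 1
  t_cross <- apd_ms + 1
  v <- numeric(length(s_ms))
  up <- s_ms >= 0 & s_ms < 2
  v[up] <- 0.5 * (1 + tanh((s_ms[up] - 1) / 0.35))
  pl <- s_ms >= 2 & s_ms < 4
  v[pl] <- amp
  rp <- s_ms >= 4 & s_ms < t_cross
  v[rp] <- amp * exp(-(s_ms[rp] - 4) / tau)
  tl <- s_ms >= t_cross
  v[tl] <- amp * lev_frac * exp(-(s_ms[tl] - t_cross) / 4)
  v
}

# vectorized template where apd varies with position (s and apd same shape)
ap_template_field <- function(s, apd, level_pct) {
  amp <- 0.5 * (1 + tanh(1 / 0.35))
  lev_frac <- 1 - level_pct / 100
  tau <- (apd - 3) / log(1 / lev_frac)
  t_cross <- apd + 1
  v <- numeric(length(s))
  up <- s >= 0 & s < 2
  v[up] <- 0.5 * (1 + tanh((s[up] - 1) / 0.35))
  pl <- s >= 2 & s < 4
  v[pl] <- amp
  rp <- s >= 4 & s < t_cross
  v[rp] <- amp * exp(-(s[rp] - 4) / tau[rp])
  tl <- s >= t_cross
  v[tl] <- amp * lev_frac * exp(-(s[tl] - t_cross[tl]) / 4)
  v
}

#' Synthesize a paced voltage movie over an APD field
#'
#' Every pixel fires a repeated analytic action potential whose duration at
#' `level_pct` equals the field value at that pixel, delayed by the arrival
#' time of a plane wave. Additive noise (white Gaussian, sinusoidal baseline
#' drift with a random per-pixel phase, linear photobleaching trend) is
#' applied after waveform synthesis. Returns the movie together with a
#' ground-truth object holding the field, the activation-delay map, and the
#' oracle supra-threshold area fraction of the true field.
#'
#' @param field an `apd_field` from [generate_apd_field()] (or numeric matrix)
#' @param meta an [acquisition_meta()]; `n_frames` sets the movie length and
#'   the grid must match the field
#' @param pacing list: `cycle_length_ms` (default 100, i.e. 10 Hz) and
#'   `n_beats` (default: as many as fit)
#' @param wave list: `direction_deg` (propagation direction, 0 = along
#'   columns) and `speed_mm_per_ms` (default 0.3)
#' @param noise list: `gaussian_sd` (fraction of AP amplitude),
#'   `drift_amplitude`, `drift_freq_hz`, `bleach_frac` (linear trend over the
#'   recording)
#' @param level_pct repolarization level the field values refer to
#' @param mask optional tissue mask
#' @param start_ms pacing onset of the first beat (default 5 ms)
#' @param dispersion_window_px,threshold_ms oracle settings for the
#'   ground-truth area fraction
#' @param seed integer seed (noise only)
#' @return list with `movie` ([voltage_movie()]) and `truth` (list:
#'   `apd_field`, `activation_field` ms, `true_area_fraction_pct`,
#'   `singularities` — empty tibble for paced movies)
#' @export
synthesize_movie <- function(field,
                             meta = acquisition_meta(n_frames = 1200L,
                                                     height = 100L,
                                                     width = 100L),
                             pacing = list(cycle_length_ms = 100,
                                           n_beats = NULL),
                             wave = list(direction_deg = 0,
                                         speed_mm_per_ms = 0.3),
                             noise = list(gaussian_sd = 0,
                                          drift_amplitude = 0,
                                          drift_freq_hz = 1,
                                          bleach_frac = 0),
                             level_pct = 90,
                             mask = NULL,
                             start_ms = 5,
                             dispersion_window_px = 10L,
                             threshold_ms = 10,
                             seed = 1L) {
  values <- if (inherits(field, "apd_field")) field$values else field
  H <- nrow(values); W <- ncol(values)
  meta$height <- H; meta$width <- W
  nf <- meta$n_frames
  fs <- meta$frame_rate_hz
  dt <- 1000 / fs
  cl <- pacing$cycle_length_ms %||% 100
  if (cl <= max(values) + 20) {
    stop("cycle length must exceed max APD + 20 ms (wave fusion)",
         call. = FALSE)
  }
  dur_ms <- nf * dt
  if (dur_ms < 2 * cl) stop("movie too short for two beats", call. = FALSE)

  dir_rad <- (wave$direction_deg %||% 0) * pi / 180
  speed <- wave$speed_mm_per_ms %||% 0.3
  rows <- matrix(seq_len(H) - 1L, H, W)
  cols <- matrix(seq_len(W) - 1L, H, W, byrow = TRUE)
  proj <- cols * cos(dir_rad) + rows * sin(dir_rad)
  delay <- (proj - min(proj)) * meta$pixel_pitch_mm / speed

  # every beat whose onset falls inside the recording
  n_beats <- pacing$n_beats %||% (floor((dur_ms - start_ms - 1e-9) / cl) + 1)
  t_ms <- (seq_len(nf) - 1L) * dt
  npix <- H * W
  apd_vec <- as.vector(values)
  delay_vec <- as.vector(delay)

  data_mat <- matrix(0, nf, npix)
  block <- 1000L
  for (b0 in seq(1L, npix, by = block)) {
    b1 <- min(npix, b0 + block - 1L)
    idx <- b0:b1
    tt <- outer(t_ms, delay_vec[idx] + start_ms, `-`)
    beat <- floor(tt / cl)
    before <- beat < 0
    # after the pacing train stops, let the last beat finish naturally
    beat[beat > (n_beats - 1)] <- n_beats - 1
    s <- tt - beat * cl
    s[before] <- -1
    apd_blk <- matrix(apd_vec[idx], nf, length(idx), byrow = TRUE)
    data_mat[, idx] <- ap_template_field(s, apd_blk, level_pct)
  }

  withr::with_seed(as.integer(seed), {
    g_sd <- noise$gaussian_sd %||% 0
    if (g_sd > 0) {
      data_mat <- data_mat + matrix(stats::rnorm(nf * npix, 0, g_sd), nf, npix)
    }
    drift_a <- noise$drift_amplitude %||% 0
    if (drift_a > 0) {
      ph <- stats::runif(npix, 0, 2 * pi)
      fd <- noise$drift_freq_hz %||% 1
      data_mat <- data_mat +
        drift_a * sin(outer(2 * pi * fd * t_ms / 1000, ph, `+`))
    }
    bl <- noise$bleach_frac %||% 0
    if (bl != 0) {
      data_mat <- data_mat - bl * (t_ms / dur_ms)
    }
  })

  movie <- voltage_movie(array(data_mat, c(nf, H, W)), meta, mask)
  truth <- list(
    apd_field = if (inherits(field, "apd_field")) field else
      structure(list(values = values, pattern = "constant"),
                class = "apd_field"),
    activation_field = delay,
    true_area_fraction_pct = true_area_fraction(values,
      mask = movie$mask, window_px = dispersion_window_px,
      threshold_ms = threshold_ms),
    singularities = tibble::tibble(frame = integer(), row = numeric(),
                                   col = numeric(), charge = integer())
  )
  list(movie = movie, truth = truth)
}

#' Generate an analytic spiral-wave (reentry) movie
#'
#' Builds a phase-defined Archimedean spiral movie
#' `v(x, y, t) = cos(2 pi f t + sum_j chirality_j * theta_j + 2 pi r_1 /
#' wavelength)` with one or more phase singularities pinned at the given
#' cores for every frame. Two cores of opposite chirality produce a
#' figure-of-eight with zero net topological charge. Ground truth records
#' the core locations and charges per frame.
#'
#' @param meta an [acquisition_meta()]
#' @param rotation_freq_hz rotation frequency (must be below a quarter of
#'   the Nyquist frequency)
#' @param cores list of `list(row=, col=, chirality=+1/-1)`; a single core
#'   may be given directly as `list(row=, col=, chirality=)`
#' @param wavelength_px spatial wavelength of the spiral arm
#' @param noise_sd additive white-noise sd
#' @param seed integer seed (noise only)
#' @return list with `movie` and `truth` (tibble `singularities`:
#'   frame, row, col, charge)
#' @export
generate_spiral_movie <- function(meta = acquisition_meta(n_frames = 500L),
                                  rotation_freq_hz = 10,
                                  cores = list(list(row = 50, col = 50,
                                                    chirality = 1L)),
                                  wavelength_px = 40,
                                  noise_sd = 0,
                                  seed = 1L) {
  if (!is.null(cores$row)) cores <- list(cores)
  fs <- meta$frame_rate_hz
  if (rotation_freq_hz > fs / 8) {
    stop("rotation frequency exceeds a quarter of the Nyquist frequency",
         call. = FALSE)
  }
  H <- meta$height; W <- meta$width; nf <- meta$n_frames
  for (co in cores) {
    if (co$row < 1 || co$row > H || co$col < 1 || co$col > W) {
      stop("spiral core outside the grid", call. = FALSE)
    }
  }
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  spatial <- matrix(0, H, W)
  for (co in cores) {
    theta <- atan2(rows - co$row, cols - co$col)
    spatial <- spatial + co$chirality * theta
  }
  r1 <- sqrt((rows - cores[[1L]]$row)^2 + (cols - cores[[1L]]$col)^2)
  spatial <- spatial + 2 * pi * r1 / wavelength_px
  t_s <- (seq_len(nf) - 1L) / fs
  data <- array(0, c(nf, H, W))
  sp_vec <- as.vector(spatial)
  mat <- outer(2 * pi * rotation_freq_hz * t_s, rep(1, H * W)) +
    matrix(sp_vec, nf, H * W, byrow = TRUE)
  data_mat <- cos(mat)
  if (noise_sd > 0) {
    withr::with_seed(as.integer(seed), {
      data_mat <- data_mat + matrix(stats::rnorm(nf * H * W, 0, noise_sd),
                                    nf, H * W)
    })
  }
  movie <- voltage_movie(array(data_mat, c(nf, H, W)), meta)
  truth <- list(
    singularities = tibble::tibble(
      frame = rep(seq_len(nf), times = length(cores)),
      row = rep(vapply(cores, `[[`, numeric(1), "row"), each = nf),
      col = rep(vapply(cores, `[[`, numeric(1), "col"), each = nf),
      charge = rep(vapply(cores, function(co) as.integer(co$chirality),
                          integer(1)), each = nf))
  )
  list(movie = movie, truth = truth)
}
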