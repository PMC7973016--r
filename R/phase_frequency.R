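# Dominant-frequency, phase and phase-singularity analysis for fibrillation
# recordings.

#' Dominant-frequency map
#'
#' Per-pixel detrended Hann-windowed periodogram; the dominant frequency is
#' the in-band peak, with the fraction of band power carried by the peak
#' recorded as a quality index. Pixels with no spectral content (flat
#' traces) are invalid.
#'
#' @param movie a [voltage_movie()]
#' @param band_hz frequency band searched, default `c(1, 40)`
#' @return object of class `df_map`: `freq_hz`, `power_fraction`, `band_hz`,
#'   `valid`
#' @export
dominant_frequency_map <- function(movie, band_hz = c(1, 40)) {
  d <- dim(movie$data)
  nf <- d[1L]; H <- d[2L]; W <- d[3L]
  fs <- movie$meta$frame_rate_hz
  if (band_hz[2L] > fs / 2) {
    stop("band extends above the Nyquist frequency", call. = FALSE)
  }
  if (nf / fs < 2) {
    warning("recording shorter than 2 s: frequency resolution coarser ",
            "than 0.5 Hz", call. = FALSE)
  }
  x <- movie$data
  dim(x) <- c(nf, H * W)
  # linear detrend + Hann window
  tc <- seq_len(nf) - (nf + 1) / 2
  slope <- colSums(x * tc) / sum(tc^2)
  x <- x - outer(tc, slope)
  x <- sweep(x, 2L, colMeans(x))
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(nf) - 1L) / (nf - 1L)))
  freqs <- (seq_len(nf) - 1L) * fs / nf
  band_idx <- which(freqs >= band_hz[1L] & freqs <= band_hz[2L])
  freq_out <- matrix(NA_real_, H, W)
  pf_out <- matrix(NA_real_, H, W)
  block <- 2000L
  npix <- H * W
  for (b0 in seq(1L, npix, by = block)) {
    b1 <- min(npix, b0 + block - 1L)
    sp <- Mod(stats::mvfft(x[, b0:b1, drop = FALSE] * hann))^2
    spb <- sp[band_idx, , drop = FALSE]
    tot <- colSums(spb)
    pk <- apply(spb, 2L, which.max)
    ok <- tot > 1e-20
    fo <- rep(NA_real_, b1 - b0 + 1L)
    po <- rep(NA_real_, b1 - b0 + 1L)
    fo[ok] <- freqs[band_idx[pk[ok]]]
    po[ok] <- spb[cbind(pk[ok], which(ok))] / tot[ok]
    freq_out[b0:b1] <- fo
    pf_out[b0:b1] <- po
  }
  valid <- is.finite(freq_out) & movie$mask
  freq_out[!valid] <- NA_real_
  structure(list(freq_hz = freq_out, power_fraction = pf_out,
                 band_hz = band_hz, valid = valid),
            class = "df_map")
}

#' Phase movie via the Hilbert transform
#'
#' Instantaneous phase of each pixel's mean-subtracted trace from the
#' analytic signal (FFT construction of the Hilbert transform). Values lie
#' in `(-pi, pi]`. Constant pixels have undefined phase and are masked.
#'
#' @param movie a [voltage_movie()] (detrended/mean-stationary input
#'   expected)
#' @return object of class `phase_movie`: `phase` array `[frame, row, col]`,
#'   `valid`, `meta`
#' @export
phase_movie <- function(movie) {
  d <- dim(movie$data)
  nf <- d[1L]; H <- d[2L]; W <- d[3L]
  x <- movie$data
  dim(x) <- c(nf, H * W)
  mu <- colMeans(x)
  x <- sweep(x, 2L, mu)
  rng <- apply(x, 2L, function(v) max(v) - min(v))
  valid <- matrix(rng > 1e-12 & as.vector(movie$mask), H, W)
  ph <- matrix(0, nf, H * W)
  block <- 2000L
  for (b0 in seq(1L, H * W, by = block)) {
    b1 <- min(H * W, b0 + block - 1L)
    ph[, b0:b1] <- Arg(analytic_signal(x[, b0:b1, drop = FALSE]))
  }
  ph[, !as.vector(valid)] <- NA_real_
  structure(list(phase = array(ph, c(nf, H, W)), valid = valid,
                 meta = movie$meta),
            class = "phase_movie")
}

#' Detect phase singularities and build an SPD map
#'
#' For every 2x2 plaquette of each frame, sums the wrapped phase
#' differences around the loop; a total of +/- 2 pi marks a phase
#' singularity at the plaquette centre with topological charge equal to the
#' winding sign. Per-frame detections are aggregated into a singularity
#' point density (SPD) map: visits per pixel neighbourhood (centred
#' `spd_window_px` window) per second.
#'
#' @param phase a [phase_movie()]
#' @param spd_window_px smoothing window for the SPD map (default 10,
#'   matching the dispersion neighbourhood)
#' @return object of class `singularity_set`: `events` tibble
#'   (`frame`, `row`, `col`, `charge`), `spd_map` (visits per window per
#'   second), `n_frames`
#' @export
detect_singularities <- function(phase, spd_window_px = 10L) {
  stopifnot(inherits(phase, "phase_movie"))
  d <- dim(phase$phase)
  nf <- d[1L]; H <- d[2L]; W <- d[3L]
  fs <- phase$meta$frame_rate_hz
  counts <- matrix(0, H, W)
  ev_frame <- list()
  vmask <- phase$valid
  v4 <- vmask[1:(H - 1), 1:(W - 1)] & vmask[1:(H - 1), 2:W] &
    vmask[2:H, 1:(W - 1)] & vmask[2:H, 2:W]
  for (k in seq_len(nf)) {
    P <- matrix(phase$phase[k, , ], H, W)
    d1 <- wrap_phase(P[1:(H - 1), 2:W] - P[1:(H - 1), 1:(W - 1)])
    d2 <- wrap_phase(P[2:H, 2:W] - P[1:(H - 1), 2:W])
    d3 <- wrap_phase(P[2:H, 1:(W - 1)] - P[2:H, 2:W])
    d4 <- wrap_phase(P[1:(H - 1), 1:(W - 1)] - P[2:H, 1:(W - 1)])
    winding <- d1 + d2 + d3 + d4
    winding[!v4] <- 0
    hit <- abs(winding) > pi  # winding is 0 or +/- 2 pi up to rounding
    if (any(hit)) {
      ri <- row(winding)[hit]
      ci <- col(winding)[hit]
      # loop orientation chosen so charge equals the winding sign of the
      # phase field (a +theta field yields +1)
      ch <- as.integer(sign(winding[hit]))
      ev_frame[[length(ev_frame) + 1L]] <-
        tibble::tibble(frame = k, row = ri + 0.5, col = ci + 0.5,
                       charge = ch)
      counts[cbind(ri, ci)] <- counts[cbind(ri, ci)] + 1
    }
  }
  events <- if (length(ev_frame)) dplyr::bind_rows(ev_frame) else
    tibble::tibble(frame = integer(), row = numeric(), col = numeric(),
                   charge = integer())
  dur_s <- nf / fs
  spd <- shift_window_sum(counts, spd_window_px) / dur_s
  structure(list(events = events, spd_map = spd, n_frames = nf,
                 spd_window_px = as.integer(spd_window_px)),
            class = "singularity_set")
}

#' @export
print.singularity_set <- function(x, ...) {
  cat(sprintf(
    "<singularity_set> %d events over %d frames | peak SPD %.2f visits/s\n",
    nrow(x$events), x$n_frames, max(x$spd_map)))
  invisible(x)
}

#' Compare APD statistics at the highest-SPD region vs a neighbouring window
#'
#' Region A is the `window_px` x `window_px` window centred on the SPD-map
#' maximum; region B is the nearest fully-valid non-overlapping window of
#' the same size (by centre distance, ties broken row-then-column). Reports
#' average APD, maximum APD and APD dispersion (population std) for each
#' region and their A - B differences.
#'
#' @param apd an `apd_map` co-registered with the singularity data
#' @param spd a `singularity_set` (or an SPD matrix)
#' @param window_px comparison window width (default 10)
#' @return tibble with rows `highest_spd`, `neighbor`, `difference` and
#'   columns `mean_apd_ms`, `max_apd_ms`, `std_apd_ms`; window centres in
#'   attributes `center_a`, `center_b`
#' @export
compare_spd_region <- function(apd, spd, window_px = 10L) {
  spd_map <- if (inherits(spd, "singularity_set")) spd$spd_map else spd
  stopifnot(inherits(apd, "apd_map"),
            identical(dim(apd$values), dim(spd_map)))
  H <- nrow(spd_map); W <- ncol(spd_map)
  w <- as.integer(window_px)
  off <- window_offsets(w)
  pk <- which(spd_map == max(spd_map), arr.ind = TRUE)[1L, ]
  # clamp the centre so the window sits inside the grid
  ca <- c(min(max(pk[1L], 1 - off[1L]), H - off[length(off)]),
          min(max(pk[2L], 1 - off[1L]), W - off[length(off)]))
  ra <- ca[1L] + off; cc_a <- ca[2L] + off

  centers_r <- (1 - off[1L]):(H - off[length(off)])
  centers_c <- (1 - off[1L]):(W - off[length(off)])
  best <- NULL
  best_d2 <- Inf
  for (r in centers_r) {
    for (cn in centers_c) {
      rb <- r + off; cb <- cn + off
      if (max(rb[1L], ra[1L]) <= min(rb[w], ra[w]) &&
            max(cb[1L], cc_a[1L]) <= min(cb[w], cc_a[w])) next  # overlaps A
      if (!all(apd$valid[rb, cb])) next
      d2 <- (r - ca[1L])^2 + (cn - ca[2L])^2
      if (d2 < best_d2) {
        best_d2 <- d2
        best <- c(r, cn)
      }
    }
  }
  if (is.null(best)) {
    stop("no fully-valid non-overlapping neighbour window", call. = FALSE)
  }
  stats_of <- function(rr, cc) {
    vals <- apd$values[rr, cc][apd$valid[rr, cc]]
    c(mean(vals), max(vals), sqrt(mean((vals - mean(vals))^2)))
  }
  a <- stats_of(ra, cc_a)
  b <- stats_of(best[1L] + off, best[2L] + off)
  out <- tibble::tibble(
    region = c("highest_spd", "neighbor", "difference"),
    mean_apd_ms = c(a[1L], b[1L], a[1L] - b[1L]),
    max_apd_ms = c(a[2L], b[2L], a[2L] - b[2L]),
    std_apd_ms = c(a[3L], b[3L], a[3L] - b[3L]))
  attr(out, "center_a") <- ca
  attr(out, "center_b") <- best
  out
}
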