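#' Signal-conditioning and APD-measurement configuration
#'
#' @param spatial_filter_px odd width of the spatial mean filter (1 = off)
#' @param temporal_filter_ms width of the temporal moving average, ms (0 = off)
#' @param repolarization_level_pct repolarization level L for APD_L, in
#'   (0, 100); 90 (APD90) is the usual optical-mapping convention, 50-90
#'   supported
#' @param detrend remove a per-pixel linear trend before normalization
#' @param beat_policy `"median_over_beats"` (robust default) or
#'   `"single_beat_index"`
#' @param beat_index beat used when `beat_policy = "single_beat_index"`
#' @param activation_fiducial `"upstroke_midpoint"` (50% upstroke crossing,
#'   noise-robust) or `"max_dvdt"`
#' @param lockout_ms refractory lockout between detected activations
#' @return an object of class `signal_config`
#' @export
signal_config <- function(spatial_filter_px = 1L,
                          temporal_filter_ms = 0,
                          repolarization_level_pct = 90,
                          detrend = FALSE,
                          beat_policy = c("median_over_beats",
                                          "single_beat_index"),
                          beat_index = 1L,
                          activation_fiducial = c("upstroke_midpoint",
                                                  "max_dvdt"),
                          lockout_ms = 30) {
  beat_policy <- match.arg(beat_policy)
  activation_fiducial <- match.arg(activation_fiducial)
  stopifnot(spatial_filter_px >= 1L, spatial_filter_px %% 2L == 1L,
            temporal_filter_ms >= 0,
            repolarization_level_pct > 0, repolarization_level_pct < 100)
  structure(
    list(spatial_filter_px = as.integer(spatial_filter_px),
         temporal_filter_ms = temporal_filter_ms,
         repolarization_level_pct = repolarization_level_pct,
         detrend = isTRUE(detrend),
         beat_policy = beat_policy,
         beat_index = as.integer(beat_index),
         activation_fiducial = activation_fiducial,
         lockout_ms = lockout_ms),
    class = "signal_config")
}

#' Condition a voltage movie for APD analysis
#'
#' Per-pixel linear detrend (optional), temporal moving-average low-pass,
#' per-frame spatial mean smoothing over tissue pixels, then per-pixel
#' amplitude normalization to `[0, 1]` over the whole recording. Pixels
#' with no dynamic range (flat traces) are marked invalid rather than
#' raising an error. The tissue mask is preserved.
#'
#' @param movie a [voltage_movie()]
#' @param config a [signal_config()]
#' @return a `voltage_movie` with normalized data, a `valid` matrix and the
#'   config recorded
#' @export
preprocess <- function(movie, config = signal_config()) {
  d <- dim(movie$data)
  nf <- d[1L]; H <- d[2L]; W <- d[3L]
  x <- movie$data
  dim(x) <- c(nf, H * W)

  if (config$detrend) {
    tc <- seq_len(nf) - (nf + 1) / 2
    slope <- colSums(x * tc) / sum(tc^2)
    x <- x - outer(tc, slope)
  }
  if (config$temporal_filter_ms > 0) {
    wid <- max(1L, round(config$temporal_filter_ms *
                           movie$meta$frame_rate_hz / 1000))
    if (wid > 1L) x <- moving_average_cols(x, wid)
  }
  if (config$spatial_filter_px > 1L) {
    w <- config$spatial_filter_px
    mnum <- shift_window_sum(movie$mask * 1, w)
    for (k in seq_len(nf)) {
      fr <- matrix(x[k, ], H, W)
      fr[!movie$mask] <- 0
      sm <- shift_window_sum(fr, w) / pmax(mnum, 1)
      sm[!movie$mask] <- matrix(x[k, ], H, W)[!movie$mask]
      x[k, ] <- sm
    }
  }

  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  rng <- hi - lo
  valid <- matrix(rng > 1e-12 & as.vector(movie$mask), H, W)
  rng[rng <= 1e-12] <- 1
  x <- sweep(sweep(x, 2L, lo), 2L, rng, `/`)

  out <- voltage_movie(array(x, c(nf, H, W)), movie$meta, movie$mask)
  out$valid <- valid
  out$preprocessed <- TRUE
  out$config <- config
  out
}

#' Detect activations (beat upstrokes) in a normalized trace
#'
#' An activation is an upward crossing of 0.5 amplitude; crossings within
#' the refractory lockout of the previous accepted activation are
#' suppressed. Indices are strictly increasing; an empty vector means no
#' crossing was found.
#'
#' @param trace numeric vector, normalized to `[0, 1]`
#' @param frame_rate_hz sampling rate
#' @param threshold crossing level (default 0.5)
#' @param lockout_ms refractory lockout (default 30 ms)
#' @return integer vector of activation frame indices (frame after the
#'   crossing)
#' @export
detect_beats <- function(trace, frame_rate_hz, threshold = 0.5,
                         lockout_ms = 30) {
  n <- length(trace)
  if (n < 2L) return(integer(0))
  up <- which(trace[-n] < threshold & trace[-1L] >= threshold) + 1L
  if (length(up) == 0L) return(integer(0))
  lock <- lockout_ms * frame_rate_hz / 1000
  keep <- up[1L]
  last <- up[1L]
  for (i in up[-1L]) {
    if (i - last >= lock) {
      keep <- c(keep, i)
      last <- i
    }
  }
  keep
}

#' Measure APD of a single beat
#'
#' APD_L is the time from the upstroke midpoint (interpolated crossing of
#' 50% of the beat's baseline-to-peak amplitude) to the first downward
#' crossing of `(1 - L/100)` of that amplitude after the peak, with linear
#' interpolation between frames. The amplitude reference is per beat
#' (local baseline to local peak), which tolerates residual drift. Returns
#' `NA` when repolarization is not reached before the next beat (or the end
#' of the trace).
#'
#' @param trace numeric trace (normalized or raw; the measure is invariant
#'   to affine rescaling)
#' @param activation_index activation frame from [detect_beats()]
#' @param level_pct repolarization level L in (0, 100)
#' @param frame_rate_hz sampling rate
#' @param next_index activation frame of the following beat (bounds the
#'   search); default end of trace
#' @param lockout_ms pre-activation window used for the baseline estimate
#' @return APD in ms, or `NA_real_` if the beat is incomplete
#' @export
compute_apd <- function(trace, activation_index, level_pct = 90,
                        frame_rate_hz = 1000, next_index = NULL,
                        lockout_ms = 30) {
  n <- length(trace)
  dt <- 1000 / frame_rate_hz
  ai <- as.integer(activation_index)
  seg_end <- if (is.null(next_index)) n else as.integer(next_index) - 1L
  if (ai < 2L || ai > n || seg_end <= ai) return(NA_real_)

  b0 <- max(1L, ai - as.integer(ceiling(lockout_ms / dt)))
  # baseline: mean of the diastolic window just before the upstroke foot
  # (noise-robust, unlike a raw minimum); fall back to the window minimum
  # when the trace is too short
  bw_hi <- ai - max(1L, as.integer(ceiling(3 / dt)))
  bw_lo <- max(1L, bw_hi - as.integer(ceiling(10 / dt)))
  baseline <- if (bw_hi > bw_lo) mean(trace[bw_lo:bw_hi]) else
    min(trace[b0:ai])
  # peak: max of a 3-frame moving average (debiases single-sample noise)
  seg_beat <- trace[ai:seg_end]
  sm <- if (length(seg_beat) >= 3L) {
    (seg_beat[1:(length(seg_beat) - 2L)] + seg_beat[2:(length(seg_beat) - 1L)] +
       seg_beat[3:length(seg_beat)]) / 3
  } else seg_beat
  peak <- max(sm)
  peak_idx <- ai + which.max(trace[ai:seg_end]) - 1L
  amp <- peak - baseline
  if (amp <= 0) return(NA_real_)

  mid <- baseline + 0.5 * amp
  # last upward crossing of mid before the peak
  lo <- b0
  seg <- trace[lo:peak_idx]
  cr <- which(seg[-length(seg)] < mid & seg[-1L] >= mid)
  if (length(cr) == 0L) return(NA_real_)
  i0 <- lo + cr[length(cr)] - 1L
  t_mid <- cross_time(trace[i0], trace[i0 + 1L], i0, mid)

  lev <- baseline + (1 - level_pct / 100) * amp
  seg2 <- trace[peak_idx:seg_end]
  dn <- which(seg2[-length(seg2)] >= lev & seg2[-1L] < lev)
  if (length(dn) == 0L) return(NA_real_)  # repolarization not reached
  # noise can trigger spurious early/late level crossings symmetrically;
  # the midpoint of the first and last down-crossing debiases the estimate
  # (they coincide on clean traces)
  j1 <- peak_idx + dn[1L] - 1L
  j2 <- peak_idx + dn[length(dn)] - 1L
  t_rep <- (cross_time(trace[j1], trace[j1 + 1L], j1, lev) +
              cross_time(trace[j2], trace[j2 + 1L], j2, lev)) / 2

  (t_rep - t_mid) * dt
}

#' Per-pixel APD map
#'
#' Runs beat detection and per-beat APD measurement on every tissue pixel of
#' a (preprocessed) movie, aggregating over beats according to the beat
#' policy (default: median over all complete beats). Pixels where detection
#' or repolarization fails are flagged invalid.
#'
#' @param movie a [voltage_movie()]; preprocessed automatically if needed
#' @param config a [signal_config()]
#' @return an object of class `apd_map`: list with `values` (ms), `level_pct`,
#'   `valid`, `meta`, `n_beats_used`
#' @export
compute_apd_map <- function(movie, config = signal_config()) {
  if (!isTRUE(movie$preprocessed)) movie <- preprocess(movie, config)
  d <- dim(movie$data)
  nf <- d[1L]; H <- d[2L]; W <- d[3L]
  fs <- movie$meta$frame_rate_hz
  x <- movie$data
  dim(x) <- c(nf, H * W)
  valid_in <- movie$valid %||% movie$mask
  values <- matrix(NA_real_, H, W)
  valid <- matrix(FALSE, H, W)
  nb_used <- matrix(0L, H, W)
  level <- config$repolarization_level_pct

  for (p in which(as.vector(valid_in))) {
    tr <- x[, p]
    acts <- detect_beats(tr, fs, lockout_ms = config$lockout_ms)
    if (length(acts) == 0L) next
    nxt <- c(acts[-1L], nf + 1L)
    apds <- vapply(seq_along(acts), function(k) {
      compute_apd(tr, acts[k], level, fs, next_index = nxt[k],
                  lockout_ms = config$lockout_ms)
    }, numeric(1))
    apds <- apds[is.finite(apds)]
    if (length(apds) == 0L) next
    v <- if (config$beat_policy == "median_over_beats") {
      stats::median(apds)
    } else {
      bi <- min(config$beat_index, length(apds))
      apds[bi]
    }
    values[p] <- v
    valid[p] <- TRUE
    nb_used[p] <- length(apds)
  }
  if (!any(valid)) {
    warning("no pixel yielded a complete beat", call. = FALSE)
  }
  structure(
    list(values = values, level_pct = level, valid = valid,
         meta = movie$meta, n_beats_used = nb_used),
    class = "apd_map")
}

#' @export
print.apd_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf(
    "<apd_map> %d x %d px | APD%g | valid %d px | mean %.1f ms | max %.1f ms\n",
    nrow(x$values), ncol(x$values), x$level_pct, sum(x$valid),
    mean(v), max(v)))
  invisible(x)
}

#' Per-pixel local activation times
#'
#' Activation time of the `beat`-th detected beat at each pixel, in ms,
#' referenced to the earliest activation on the map (interpolated 50%
#' upstroke crossing).
#'
#' @param movie a (preprocessed) [voltage_movie()]
#' @param config a [signal_config()]
#' @param beat beat number to map (default 1)
#' @return object of class `activation_map`: list with `times_ms`, `valid`,
#'   `meta`
#' @export
compute_activation_map <- function(movie, config = signal_config(),
                                   beat = 1L) {
  if (!isTRUE(movie$preprocessed)) movie <- preprocess(movie, config)
  d <- dim(movie$data)
  nf <- d[1L]; H <- d[2L]; W <- d[3L]
  fs <- movie$meta$frame_rate_hz
  x <- movie$data
  dim(x) <- c(nf, H * W)
  valid_in <- movie$valid %||% movie$mask
  times <- matrix(NA_real_, H, W)
  for (p in which(as.vector(valid_in))) {
    tr <- x[, p]
    acts <- detect_beats(tr, fs, lockout_ms = config$lockout_ms)
    if (length(acts) < beat) next
    i <- acts[beat]
    if (i < 2L) next
    t_cr <- cross_time(tr[i - 1L], tr[i], i - 1L, 0.5)
    times[p] <- (t_cr - 1) * 1000 / fs
  }
  valid <- is.finite(times)
  times <- times - min(times[valid])
  structure(list(times_ms = times, valid = valid, meta = movie$meta),
            class = "activation_map")
}

#' Local conduction-velocity map
#'
#' Fits a plane to the local activation times in a centred window around
#' each pixel; conduction speed is the inverse gradient magnitude
#' (mm/ms). Pixels whose window is incompletely valid, whose fit is
#' singular or near-flat (simultaneous activation), or whose fit residual
#' exceeds the tolerance are invalid.
#'
#' @param activation an `activation_map` (or numeric matrix of times, ms)
#' @param pixel_pitch_mm pixel size in mm
#' @param window_px odd window width (default 5)
#' @param residual_tol_ms maximum RMS plane-fit residual (default 1 ms)
#' @param min_grad_ms_per_px gradients below this are treated as
#'   simultaneous activation (default 1e-6)
#' @return list of class `cv_map`: `speed_mm_per_ms` matrix and `valid`
#' @export
estimate_cv_map <- function(activation, pixel_pitch_mm = 0.095,
                            window_px = 5L, residual_tol_ms = 1,
                            min_grad_ms_per_px = 1e-6) {
  times <- if (inherits(activation, "activation_map")) activation$times_ms
           else activation
  vin <- if (inherits(activation, "activation_map")) activation$valid
         else is.finite(times)
  H <- nrow(times); W <- ncol(times)
  stopifnot(window_px %% 2L == 1L, window_px >= 3L)
  h <- (window_px - 1L) %/% 2L
  off <- -h:h
  dg <- expand.grid(dr = off, dc = off)
  speed <- matrix(NA_real_, H, W)
  valid <- matrix(FALSE, H, W)
  for (i in (1L + h):(H - h)) {
    for (j in (1L + h):(W - h)) {
      if (!vin[i, j]) next
      rw <- i + dg$dr; cw <- j + dg$dc
      tv <- times[cbind(rw, cw)]
      ok <- is.finite(tv) & vin[cbind(rw, cw)]
      if (sum(ok) < window_px^2) next  # require a fully valid window
      X <- cbind(1, dg$dc[ok], dg$dr[ok])
      fit <- tryCatch(qr.solve(crossprod(X), crossprod(X, tv[ok])),
                      error = function(e) NULL)
      if (is.null(fit)) next
      res <- tv[ok] - X %*% fit
      if (sqrt(mean(res^2)) > residual_tol_ms) next
      g <- sqrt(fit[2L]^2 + fit[3L]^2)  # ms per px
      if (g < min_grad_ms_per_px) next  # simultaneous activation
      speed[i, j] <- pixel_pitch_mm / g
      valid[i, j] <- TRUE
    }
  }
  structure(list(speed_mm_per_ms = speed, valid = valid,
                 window_px = as.integer(window_px)),
            class = "cv_map")
}
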