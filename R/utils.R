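# Internal helpers shared across modules.

#' Window offsets for a centred sliding window
#'
#' Odd widths are symmetric; even widths carry the extra row/column on the
#' bottom/right so that results are bit-reproducible.
#'
#' @param window_px window width in pixels (integer >= 1)
#' @return integer vector of offsets relative to the centre pixel
#' @keywords internal
#' @noRd
window_offsets <- function(window_px) {
  w <- as.integer(window_px)
  stopifnot(w >= 1L)
  if (w %% 2L == 1L) {
    h <- (w - 1L) %/% 2L
    seq.int(-h, h)
  } else {
    seq.int(-(w %/% 2L - 1L), w %/% 2L)
  }
}

# Windowed sum by explicit shift accumulation (numerically gentler than a
# summed-area table; cost w^2 matrix adds).
shift_window_sum <- function(x, window_px) {
  H <- nrow(x)
  W <- ncol(x)
  out <- matrix(0, H, W)
  for (dr in window_offsets(window_px)) {
    ri <- max(1L, 1L - dr):min(H, H - dr)
    if (length(ri) == 0L) next
    for (dc in window_offsets(window_px)) {
      ci <- max(1L, 1L - dc):min(W, W - dc)
      if (length(ci) == 0L) next
      out[ri, ci] <- out[ri, ci] + x[ri + dr, ci + dc]
    }
  }
  out
}

# 8-connected component labelling by iterative minimum-label propagation.
# Adequate for optical-mapping grids (~1e4 px); converges in O(diameter)
# sweeps.
label_components_8 <- function(binary) {
  H <- nrow(binary)
  W <- ncol(binary)
  lab <- matrix(0L, H, W)
  lab[binary] <- seq_len(sum(binary))
  idx <- matrix(seq_len(H * W), H, W)
  lab[binary] <- idx[binary]
  shifts <- list(
    c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
    c(0L, -1L), c(0L, 1L),
    c(1L, -1L), c(1L, 0L), c(1L, 1L)
  )
  repeat {
    new_lab <- lab
    for (s in shifts) {
      dr <- s[1]; dc <- s[2]
      ri <- max(1L, 1L - dr):min(H, H - dr)
      ci <- max(1L, 1L - dc):min(W, W - dc)
      nb <- lab[ri + dr, ci + dc, drop = FALSE]
      cur <- new_lab[ri, ci, drop = FALSE]
      take <- nb > 0L & cur > 0L & nb < cur
      cur[take] <- nb[take]
      new_lab[ri, ci] <- cur
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  # compact labels to 1..k
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

# Analytic signal per column via FFT (columns are time series).
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n %/% 2L + 1L] <- 1
    h[2:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) %/% 2L)] <- 2
  }
  stats::mvfft(stats::mvfft(x) * h, inverse = TRUE) / n
}

# Wrap phase differences into (-pi, pi].
wrap_phase <- function(d) {
  out <- -((-d + pi) %% (2 * pi) - pi)
  out
}

# Moving average along columns with edge handling by partial windows.
moving_average_cols <- function(x, width) {
  w <- as.integer(width)
  if (w <= 1L) return(x)
  n <- nrow(x)
  off <- window_offsets(w)
  cs <- apply(x, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = n)
  pad <- rbind(0, cs)
  lo <- pmax(0L, seq_len(n) + off[1L] - 1L)
  hi <- pmin(n, seq_len(n) + off[length(off)])
  sums <- pad[hi + 1L, , drop = FALSE] - pad[lo + 1L, , drop = FALSE]
  counts <- hi - lo
  sums / counts
}

# Linear interpolation of the time (in fractional index units) where a
# series crosses `level` between samples i and i+1.
cross_time <- function(y0, y1, i, level) {
  i + (level - y0) / (y1 - y0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
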