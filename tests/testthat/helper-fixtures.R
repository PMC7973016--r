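# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles are deliberately naive (double loops, closed forms) and never call
# the production code paths they check.

# paced synthetic recording over a field, small enough for routine tests
make_paced_sim <- function(grid = c(40L, 40L), pattern = "clustered",
                           island_params = list(count = 6, mean_radius_px = 5,
                                                elevation_ms = 25),
                           noise = list(gaussian_sd = 0),
                           n_frames = 1200L, seed = 3L) {
  field <- generate_apd_field(pattern, grid, 50, island_params, seed = seed)
  meta <- acquisition_meta(n_frames = n_frames, height = grid[1L],
                           width = grid[2L])
  sim <- synthesize_movie(field, meta, noise = noise, seed = seed)
  sim$field <- field
  sim
}

# population-std windowed dispersion at one pixel, straight from the
# definition (independent of both dispersion_map and
# brute_force_dispersion)
window_std_at <- function(values, i, j, w) {
  off <- if (w %% 2L == 1L) -((w - 1L) %/% 2L):((w - 1L) %/% 2L) else
    -(w %/% 2L - 1L):(w %/% 2L)
  ri <- i + off
  ci <- j + off
  ri <- ri[ri >= 1 & ri <= nrow(values)]
  ci <- ci[ci >= 1 & ci <= ncol(values)]
  vals <- as.vector(values[ri, ci])
  sqrt(mean((vals - mean(vals))^2))
}

# Moran's I by the textbook double loop over all pixel pairs
morans_i_brute <- function(x, weights = "rook") {
  H <- nrow(x); W <- ncol(x)
  n <- H * W
  z <- as.vector(x) - mean(x)
  coords <- cbind(rep(seq_len(H), times = W), rep(seq_len(W), each = H))
  num <- 0
  wtot <- 0
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      dr <- abs(coords[a, 1] - coords[b, 1])
      dc <- abs(coords[a, 2] - coords[b, 2])
      wab <- if (weights == "rook") as.numeric(dr + dc == 1) else
        as.numeric(max(dr, dc) == 1)
      num <- num + wab * z[a] * z[b]
      wtot <- wtot + wab
    }
  }
  (n / wtot) * num / sum(z^2)
}

# quadrat counts by direct assignment (full-rectangle region, grid a
# multiple of the quadrat size)
quadrat_counts_brute <- function(pts, H, W, q) {
  counts <- matrix(0L, H %/% q, W %/% q)
  for (k in seq_len(nrow(pts))) {
    qi <- min(nrow(counts), floor((pts[k, 1] - 0.5) / q) + 1L)
    qj <- min(ncol(counts), floor((pts[k, 2] - 0.5) / q) + 1L)
    counts[qi, qj] <- counts[qi, qj] + 1L
  }
  as.vector(counts)
}

# winding number of a phase field around a square loop centred on (r0, c0)
winding_number <- function(phase2d, r0, c0, radius = 4L) {
  rr <- round(r0); cc <- round(c0)
  top <- rr - radius; bot <- rr + radius
  lef <- cc - radius; rig <- cc + radius
  loop <- rbind(
    cbind(top, lef:rig),
    cbind(top:bot, rig),
    cbind(bot, rig:lef),
    cbind(bot:top, lef))
  vals <- phase2d[loop]
  d <- diff(c(vals, vals[1L]))
  d <- -((-d + pi) %% (2 * pi) - pi)
  round(sum(d) / (2 * pi))
}
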