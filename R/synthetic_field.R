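#' Generate a ground-truth APD field
#'
#' Builds a per-pixel action potential duration (ms) field consisting of a
#' homogeneous baseline plus elevated-APD islands laid out in one of the
#' three archetypal spatial arrangements of repolarization heterogeneity:
#'
#' * `"uniform"` — island centres on a jittered regular lattice (evenly
#'   spaced areas of dispersion);
#' * `"random"` — homogeneous Poisson (binomial) placement, any location
#'   equally likely;
#' * `"clustered"` — a Matern-style cluster process: parent centres with
#'   island offspring scattered within a cluster radius, producing patchy
#'   archipelagos of islands, optionally biased toward the tissue border;
#' * `"constant"` — no islands, zero spatial variance.
#'
#' Islands are rasterized as ovoids (random-orientation ellipses) or
#' serpiginous shapes (dilated self-avoiding random walks). Output is
#' deterministic given `seed`.
#'
#' @param pattern `"uniform"`, `"random"`, `"clustered"` or `"constant"`
#' @param grid `c(height, width)` in pixels
#' @param baseline_apd_ms baseline APD in ms (> 0)
#' @param island_params list with `count` (number of islands),
#'   `mean_radius_px` (mean island radius, px), `elevation_ms` (APD elevation
#'   inside islands, ms), `shape` (`"ovoid"` or `"serpiginous"`)
#' @param cluster_radius_px scatter radius of offspring about their parent
#'   (clustered pattern)
#' @param n_parents number of cluster parents (clustered pattern); default
#'   `max(2, round(count / 5))`
#' @param jitter_frac lattice jitter as a fraction of the lattice cell
#'   (uniform pattern)
#' @param edge_bias place cluster parents preferentially near the tissue
#'   border (clustered pattern)
#' @param seed integer seed
#' @return an object of class `apd_field`: list with `values` (H x W matrix,
#'   ms), `pattern`, `baseline_apd_ms`, `island_params`, `centers` (tibble of
#'   island centres, one row per island), `seed`
#' @export
generate_apd_field <- function(pattern = c("clustered", "uniform", "random",
                                           "constant"),
                               grid = c(100L, 100L),
                               baseline_apd_ms = 50,
                               island_params = list(count = 30,
                                                    mean_radius_px = 6,
                                                    elevation_ms = 25,
                                                    shape = "ovoid"),
                               cluster_radius_px = 8,
                               n_parents = NULL,
                               jitter_frac = 0.25,
                               edge_bias = FALSE,
                               seed = 1L) {
  pattern <- match.arg(pattern)
  H <- as.integer(grid[1L]); W <- as.integer(grid[2L])
  stopifnot(H >= 10L, W >= 10L, baseline_apd_ms > 0)
  ip <- utils::modifyList(
    list(count = 30L, mean_radius_px = 6, elevation_ms = 25, shape = "ovoid"),
    island_params)
  n <- if (pattern == "constant") 0L else as.integer(ip$count)
  r <- ip$mean_radius_px
  stopifnot(n >= 0L)
  if (n > 0L && r >= min(H, W) / 2) {
    stop("island radius must be below half the grid extent", call. = FALSE)
  }
  if (n > 0 && n * pi * r^2 > 0.9 * H * W) {
    stop("island parameters demand > 90% coverage of the grid; infeasible",
         call. = FALSE)
  }

  withr::with_seed(as.integer(seed), {
    centers <- switch(pattern,
      constant = matrix(numeric(0), ncol = 2L),
      uniform = place_lattice(n, H, W, jitter_frac),
      random = cbind(stats::runif(n, 1, H), stats::runif(n, 1, W)),
      clustered = place_matern(n, H, W, cluster_radius_px,
                               n_parents %||% max(2L, round(n / 5)),
                               edge_bias))
    values <- matrix(baseline_apd_ms, H, W)
    if (n > 0L) {
      inside <- matrix(FALSE, H, W)
      for (k in seq_len(nrow(centers))) {
        px <- if (identical(ip$shape, "serpiginous")) {
          rasterize_serpiginous(centers[k, 1L], centers[k, 2L], r, H, W)
        } else {
          rasterize_ovoid(centers[k, 1L], centers[k, 2L], r, H, W)
        }
        inside[px] <- TRUE
      }
      values[inside] <- baseline_apd_ms + ip$elevation_ms
    }
  })

  structure(
    list(values = values,
         pattern = pattern,
         baseline_apd_ms = baseline_apd_ms,
         island_params = ip,
         centers = tibble::tibble(row = centers[, 1L], col = centers[, 2L]),
         seed = as.integer(seed)),
    class = "apd_field")
}

#' @export
print.apd_field <- function(x, ...) {
  cat(sprintf("<apd_field> %d x %d px | pattern: %s | baseline %.1f ms | %d islands\n",
              nrow(x$values), ncol(x$values), x$pattern, x$baseline_apd_ms,
              nrow(x$centers)))
  invisible(x)
}

# jittered regular lattice covering the grid
place_lattice <- function(n, H, W, jitter_frac) {
  k1 <- max(1L, floor(sqrt(n * H / W)))
  k2 <- ceiling(n / k1)
  while (k1 * k2 < n) k2 <- k2 + 1L
  ch <- H / k1; cw <- W / k2
  cells <- expand.grid(i = seq_len(k1), j = seq_len(k2))
  cells <- cells[seq_len(n), , drop = FALSE]
  rr <- (cells$i - 0.5) * ch + stats::runif(n, -jitter_frac * ch / 2,
                                            jitter_frac * ch / 2)
  cc <- (cells$j - 0.5) * cw + stats::runif(n, -jitter_frac * cw / 2,
                                            jitter_frac * cw / 2)
  cbind(pmin(pmax(rr, 1), H), pmin(pmax(cc, 1), W))
}

# Matern cluster process with fixed total offspring count
place_matern <- function(n, H, W, cluster_radius, n_parents, edge_bias) {
  m <- max(1L, as.integer(n_parents))
  margin <- cluster_radius
  if (edge_bias) {
    # parents drawn near the border band
    band <- max(3, 0.15 * min(H, W))
    side <- sample.int(4L, m, replace = TRUE)
    pr <- pc <- numeric(m)
    for (i in seq_len(m)) {
      if (side[i] == 1L) { pr[i] <- stats::runif(1, 1, band); pc[i] <- stats::runif(1, 1, W) }
      else if (side[i] == 2L) { pr[i] <- stats::runif(1, H - band, H); pc[i] <- stats::runif(1, 1, W) }
      else if (side[i] == 3L) { pc[i] <- stats::runif(1, 1, band); pr[i] <- stats::runif(1, 1, H) }
      else { pc[i] <- stats::runif(1, W - band, W); pr[i] <- stats::runif(1, 1, H) }
    }
  } else {
    pr <- stats::runif(m, 1 + margin, H - margin)
    pc <- stats::runif(m, 1 + margin, W - margin)
  }
  parent <- sample.int(m, n, replace = TRUE)
  ang <- stats::runif(n, 0, 2 * pi)
  rad <- cluster_radius * sqrt(stats::runif(n))
  rr <- pr[parent] + rad * sin(ang)
  cc <- pc[parent] + rad * cos(ang)
  cbind(pmin(pmax(rr, 1), H), pmin(pmax(cc, 1), W))
}

# ellipse with random orientation and mild eccentricity, area ~ pi r^2
rasterize_ovoid <- function(r0, c0, mean_radius, H, W) {
  ecc <- stats::runif(1, 1, 1.8)
  theta <- stats::runif(1, 0, pi)
  rr <- mean_radius * stats::rnorm(1, 1, 0.15)
  rr <- max(1.5, rr)
  a <- rr * sqrt(ecc); b <- rr / sqrt(ecc)
  ext <- ceiling(a) + 1L
  ri <- max(1L, floor(r0 - ext)):min(H, ceiling(r0 + ext))
  ci <- max(1L, floor(c0 - ext)):min(W, ceiling(c0 + ext))
  dg <- expand.grid(row = ri, col = ci)
  dr <- dg$row - r0; dc <- dg$col - c0
  u <- (dc * cos(theta) + dr * sin(theta)) / a
  v <- (-dc * sin(theta) + dr * cos(theta)) / b
  keep <- u^2 + v^2 <= 1
  cbind(dg$row[keep], dg$col[keep])
}

# dilated self-avoiding random walk
rasterize_serpiginous <- function(r0, c0, mean_radius, H, W) {
  len <- max(6L, round(4 * mean_radius))
  thick <- max(1L, round(mean_radius / 3))
  path <- matrix(c(round(r0), round(c0)), ncol = 2L)
  visited <- new.env(hash = TRUE)
  assign(paste(path[1, ], collapse = ","), TRUE, envir = visited)
  steps <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  cur <- path[1L, ]
  for (s in seq_len(len)) {
    cand <- sweep(steps, 2L, cur, `+`)
    ok <- cand[, 1L] >= 1 & cand[, 1L] <= H & cand[, 2L] >= 1 & cand[, 2L] <= W
    keys <- paste(cand[, 1L], cand[, 2L], sep = ",")
    ok <- ok & !vapply(keys, exists, logical(1), envir = visited)
    if (!any(ok)) break
    pick <- which(ok)[sample.int(sum(ok), 1L)]
    cur <- cand[pick, ]
    assign(keys[pick], TRUE, envir = visited)
    path <- rbind(path, cur)
  }
  # dilate the walk by `thick`
  out <- matrix(integer(0), ncol = 2L)
  for (k in seq_len(nrow(path))) {
    ri <- max(1L, path[k, 1L] - thick):min(H, path[k, 1L] + thick)
    ci <- max(1L, path[k, 2L] - thick):min(W, path[k, 2L] + thick)
    dg <- expand.grid(row = ri, col = ci)
    d2 <- (dg$row - path[k, 1L])^2 + (dg$col - path[k, 2L])^2
    out <- rbind(out, cbind(dg$row[d2 <= thick^2], dg$col[d2 <= thick^2]))
  }
  unique(out)
}

#' Brute-force windowed dispersion (reference oracle)
#'
#' Direct per-pixel double loop computing the windowed population standard
#' deviation (or max - min range) of a 2D field. Serves as the independent
#' reference against which the production sliding-window implementation is
#' validated, and as the generator's own oracle for the true supra-threshold
#' area fraction. Same windowing convention as [dispersion_map()]: centred
#' window (even widths extend one extra pixel bottom/right), pixels with
#' < 50% valid in-window neighbours invalid.
#'
#' @param values numeric H x W matrix
#' @param valid logical H x W matrix (default all valid)
#' @param window_px window width in pixels
#' @param statistic `"std"` or `"max_minus_min"`
#' @return list with `values` (H x W matrix), `valid` (logical matrix)
#' @export
brute_force_dispersion <- function(values, valid = NULL, window_px = 10L,
                                   statistic = c("std", "max_minus_min")) {
  statistic <- match.arg(statistic)
  H <- nrow(values); W <- ncol(values)
  if (is.null(valid)) valid <- matrix(TRUE, H, W)
  off <- window_offsets(window_px)
  need <- 0.5 * window_px^2
  out <- matrix(NA_real_, H, W)
  ok <- matrix(FALSE, H, W)
  for (i in seq_len(H)) {
    ri <- i + off
    ri <- ri[ri >= 1 & ri <= H]
    for (j in seq_len(W)) {
      if (!valid[i, j]) next
      ci <- j + off
      ci <- ci[ci >= 1 & ci <= W]
      vwin <- values[ri, ci]
      mwin <- valid[ri, ci]
      vals <- vwin[mwin]
      if (length(vals) < need) next
      out[i, j] <- if (statistic == "std") {
        mu <- mean(vals)
        sqrt(mean((vals - mu)^2))
      } else {
        max(vals) - min(vals)
      }
      ok[i, j] <- TRUE
    }
  }
  list(values = out, valid = ok)
}

#' True supra-threshold area fraction of an APD field
#'
#' The generator's oracle: applies [brute_force_dispersion()] to the true
#' field and reports the percentage of computable tissue with dispersion
#' above threshold.
#'
#' @param field an `apd_field` or numeric matrix
#' @param mask logical tissue mask (default all tissue)
#' @param window_px dispersion window width (default 10)
#' @param threshold_ms binarization threshold, strict `>` (default 10)
#' @param statistic `"std"` or `"max_minus_min"`
#' @return percentage in `[0, 100]`
#' @export
true_area_fraction <- function(field, mask = NULL, window_px = 10L,
                               threshold_ms = 10,
                               statistic = "std") {
  values <- if (inherits(field, "apd_field")) field$values else field
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  ref <- brute_force_dispersion(values, mask, window_px, statistic)
  denom <- sum(ref$valid & mask)
  if (denom == 0) stop("no computable pixels", call. = FALSE)
  100 * sum(ref$values > threshold_ms & ref$valid & mask, na.rm = TRUE) / denom
}

#' Tune a clustered field toward a target supra-threshold fraction
#'
#' Increases the island count of a clustered field until the oracle
#' supra-threshold area fraction reaches `target_pct`, returning the field
#' whose oracle fraction is closest to the target. Deterministic given
#' `seed`.
#'
#' @param target_pct target supra-threshold area percentage
#' @param grid,baseline_apd_ms,island_params,seed,... forwarded to
#'   [generate_apd_field()]
#' @param window_px,threshold_ms oracle dispersion settings
#' @return an `apd_field` with attribute `oracle_fraction_pct`
#' @export
field_with_target_fraction <- function(target_pct, grid = c(100L, 100L),
                                       baseline_apd_ms = 50,
                                       island_params = list(count = 5,
                                                            mean_radius_px = 6,
                                                            elevation_ms = 25,
                                                            shape = "ovoid"),
                                       window_px = 10L, threshold_ms = 10,
                                       seed = 1L, ...) {
  best <- NULL
  best_gap <- Inf
  count <- island_params$count %||% 5L
  for (it in seq_len(40L)) {
    island_params$count <- count
    f <- generate_apd_field("clustered", grid, baseline_apd_ms,
                            island_params, seed = seed, ...)
    frac <- true_area_fraction(f, window_px = window_px,
                               threshold_ms = threshold_ms)
    if (abs(frac - target_pct) < best_gap) {
      best <- f
      best_gap <- abs(frac - target_pct)
      attr(best, "oracle_fraction_pct") <- frac
    }
    if (frac >= target_pct) break
    count <- count + max(1L, ceiling(count * 0.3))
  }
  best
}
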