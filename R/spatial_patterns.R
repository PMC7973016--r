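# Point-pattern statistics operationalizing the uniform / random / clustered
# taxonomy of APD-dispersion arrangements.

#' Quadrat variance-to-mean ratio (index of dispersion)
#'
#' Partitions the region into `quadrat_size_px` square quadrats (anchored
#' top-left; quadrats with < 50% of their area inside the region are
#' dropped), counts points per quadrat, and reports the variance-to-mean
#' ratio of the counts with the chi-square index-of-dispersion test
#' (`chi2 = VMR * (n_quadrats - 1)`, sample variance; two-sided p). Under
#' complete spatial randomness VMR is about 1; VMR > 1 indicates clumping,
#' VMR < 1 regularity. Fewer than 5 points is an indeterminate signal (NA
#' statistics), not an error.
#'
#' @param points two-column matrix or data frame of `(row, col)` positions
#' @param region logical mask matrix, or `c(H, W)` for a full rectangle
#' @param quadrat_size_px quadrat side length in pixels
#' @return one-row tibble: `vmr`, `chi2`, `p`, `n_quadrats`, `n_points`
#' @export
quadrat_vmr <- function(points, region, quadrat_size_px = 20L) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  reg <- region_mask(region)
  H <- nrow(reg); W <- ncol(reg)
  q <- as.integer(quadrat_size_px)
  nqr <- ceiling(H / q); nqc <- ceiling(W / q)
  counts <- c()
  for (qi in seq_len(nqr)) {
    for (qj in seq_len(nqc)) {
      r0 <- (qi - 1L) * q + 1L; r1 <- min(H, qi * q)
      c0 <- (qj - 1L) * q + 1L; c1 <- min(W, qj * q)
      inside <- sum(reg[r0:r1, c0:c1])
      if (inside < 0.5 * q^2) next  # partial quadrat dropped
      n_in <- sum(pts[, 1L] >= r0 - 0.5 & pts[, 1L] < r1 + 0.5 &
                    pts[, 2L] >= c0 - 0.5 & pts[, 2L] < c1 + 0.5)
      counts <- c(counts, n_in)
    }
  }
  if (length(counts) < 2L) {
    stop("fewer than 2 usable quadrats; enlarge region or shrink quadrats",
         call. = FALSE)
  }
  if (nrow(pts) < 5L) {
    return(tibble::tibble(vmr = NA_real_, chi2 = NA_real_, p = NA_real_,
                          n_quadrats = length(counts),
                          n_points = nrow(pts)))
  }
  nq <- length(counts)
  vmr <- stats::var(counts) / mean(counts)
  chi2 <- vmr * (nq - 1)
  p_up <- stats::pchisq(chi2, df = nq - 1, lower.tail = FALSE)
  p_lo <- stats::pchisq(chi2, df = nq - 1)
  p <- min(1, 2 * min(p_up, p_lo))
  tibble::tibble(vmr = vmr, chi2 = chi2, p = p, n_quadrats = nq,
                 n_points = nrow(pts))
}

#' Clark-Evans nearest-neighbour index
#'
#' Ratio of the observed mean nearest-neighbour distance to the expectation
#' `0.5 / sqrt(density)` under complete spatial randomness. R < 1 signals
#' clustering, R > 1 regularity (R -> 2 for a perfect square lattice). The
#' z statistic uses the standard normal approximation
#' (`se = 0.26136 / sqrt(n * density)`). The `"guard"` edge correction
#' averages nearest-neighbour distances only over focal points at least a
#' guard margin (default: the CSR-expected distance) inside the region
#' bounding box, while all points remain candidate neighbours.
#'
#' @param points two-column matrix or data frame of `(row, col)` positions
#'   (n >= 5; coincident points allowed)
#' @param area region area in the same squared units (e.g. pixel count of
#'   the tissue mask)
#' @param edge_correction `"none"` or `"guard"`
#' @param bbox region bounding box `c(rmin, rmax, cmin, cmax)` for the guard
#'   correction; defaults to the point cloud's bounding box
#' @param guard_width guard margin; default `0.5 / sqrt(n / area)`
#' @return one-row tibble: `r`, `z`, `n`, `n_focal`, `mean_nn_dist`
#' @export
clark_evans <- function(points, area, edge_correction = c("none", "guard"),
                        bbox = NULL, guard_width = NULL) {
  edge_correction <- match.arg(edge_correction)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 5L) {
    return(tibble::tibble(r = NA_real_, z = NA_real_, n = n,
                          n_focal = 0L, mean_nn_dist = NA_real_))
  }
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  nnd <- apply(dm, 1L, min)
  lambda <- n / area
  r_exp <- 0.5 / sqrt(lambda)
  focal <- rep(TRUE, n)
  if (edge_correction == "guard") {
    bb <- bbox %||% c(min(pts[, 1L]), max(pts[, 1L]),
                      min(pts[, 2L]), max(pts[, 2L]))
    g <- guard_width %||% r_exp
    focal <- pts[, 1L] >= bb[1L] + g & pts[, 1L] <= bb[2L] - g &
      pts[, 2L] >= bb[3L] + g & pts[, 2L] <= bb[4L] - g
    if (sum(focal) < 5L) focal <- rep(TRUE, n)  # guard ate the sample
  }
  r_obs <- mean(nnd[focal])
  se <- 0.26136 / sqrt(sum(focal) * lambda)
  tibble::tibble(r = r_obs / r_exp, z = (r_obs - r_exp) / se, n = n,
                 n_focal = sum(focal), mean_nn_dist = r_obs)
}

#' Moran's I spatial autocorrelation on a gridded map
#'
#' Global Moran's I over the valid pixels of a (dispersion) map with binary
#' contiguity weights: `"rook"` (4-neighbour) or `"queen"` (8-neighbour).
#' +1 for smooth block structure, about `-1/(n-1)` for spatially independent
#' noise, -1 for a perfect rook checkerboard. A zero-variance map has no
#' defined autocorrelation and returns NA.
#'
#' @param dmap a [dispersion_map()] or numeric matrix
#' @param weights `"rook"` or `"queen"` contiguity
#' @param valid optional validity matrix for plain-matrix input
#' @return Moran's I (scalar, NA when undefined)
#' @export
morans_i <- function(dmap, weights = c("rook", "queen"), valid = NULL) {
  weights <- match.arg(weights)
  x <- if (inherits(dmap, "dispersion_map")) dmap$values else dmap
  vin <- if (inherits(dmap, "dispersion_map")) dmap$valid else
    (valid %||% is.finite(x))
  n <- sum(vin)
  if (n < 9L) stop("Moran's I needs >= 9 valid pixels", call. = FALSE)
  xv <- x[vin]
  if (stats::var(xv) == 0) return(NA_real_)
  z <- matrix(0, nrow(x), ncol(x))
  z[vin] <- xv - mean(xv)
  vnum <- vin * 1
  shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (weights == "queen") {
    shifts <- c(shifts, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }
  num <- 0
  wtot <- 0
  H <- nrow(x); W <- ncol(x)
  for (s in shifts) {
    dr <- s[1L]; dc <- s[2L]
    ri <- max(1L, 1L - dr):min(H, H - dr)
    ci <- max(1L, 1L - dc):min(W, W - dc)
    num <- num + sum(z[ri, ci] * z[ri + dr, ci + dc])
    wtot <- wtot + sum(vnum[ri, ci] * vnum[ri + dr, ci + dc])
  }
  (n / wtot) * num / sum(z[vin]^2)
}

#' Classify a dispersion arrangement as uniform, random or clustered
#'
#' Rule-based operationalization of the three theoretical dispersion
#' patterns, applied to island centroids (point-process view), with Moran's
#' I on the continuous dispersion map as a recorded covariate:
#'
#' * **clustered** - the quadrat index-of-dispersion rejects toward VMR > 1
#'   at `alpha` and the Clark-Evans index R < 1;
#' * **uniform** - the test rejects toward VMR < 1 and R > 1;
#' * **random** - neither direction rejected;
#' * **indeterminate** - conflicting signals, or fewer than 5 islands.
#'
#' The directional rejections use the one-sided chi-square tails at
#' `alpha` each (the reported p-value stays two-sided), so under complete
#' spatial randomness the random label is produced with probability about
#' `1 - 2 * alpha`.
#'
#' @param centroids two-column matrix/data frame of island centroids
#'   `(row, col)`, e.g. from [extract_islands()]
#' @param region logical mask matrix or `c(H, W)` rectangle
#' @param quadrat_size_px quadrat side; default 20 px (twice the dispersion
#'   window, so quadrats exceed island scale)
#' @param alpha significance level per one-sided test (default 0.05)
#' @param dmap optional [dispersion_map()] for Moran's I
#' @param weights contiguity for Moran's I
#' @param edge_correction Clark-Evans edge handling
#' @return object of class `pattern_report`
#' @export
classify_pattern <- function(centroids, region, quadrat_size_px = 20L,
                             alpha = 0.05, dmap = NULL,
                             weights = "rook",
                             edge_correction = "guard") {
  pts <- as.matrix(centroids)[, 1:2, drop = FALSE]
  reg <- region_mask(region)
  n <- nrow(pts)
  qv <- quadrat_vmr(pts, reg, quadrat_size_px)
  area <- sum(reg)
  bb <- c(1, nrow(reg), 1, ncol(reg))
  ce <- clark_evans(pts, area, edge_correction = edge_correction, bbox = bb)
  mi <- if (!is.null(dmap)) morans_i(dmap, weights = weights) else NA_real_

  if (n < 5L || !is.finite(qv$vmr)) {
    label <- "indeterminate"
    sig_cl <- sig_un <- NA
  } else {
    p_up <- stats::pchisq(qv$chi2, df = qv$n_quadrats - 1,
                          lower.tail = FALSE)
    p_lo <- stats::pchisq(qv$chi2, df = qv$n_quadrats - 1)
    sig_cl <- p_up < alpha
    sig_un <- p_lo < alpha
    label <- if (sig_cl && is.finite(ce$r) && ce$r < 1) "clustered"
    else if (sig_un && is.finite(ce$r) && ce$r > 1) "uniform"
    else if (!sig_cl && !sig_un) "random"
    else "indeterminate"
  }
  structure(
    list(vmr = qv$vmr, vmr_p = qv$p, vmr_chi2 = qv$chi2,
         n_quadrats = qv$n_quadrats,
         clark_evans_r = ce$r, ce_z = ce$z,
         morans_i = mi,
         label = label, n_islands = n,
         quadrat_size_px = as.integer(quadrat_size_px),
         alpha = alpha),
    class = "pattern_report")
}

#' @export
print.pattern_report <- function(x, ...) {
  cat(sprintf("<pattern_report> label: %s (n = %d islands)\n",
              x$label, x$n_islands))
  cat(sprintf("  VMR %.3f (p = %.3g, %d quadrats of %d px)\n",
              x$vmr, x$vmr_p, x$n_quadrats, x$quadrat_size_px))
  cat(sprintf("  Clark-Evans R %.3f (z = %.2f) | Moran's I %.3f\n",
              x$clark_evans_r, x$ce_z, x$morans_i))
  invisible(x)
}

region_mask <- function(region) {
  if (is.matrix(region)) {
    matrix(as.logical(region), nrow(region), ncol(region))
  } else {
    matrix(TRUE, region[1L], region[2L])
  }
}
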