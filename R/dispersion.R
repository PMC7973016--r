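#' Windowed APD dispersion map
#'
#' Spatial dispersion of repolarization, defined as the standard deviation
#' of APD across neighbouring pixels: a centred `window_px` x `window_px`
#' sliding window (stride 1) computes the population standard deviation of
#' the valid in-window APDs at every pixel. Even window widths carry the
#' extra row/column on the bottom/right. Pixels whose window holds fewer
#' than 50% valid neighbours are invalid, which keeps tissue-edge curvature
#' from inflating border dispersion. `statistic = "max_minus_min"` computes
#' the high-APD-gradient variant instead: the largest difference between a
#' long and a short APD within the window.
#'
#' @param apd an `apd_map` from [compute_apd_map()], or a numeric matrix
#' @param window_px window width in pixels (default 10, the conventional
#'   neighbourhood)
#' @param statistic `"std"` (population std) or `"max_minus_min"` (range)
#' @param valid optional validity matrix when `apd` is a plain matrix
#' @return object of class `dispersion_map`: `values` (ms), `window_px`,
#'   `statistic`, `valid`
#' @export
dispersion_map <- function(apd, window_px = 10L,
                           statistic = c("std", "max_minus_min"),
                           valid = NULL) {
  statistic <- match.arg(statistic)
  values <- if (inherits(apd, "apd_map")) apd$values else apd
  vin <- if (inherits(apd, "apd_map")) apd$valid else
    (valid %||% is.finite(values))
  H <- nrow(values); W <- ncol(values)
  w <- as.integer(window_px)
  if (w < 2L) stop("window_px must be >= 2", call. = FALSE)
  if (w > min(H, W)) stop("window larger than the map", call. = FALSE)

  need <- 0.5 * w^2
  vnum <- vin * 1
  n_in <- shift_window_sum(vnum, w)
  out_valid <- vin & n_in >= need

  if (statistic == "std") {
    # centre on the global mean first: keeps the accumulated sums small
    g <- mean(values[vin])
    vc <- values - g
    vc[!vin] <- 0
    s1 <- shift_window_sum(vc, w)
    s2 <- shift_window_sum(vc * vc, w)
    mu <- s1 / n_in
    varr <- pmax(s2 / n_in - mu^2, 0)
    out <- sqrt(varr)
  } else {
    hi <- matrix(-Inf, H, W)
    lo <- matrix(Inf, H, W)
    vhi <- values; vhi[!vin] <- -Inf
    vlo <- values; vlo[!vin] <- Inf
    for (dr in window_offsets(w)) {
      ri <- max(1L, 1L - dr):min(H, H - dr)
      for (dc in window_offsets(w)) {
        ci <- max(1L, 1L - dc):min(W, W - dc)
        hi[ri, ci] <- pmax(hi[ri, ci], vhi[ri + dr, ci + dc])
        lo[ri, ci] <- pmin(lo[ri, ci], vlo[ri + dr, ci + dc])
      }
    }
    out <- hi - lo
  }
  out[!out_valid] <- NA_real_
  structure(list(values = out, window_px = w, statistic = statistic,
                 valid = out_valid),
            class = "dispersion_map")
}

#' High-APD-gradient map
#'
#' Convenience wrapper: per-pixel (max - min) of valid APDs in the centred
#' window, the definition of a high APD gradient region. Identical masking
#' rules to [dispersion_map()].
#'
#' @inheritParams dispersion_map
#' @return a `dispersion_map` with `statistic = "max_minus_min"`
#' @export
gradient_map <- function(apd, window_px = 10L, valid = NULL) {
  dispersion_map(apd, window_px, statistic = "max_minus_min", valid = valid)
}

#' @export
print.dispersion_map <- function(x, ...) {
  cat(sprintf("<dispersion_map> %d x %d px | %s | window %d px | valid %d px\n",
              nrow(x$values), ncol(x$values), x$statistic, x$window_px,
              sum(x$valid)))
  invisible(x)
}

#' Binarize a dispersion map at a threshold
#'
#' Strict inequality: a pixel is "above" when its dispersion exceeds the
#' threshold (`values > threshold_ms`); exactly-at-threshold pixels and
#' invalid pixels are below. The 10 ms default is the cut-off above which
#' reentry was most commonly observed.
#'
#' @param dmap a [dispersion_map()]
#' @param threshold_ms threshold in ms (>= 0, default 10)
#' @return object of class `binary_dispersion_map`: `above` (logical),
#'   `threshold_ms`, `source_statistic`, `valid`
#' @export
binarize <- function(dmap, threshold_ms = 10) {
  stopifnot(inherits(dmap, "dispersion_map"), threshold_ms >= 0)
  above <- dmap$values > threshold_ms & dmap$valid
  above[is.na(above)] <- FALSE
  structure(list(above = above, threshold_ms = threshold_ms,
                 source_statistic = dmap$statistic, valid = dmap$valid),
            class = "binary_dispersion_map")
}

#' @export
print.binary_dispersion_map <- function(x, ...) {
  cat(sprintf(
    "<binary_dispersion_map> %d x %d px | > %.1f ms (%s) | above: %d px\n",
    nrow(x$above), ncol(x$above), x$threshold_ms, x$source_statistic,
    sum(x$above)))
  invisible(x)
}

#' Supra-threshold area fraction
#'
#' Percentage of mapped tissue exhibiting dispersion above threshold: the
#' yellow-to-total ratio of a binarized dispersion map, with the denominator
#' restricted to pixels where dispersion was computable.
#'
#' @param bmap a [binarize()]d dispersion map
#' @param mask optional tissue mask; intersected with the computable region
#' @return percent in `[0, 100]`
#' @export
area_fraction <- function(bmap, mask = NULL) {
  stopifnot(inherits(bmap, "binary_dispersion_map"))
  denom_mask <- bmap$valid
  if (!is.null(mask)) denom_mask <- denom_mask & mask
  denom <- sum(denom_mask)
  if (denom == 0) stop("empty mask: no computable pixels", call. = FALSE)
  100 * sum(bmap$above & denom_mask) / denom
}

#' Extract dispersion islands (connected components)
#'
#' 8-connected components of the supra-threshold region with per-island
#' morphometry: pixel count, physical area, centroid, elongation
#' (major/minor axis ratio of the second-moment ellipse), solidity
#' (area / convex hull area), and a shape label - `"serpiginous"` when the
#' island is strongly elongated (> 3) or poorly filled (solidity < 0.6),
#' `"ovoid"` otherwise. The shape cut-offs are package conventions for the
#' qualitative shape vocabulary.
#'
#' @param bmap a [binarize()]d dispersion map (or logical matrix)
#' @param pixel_pitch_mm pixel size in mm
#' @return a tibble of class `island_set`, one row per island: `id`,
#'   `n_px`, `area_mm2`, `centroid_row`, `centroid_col`, `elongation`,
#'   `solidity`, `shape_label`
#' @export
extract_islands <- function(bmap, pixel_pitch_mm = 0.095) {
  above <- if (inherits(bmap, "binary_dispersion_map")) bmap$above else bmap
  lab <- label_components_8(above)
  k <- max(lab)
  rows <- row(lab)[lab > 0L]
  cols <- col(lab)[lab > 0L]
  ids <- lab[lab > 0L]
  out <- vector("list", k)
  for (i in seq_len(k)) {
    rr <- rows[ids == i]
    cc <- cols[ids == i]
    n_px <- length(rr)
    # second-moment ellipse; 1/12 is the variance of a unit pixel
    vr <- mean((rr - mean(rr))^2) + 1 / 12
    vc <- mean((cc - mean(cc))^2) + 1 / 12
    vrc <- mean((rr - mean(rr)) * (cc - mean(cc)))
    ev <- eigen(matrix(c(vr, vrc, vrc, vc), 2L), symmetric = TRUE)$values
    elong <- sqrt(max(ev) / max(min(ev), 1e-12))
    sol <- island_solidity(rr, cc)
    out[[i]] <- tibble::tibble(
      id = i, n_px = n_px,
      area_mm2 = n_px * pixel_pitch_mm^2,
      centroid_row = mean(rr), centroid_col = mean(cc),
      elongation = elong, solidity = sol,
      shape_label = if (elong > 3 || sol < 0.6) "serpiginous" else "ovoid")
  }
  res <- if (k == 0L) {
    tibble::tibble(id = integer(), n_px = integer(), area_mm2 = numeric(),
                   centroid_row = numeric(), centroid_col = numeric(),
                   elongation = numeric(), solidity = numeric(),
                   shape_label = character())
  } else {
    dplyr::bind_rows(out)
  }
  class(res) <- c("island_set", class(res))
  attr(res, "pixel_pitch_mm") <- pixel_pitch_mm
  res
}

# solidity from the convex hull of the pixel squares (each pixel contributes
# its 4 corners so single pixels and thin lines stay well-defined)
island_solidity <- function(rr, cc) {
  pts <- cbind(c(rr - 0.5, rr - 0.5, rr + 0.5, rr + 0.5),
               c(cc - 0.5, cc + 0.5, cc - 0.5, cc + 0.5))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  if (m < 3L) return(1)
  # shoelace
  a <- abs(sum(hp[, 1L] * hp[c(2:m, 1L), 2L] -
                 hp[c(2:m, 1L), 1L] * hp[, 2L])) / 2
  min(1, length(rr) / max(a, length(rr) * 1e-12))
}

#' Per-group summary with a one-sample t-test
#'
#' Mean +/- SEM of per-subject percentages and a two-sided one-sample
#' t-test against a reference value, the group-statistics convention for
#' supra-threshold area fractions. A zero-variance sample is degenerate:
#' the p-value is reported as 1 (t = 0) when the mean equals the null and 0
#' otherwise, with a warning.
#'
#' @param values numeric vector of per-subject values (n >= 2)
#' @param null_value reference value for the t-test (default 0)
#' @param alpha significance level for the `significant` flag
#' @return one-row tibble: `n`, `mean`, `sem`, `t`, `df`, `p`, `significant`
#' @export
group_stats <- function(values, null_value = 0, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("group_stats needs n >= 2 values", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  sem <- s / sqrt(n)
  if (s == 0) {
    warning("zero variance: degenerate one-sample t-test", call. = FALSE)
    tt <- if (m == null_value) 0 else sign(m - null_value) * Inf
    p <- if (m == null_value) 1 else 0
  } else {
    tt <- (m - null_value) / sem
    p <- 2 * stats::pt(-abs(tt), df = n - 1)
  }
  tibble::tibble(n = n, mean = m, sem = sem, t = tt, df = n - 1L, p = p,
                 significant = p < alpha)
}
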