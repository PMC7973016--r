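#' Acquisition metadata for an optical-mapping movie
#'
#' Captures the camera parameters of a voltage-dye acquisition. Defaults mirror
#' a MiCAM-style CMOS acquisition: 1,000 frames/s, 100 x 100 pixels at
#' 0.095 mm per pixel.
#'
#' @param frame_rate_hz sampling rate in frames per second (> 0)
#' @param pixel_pitch_mm physical pixel size in mm (> 0)
#' @param n_frames,height,width movie dimensions (positive integers)
#' @param subject_label free-text subject identifier
#' @param chamber one of `"atrium"`, `"ventricle"`, `"unknown"`
#' @return an object of class `acquisition_meta`
#' @export
acquisition_meta <- function(frame_rate_hz = 1000, pixel_pitch_mm = 0.095,
                             n_frames = 1000L, height = 100L, width = 100L,
                             subject_label = "unlabelled",
                             chamber = c("unknown", "atrium", "ventricle")) {
  chamber <- match.arg(chamber)
  stopifnot(frame_rate_hz > 0, pixel_pitch_mm > 0,
            n_frames >= 1, height >= 1, width >= 1)
  structure(
    list(frame_rate_hz = as.numeric(frame_rate_hz),
         pixel_pitch_mm = as.numeric(pixel_pitch_mm),
         n_frames = as.integer(n_frames),
         height = as.integer(height),
         width = as.integer(width),
         subject_label = as.character(subject_label),
         chamber = chamber),
    class = "acquisition_meta"
  )
}

#' Voltage-fluorescence movie container
#'
#' A calibrated 3D fluorescence recording indexed `[frame, row, col]` with
#' acquisition metadata and a tissue mask. Coordinates are row-major,
#' origin top-left; rows index down, columns index right.
#'
#' @param data numeric array `[frame, row, col]` with finite values
#' @param meta an [acquisition_meta()] object (dimensions are reconciled)
#' @param mask logical matrix `[row, col]`, `TRUE` = tissue; defaults to
#'   all-tissue
#' @return an object of class `voltage_movie`
#' @export
voltage_movie <- function(data, meta = acquisition_meta(), mask = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(!is.finite(data))) {
    stop("voltage movie contains non-finite values", call. = FALSE)
  }
  d <- dim(data)
  meta$n_frames <- d[1L]
  meta$height <- d[2L]
  meta$width <- d[3L]
  if (is.null(mask)) {
    mask <- matrix(TRUE, d[2L], d[3L])
  }
  mask <- matrix(as.logical(mask), d[2L], d[3L])
  if (!identical(dim(mask), d[2:3])) {
    stop("mask shape does not match frame shape", call. = FALSE)
  }
  if (!any(mask)) stop("mask has no tissue pixels", call. = FALSE)
  structure(list(data = data, meta = meta, mask = mask),
            class = "voltage_movie")
}

#' @export
print.voltage_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voltage_movie> %d frames x %d x %d px | %.0f f/s | %.3f mm/px | %s (%s)\n",
    d[1], d[2], d[3], x$meta$frame_rate_hz, x$meta$pixel_pitch_mm,
    x$meta$subject_label, x$meta$chamber))
  cat(sprintf("  tissue pixels: %d / %d\n", sum(x$mask), d[2] * d[3]))
  invisible(x)
}

#' Read an optical-mapping movie from disk
#'
#' Two on-disk layouts are supported:
#' * `"tiff_stack"`: a multi-page TIFF, one page per frame, with a YAML
#'   sidecar (`<path>.yml` or passed via `sidecar`) declaring at least
#'   `frame_rate_hz` and `pixel_pitch_mm`.
#' * `"raw_binary"`: a headerless binary dump of the `[frame, row, col]`
#'   array plus a YAML sidecar declaring `dtype` (`float64`, `float32` or
#'   `uint16`), `n_frames`, `height`, `width`, `frame_rate_hz`,
#'   `pixel_pitch_mm`, and optionally `byte_order`, `subject_label`,
#'   `chamber`, `mask_path`.
#'
#' A mask referenced by `mask_path` may be a PNG (binarized at > 0) or a CSV
#' of 0/1. The declared frame count must match the data on disk; a mismatch
#' is an error, never a silent truncation.
#'
#' @param path path to the movie file
#' @param format `"tiff_stack"` or `"raw_binary"`
#' @param sidecar path to the YAML sidecar; defaults to `<path>.yml`
#' @return a [voltage_movie()]
#' @export
read_movie <- function(path, format = c("tiff_stack", "raw_binary"),
                       sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("movie file not found: ", path, call. = FALSE)
  sidecar <- sidecar %||% paste0(path, ".yml")
  hdr <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()

  if (format == "tiff_stack") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    nf <- length(pages)
    H <- nrow(pages[[1L]])
    W <- ncol(pages[[1L]])
    data <- array(0, c(nf, H, W))
    for (k in seq_len(nf)) data[k, , ] <- pages[[k]]
    if (!is.null(hdr$n_frames) && as.integer(hdr$n_frames) != nf) {
      stop(sprintf("sidecar declares %d frames but TIFF holds %d",
                   as.integer(hdr$n_frames), nf), call. = FALSE)
    }
  } else {
    dtype <- hdr$dtype %||% stop("raw_binary requires a sidecar with dtype/shape",
                                 call. = FALSE)
    nf <- as.integer(hdr$n_frames)
    H <- as.integer(hdr$height)
    W <- as.integer(hdr$width)
    if (any(is.na(c(nf, H, W)))) {
      stop("raw_binary sidecar must declare n_frames, height, width",
           call. = FALSE)
    }
    sz <- switch(dtype, float64 = 8L, float32 = 4L, uint16 = 2L,
                 stop("unsupported dtype: ", dtype, call. = FALSE))
    endian <- hdr$byte_order %||% "little"
    n_expect <- nf * H * W
    bytes_on_disk <- file.size(path)
    if (bytes_on_disk != n_expect * sz) {
      stop(sprintf(
        "raw file holds %d bytes but header implies %d (%d x %d x %d x %d)",
        bytes_on_disk, n_expect * sz, nf, H, W, sz), call. = FALSE)
    }
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- switch(dtype,
      float64 = readBin(con, "double", n = n_expect, size = 8L, endian = endian),
      float32 = readBin(con, "double", n = n_expect, size = 4L, endian = endian),
      uint16 = readBin(con, "integer", n = n_expect, size = 2L,
                       signed = FALSE, endian = endian))
    # stored frame-major: frame slices of row-major [row, col] planes
    data <- aperm(array(as.numeric(vals), c(W, H, nf)), c(3L, 2L, 1L))
  }

  meta <- acquisition_meta(
    frame_rate_hz = as.numeric(hdr$frame_rate_hz %||% 1000),
    pixel_pitch_mm = as.numeric(hdr$pixel_pitch_mm %||% 0.095),
    n_frames = dim(data)[1L], height = dim(data)[2L], width = dim(data)[3L],
    subject_label = hdr$subject_label %||% "unlabelled",
    chamber = hdr$chamber %||% "unknown")

  mask <- NULL
  if (!is.null(hdr$mask_path)) {
    mp <- hdr$mask_path
    if (!file.exists(mp)) mp <- file.path(dirname(path), hdr$mask_path)
    mask <- read_mask(mp)
  }
  voltage_movie(data, meta, mask)
}

#' Write an optical-mapping movie to disk
#'
#' `raw_binary` (float64) round-trips bit-for-bit; `tiff_stack` stores
#' 32-bit float pages and requires data in `[0, 1]`. A YAML sidecar with
#' the acquisition metadata is written alongside.
#'
#' @param movie a [voltage_movie()]
#' @param path output path
#' @param format `"raw_binary"` or `"tiff_stack"`
#' @return `path`, invisibly
#' @export
write_movie <- function(movie, path, format = c("raw_binary", "tiff_stack")) {
  format <- match.arg(format)
  d <- dim(movie$data)
  hdr <- list(n_frames = d[1L], height = d[2L], width = d[3L],
              frame_rate_hz = movie$meta$frame_rate_hz,
              pixel_pitch_mm = movie$meta$pixel_pitch_mm,
              subject_label = movie$meta$subject_label,
              chamber = movie$meta$chamber)
  if (format == "raw_binary") {
    hdr$dtype <- "float64"
    hdr$byte_order <- "little"
    con <- file(path, "wb")
    writeBin(as.vector(aperm(movie$data, c(3L, 2L, 1L))), con, size = 8L,
             endian = "little")
    close(con)
  } else {
    rng <- range(movie$data)
    if (rng[1L] < 0 || rng[2L] > 1) {
      stop("tiff_stack requires data in [0, 1]; rescale first", call. = FALSE)
    }
    pages <- lapply(seq_len(d[1L]), function(k) movie$data[k, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  yaml::write_yaml(hdr, paste0(path, ".yml"))
  invisible(path)
}

# Mask loader: PNG binarized at > 0, or CSV of 0/1.
read_mask <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img > 0
  } else {
    as.matrix(utils::read.csv(path, header = FALSE)) > 0
  }
}

#' Write a 2D scalar or binary map
#'
#' `csv` and `bin` are lossless (to printed precision for csv, exact for
#' bin); `png` renders with a fixed documented colour scale. Binary maps use
#' the green (below threshold) / yellow (above threshold) convention of
#' binarized dispersion figures; continuous maps a dark-blue-to-yellow ramp.
#' `NA` pixels render as black background.
#'
#' @param map2d numeric or logical matrix (NA = outside mask)
#' @param path output path
#' @param format `"csv"`, `"png"` or `"bin"`
#' @return `path`, invisibly
#' @export
write_map <- function(map2d, path, format = c("csv", "png", "bin")) {
  format <- match.arg(format)
  is_binary <- is.logical(map2d)
  m <- map2d
  if (format == "csv") {
    utils::write.table(m, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (format == "bin") {
    con <- file(path, "wb")
    writeBin(dim(m), con, size = 4L, endian = "little")
    vals <- as.numeric(m)
    writeBin(vals, con, size = 8L, endian = "little")
    close(con)
  } else {
    H <- nrow(m); W <- ncol(m)
    rgb <- array(0, c(H, W, 3L))
    if (is_binary) {
      green <- c(0, 0.8, 0)
      yellow <- c(1, 1, 0)
      for (ch in 1:3) {
        plane <- matrix(green[ch], H, W)
        plane[m] <- yellow[ch]
        rgb[, , ch] <- plane
      }
      na_px <- is.na(m)
    } else {
      rng <- range(m, na.rm = TRUE)
      z <- if (diff(rng) > 0) (m - rng[1L]) / diff(rng) else m * 0
      # dark blue -> yellow ramp
      rgb[, , 1L] <- z
      rgb[, , 2L] <- z
      rgb[, , 3L] <- 0.5 * (1 - z)
      na_px <- is.na(z)
    }
    if (any(na_px)) for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[na_px] <- 0
      rgb[, , ch] <- plane
    }
    png::writePNG(rgb, path)
  }
  invisible(path)
}

#' Read a 2D map written by [write_map()]
#'
#' @param path file path
#' @param format `"csv"` or `"bin"`
#' @return numeric matrix
#' @export
read_map <- function(path, format = c("csv", "bin")) {
  format <- match.arg(format)
  if (format == "csv") {
    as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    d <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
    matrix(readBin(con, "double", n = prod(d), size = 8L, endian = "little"),
           d[1L], d[2L])
  }
}

#' Append per-subject scalar metrics to a tidy CSV
#'
#' One row per metric with a stable column order
#' (`subject_label`, `chamber`, `metric`, `value`). Appending to an existing
#' file preserves the header; a duplicate (subject, chamber, metric)
#' combination is kept and flagged with a message.
#'
#' @param records data frame with columns `subject_label`, `chamber`,
#'   `metric`, `value` (zero rows allowed)
#' @param path output CSV path
#' @param append append to an existing file rather than overwrite
#' @return the tibble written, invisibly
#' @export
write_metrics <- function(records, path, append = FALSE) {
  cols <- c("subject_label", "chamber", "metric", "value")
  records <- tibble::as_tibble(records)
  if (nrow(records) > 0 && !all(cols %in% names(records))) {
    stop("metric records need columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) {
    records <- tibble::tibble(subject_label = character(),
                              chamber = character(),
                              metric = character(), value = numeric())
  }
  records <- records[cols]
  existing <- if (append && file.exists(path)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else NULL
  combined <- if (is.null(existing)) records else
    dplyr::bind_rows(tibble::as_tibble(existing), records)
  dup <- duplicated(combined[c("subject_label", "chamber", "metric")])
  if (any(dup)) {
    message(sum(dup), " duplicate metric row(s) kept: ",
            paste(unique(combined$metric[dup]), collapse = ", "))
  }
  utils::write.csv(combined, path, row.names = FALSE, quote = TRUE)
  invisible(tibble::as_tibble(combined))
}
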