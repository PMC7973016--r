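# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a 2D map into a long tibble
#'
#' @param x an `apd_map`, `dispersion_map`, `binary_dispersion_map` or
#'   `df_map`
#' @param ... unused
#' @return tibble with columns `row`, `col`, `value` (invalid pixels NA)
#' @method tidy apd_map
#' @export
tidy.apd_map <- function(x, ...) {
  map_to_tibble(x$values, x$valid)
}

#' @rdname tidy.apd_map
#' @method tidy dispersion_map
#' @export
tidy.dispersion_map <- function(x, ...) {
  map_to_tibble(x$values, x$valid)
}

#' @rdname tidy.apd_map
#' @method tidy binary_dispersion_map
#' @export
tidy.binary_dispersion_map <- function(x, ...) {
  out <- map_to_tibble(x$above * 1, x$valid)
  dplyr::mutate(out, above = .data$value > 0, value = NULL)
}

#' @rdname tidy.apd_map
#' @method tidy df_map
#' @export
tidy.df_map <- function(x, ...) {
  map_to_tibble(x$freq_hz, x$valid)
}

map_to_tibble <- function(values, valid) {
  H <- nrow(values); W <- ncol(values)
  v <- values
  v[!valid] <- NA
  tibble::tibble(row = rep(seq_len(H), times = W),
                 col = rep(seq_len(W), each = H),
                 value = as.vector(v))
}

#' Tidy a pattern report
#'
#' @param x a `pattern_report` from [classify_pattern()]
#' @param ... unused
#' @return one-row tibble of the recorded statistics and the label
#' @method tidy pattern_report
#' @export
tidy.pattern_report <- function(x, ...) {
  tibble::tibble(
    label = x$label, n_islands = x$n_islands,
    vmr = x$vmr, vmr_p = x$vmr_p, vmr_chi2 = x$vmr_chi2,
    n_quadrats = x$n_quadrats,
    clark_evans_r = x$clark_evans_r, ce_z = x$ce_z,
    morans_i = x$morans_i,
    quadrat_size_px = x$quadrat_size_px, alpha = x$alpha)
}

#' @rdname tidy.pattern_report
#' @method glance pattern_report
#' @export
glance.pattern_report <- function(x, ...) {
  tibble::tibble(label = x$label, n_islands = x$n_islands,
                 vmr = x$vmr, clark_evans_r = x$clark_evans_r,
                 morans_i = x$morans_i)
}

#' Glance at a pipeline result
#'
#' @param x a `pipeline_result` from [run_pipeline()]
#' @param ... unused
#' @return one-row tibble: area fraction, island count, pattern label, APD
#'   summary
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  v <- x$apd_map$values[x$apd_map$valid]
  tibble::tibble(
    area_fraction_pct = x$area_fraction_pct,
    n_islands = nrow(x$islands),
    pattern_label = x$pattern_label,
    mean_apd_ms = mean(v), max_apd_ms = max(v),
    threshold_ms = x$config$threshold_ms)
}

#' Plot a scalar or binary map
#'
#' Continuous maps use a viridis fill; binarized dispersion maps use the
#' green (below) / yellow (above) convention. The y axis is flipped so the
#' origin sits top-left, matching the array convention.
#'
#' @param object a map object
#' @param ... unused
#' @return a ggplot
#' @method autoplot apd_map
#' @export
autoplot.apd_map <- function(object, ...) {
  plot_scalar_map(tidy(object), sprintf("APD%g (ms)", object$level_pct))
}

#' @rdname autoplot.apd_map
#' @method autoplot dispersion_map
#' @export
autoplot.dispersion_map <- function(object, ...) {
  lab <- if (object$statistic == "std") "std(APD) (ms)" else
    "APD range (ms)"
  plot_scalar_map(tidy(object), lab)
}

#' @rdname autoplot.apd_map
#' @method autoplot df_map
#' @export
autoplot.df_map <- function(object, ...) {
  plot_scalar_map(tidy(object), "dominant frequency (Hz)")
}

#' @rdname autoplot.apd_map
#' @method autoplot binary_dispersion_map
#' @export
autoplot.binary_dispersion_map <- function(object, ...) {
  df <- tidy(object)
  df$state <- ifelse(is.na(df$above), "outside",
                     ifelse(df$above, "above", "below"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$state)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(above = "#FFD700",
                                          below = "#228B22",
                                          outside = "grey15"),
                               name = sprintf("> %.0f ms",
                                              object$threshold_ms)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

plot_scalar_map <- function(df, fill_lab) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = fill_lab, na.value = "grey15") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
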