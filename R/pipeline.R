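#' Assemble a validated end-to-end run configuration
#'
#' Collects every stage's settings in one object, validated up front. The
#' defaults mirror a MiCAM-style acquisition (1,000 frames/s, 100 x 100
#' pixels at 0.095 mm/px), 10 Hz pacing, the 10 x 10 px dispersion window
#' and the 10 ms binarization threshold.
#'
#' @param pattern synthetic scenario pattern for [generate_apd_field()]
#' @param grid grid size `c(H, W)`
#' @param baseline_apd_ms baseline APD (ms)
#' @param island_params island parameters, see [generate_apd_field()]
#' @param pacing,wave,noise movie-synthesis settings, see
#'   [synthesize_movie()]
#' @param n_frames movie length in frames
#' @param signal a [signal_config()]
#' @param window_px dispersion window width
#' @param threshold_ms binarization threshold
#' @param statistic `"std"` or `"max_minus_min"`
#' @param quadrat_size_px quadrat size for the pattern classifier
#' @param alpha classifier significance level
#' @param seed integer seed governing every random draw of the run
#' @param subject_label,chamber subject metadata carried into metrics
#' @param out_dir optional output directory; when set, maps, islands,
#'   metrics and the serialized config are written there
#' @return an object of class `run_config`
#' @export
run_config <- function(pattern = "clustered",
                       grid = c(100L, 100L),
                       baseline_apd_ms = 50,
                       island_params = list(count = 30, mean_radius_px = 6,
                                            elevation_ms = 25,
                                            shape = "ovoid"),
                       pacing = list(cycle_length_ms = 100, n_beats = NULL),
                       wave = list(direction_deg = 0, speed_mm_per_ms = 0.3),
                       noise = list(gaussian_sd = 0, drift_amplitude = 0,
                                    drift_freq_hz = 1, bleach_frac = 0),
                       n_frames = 1200L,
                       signal = signal_config(),
                       window_px = 10L,
                       threshold_ms = 10,
                       statistic = "std",
                       quadrat_size_px = 20L,
                       alpha = 0.05,
                       seed = 1L,
                       subject_label = "sim",
                       chamber = "unknown",
                       out_dir = NULL) {
  stopifnot(window_px >= 2L, threshold_ms >= 0, alpha > 0, alpha < 1,
            n_frames >= 2L)
  structure(
    list(pattern = pattern, grid = as.integer(grid),
         baseline_apd_ms = baseline_apd_ms, island_params = island_params,
         pacing = pacing, wave = wave, noise = noise,
         n_frames = as.integer(n_frames), signal = signal,
         window_px = as.integer(window_px), threshold_ms = threshold_ms,
         statistic = statistic,
         quadrat_size_px = as.integer(quadrat_size_px), alpha = alpha,
         seed = as.integer(seed), subject_label = subject_label,
         chamber = chamber, out_dir = out_dir),
    class = "run_config")
}

#' Run the full dispersion-analysis pipeline
#'
#' Simulate (or accept) a movie, then: preprocess, APD map, dispersion map,
#' binarize, supra-threshold area fraction, island extraction, pattern
#' classification. Deterministic given the config seed. When
#' `config$out_dir` is set, writes the APD/dispersion maps (CSV), the
#' binary map (green/yellow PNG), the island table, a tidy metrics CSV and
#' the serialized config.
#'
#' @param config a [run_config()]
#' @param movie optional [voltage_movie()]; when omitted, a synthetic
#'   scenario is generated from the config
#' @return list of class `pipeline_result`: `apd_map`, `dispersion`,
#'   `binary`, `islands`, `pattern`, `metrics` (tibble), `truth` (for
#'   simulated runs), `config`
#' @export
run_pipeline <- function(config = run_config(), movie = NULL) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (is.null(movie)) {
    field <- generate_apd_field(config$pattern, config$grid,
                                config$baseline_apd_ms,
                                config$island_params, seed = config$seed)
    meta <- acquisition_meta(n_frames = config$n_frames,
                             height = config$grid[1L],
                             width = config$grid[2L],
                             subject_label = config$subject_label,
                             chamber = config$chamber)
    sim <- synthesize_movie(field, meta, config$pacing, config$wave,
                            config$noise,
                            level_pct = config$signal$repolarization_level_pct,
                            dispersion_window_px = config$window_px,
                            threshold_ms = config$threshold_ms,
                            seed = config$seed)
    movie <- sim$movie
    truth <- sim$truth
  }
  pp <- preprocess(movie, config$signal)
  amap <- compute_apd_map(pp, config$signal)
  dmap <- dispersion_map(amap, config$window_px, config$statistic)
  bmap <- binarize(dmap, config$threshold_ms)
  frac <- area_fraction(bmap)
  islands <- extract_islands(bmap, movie$meta$pixel_pitch_mm)
  pattern <- classify_pattern(
    islands[, c("centroid_row", "centroid_col")],
    region = movie$mask, quadrat_size_px = config$quadrat_size_px,
    alpha = config$alpha, dmap = dmap)

  apd_vals <- amap$values[amap$valid]
  metrics <- tibble::tibble(
    subject_label = config$subject_label,
    chamber = config$chamber,
    metric = c("area_fraction_pct", "mean_apd_ms", "max_apd_ms",
               "apd_dispersion_ms", "n_islands", "vmr", "clark_evans_r",
               "morans_i"),
    value = c(frac, mean(apd_vals), max(apd_vals),
              sqrt(mean((apd_vals - mean(apd_vals))^2)),
              nrow(islands), pattern$vmr, pattern$clark_evans_r,
              pattern$morans_i))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write_map(amap$values, file.path(od, "apd_map.csv"), "csv")
    write_map(dmap$values, file.path(od, "dispersion_map.csv"), "csv")
    write_map(bmap$above, file.path(od, "binary_map.png"), "png")
    utils::write.csv(islands, file.path(od, "islands.csv"),
                     row.names = FALSE)
    write_metrics(metrics, file.path(od, "metrics.csv"))
    cfg <- config
    cfg$signal <- unclass(cfg$signal)
    yaml::write_yaml(unclass(cfg), file.path(od, "config.yml"))
  }

  structure(list(apd_map = amap, dispersion = dmap, binary = bmap,
                 islands = islands, pattern = pattern, metrics = metrics,
                 truth = truth, config = config,
                 pattern_label = pattern$label,
                 area_fraction_pct = frac),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %s | area > %.0f ms: %.2f%% | %d islands | label: %s\n",
    x$config$subject_label, x$config$threshold_ms, x$area_fraction_pct,
    nrow(x$islands), x$pattern_label))
  invisible(x)
}

#' Summarize a simulated cohort of subjects
#'
#' Per-group mean +/- SEM of a metric with a one-sample t-test against a
#' reference value (via [group_stats()]); with exactly two groups a Welch
#' two-sample contrast between them is appended.
#'
#' @param metrics tidy metrics tibble (rows = subject x metric) as produced
#'   by [run_pipeline()] / [write_metrics()], plus a `group` column
#' @param metric name of the metric to summarize
#' @param null_value one-sample reference value
#' @param alpha significance level
#' @return tibble with one row per group (and a `contrast` row for two
#'   groups): group, n, mean, sem, t, df, p, significant
#' @export
cohort_summary <- function(metrics, metric = "area_fraction_pct",
                           null_value = 0, alpha = 0.05) {
  stopifnot("group" %in% names(metrics))
  df <- dplyr::filter(metrics, .data$metric == !!metric)
  if (nrow(df) == 0) stop("metric not found: ", metric, call. = FALSE)
  groups <- split(df$value, df$group)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs >= 2 subjects", call. = FALSE)
  }
  rows <- purrr::imap(groups, function(v, g) {
    gs <- suppressWarnings(group_stats(v, null_value, alpha))
    dplyr::mutate(gs, group = g, .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  if (length(groups) == 2L) {
    a <- groups[[1L]]; b <- groups[[2L]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      tt <- list(statistic = c(t = if (mean(a) == mean(b)) 0 else Inf),
                 parameter = c(df = length(a) + length(b) - 2),
                 p.value = if (mean(a) == mean(b)) 1 else 0)
    } else {
      tt <- stats::t.test(a, b)
    }
    out <- dplyr::bind_rows(out, tibble::tibble(
      group = paste(names(groups), collapse = " vs "),
      n = length(a) + length(b),
      mean = mean(a) - mean(b), sem = NA_real_,
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, significant = tt$p.value < alpha))
  }
  out
}
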