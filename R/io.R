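#' Assemble a full run configuration
#'
#' One YAML-serializable object describing an end-to-end run: simulator
#' parameters, tube geometry in the frame, threshold, rendering, odor and
#' averaging settings. Round-trips losslessly through
#' [write_run_config()] / [read_run_config()].
#'
#' @param sim Named list of [assay_sim_config()] arguments.
#' @param geometry Named list of [tube_geometry()] arguments.
#' @param threshold Named list of [threshold_spec()] arguments.
#' @param render Named list of [render_frames()] rendering arguments
#'   (`height_px`, `fly_radius_px`, `fly_intensity`, `background`,
#'   `noise_sd`).
#' @param odor Odor name used for window lookup.
#' @param window Optional `c(start_min, end_min)` override.
#' @param analysis_interval_s Downsampling interval for analysis (default
#'   10 s).
#' @param flip_sign Report the avoidance index with avoidance positive.
#' @return A `run_config` (named list).
#' @examples
#' cfg <- run_config(sim = list(n_flies = 8, duration_s = 60, seed = 3))
#' cfg$odor
#' @export
run_config <- function(sim = list(),
                       geometry = list(c0 = 1, c1 = 300, odorant_end = "left"),
                       threshold = list(mode = "fixed", level = 0.5,
                                        polarity = "bright_flies"),
                       render = list(height_px = 40, fly_radius_px = 2,
                                     fly_intensity = 1, background = 0,
                                     noise_sd = 0.02),
                       odor = "benzaldehyde",
                       window = NULL,
                       analysis_interval_s = 10,
                       flip_sign = FALSE) {
  structure(
    list(sim = sim, geometry = geometry, threshold = threshold,
         render = render, odor = odor, window = window,
         analysis_interval_s = analysis_interval_s, flip_sign = flip_sign),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  if (!inherits(cfg, "run_config")) {
    ft_abort("`cfg` must be a run_config().", "flytube_bad_argument")
  }
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    ft_abort(sprintf("No such config file: %s", path), "flytube_io_error")
  }
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

# short hash of the run configuration, recorded in output headers for
# provenance
config_hash <- function(cfg) substr(rlang::hash(unclass(cfg)), 1, 12)

.resolve_sim_config <- function(cfg) do.call(assay_sim_config, cfg$sim)
.resolve_geometry <- function(cfg) do.call(tube_geometry, cfg$geometry)
.resolve_threshold <- function(cfg) do.call(threshold_spec, cfg$threshold)
.resolve_window <- function(cfg) {
  if (!is.null(cfg$window)) {
    odor_window(cfg$odor, cfg$window[[1]], cfg$window[[2]])
  } else {
    default_window(cfg$odor)
  }
}

#' Write a tibble as CSV with provenance header comments
#'
#' @param df Data frame.
#' @param path Output path.
#' @param comments Character vector written as leading `# ` lines.
#' @return `path`, invisibly.
#' @export
write_csv_commented <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste("#", comments), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by the package (leading `#` comments skipped)
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_csv_commented <- function(path) {
  if (!file.exists(path)) {
    ft_abort(sprintf("No such file: %s", path), "flytube_io_error")
  }
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read a per-frame tracking series from CSV
#'
#' Expects at least `time_s` and `com` columns (as written by
#' [cli_track()]); restores the `com_series` class and cadence.
#'
#' @param path CSV path.
#' @return A `com_series` tibble.
#' @export
read_series_csv <- function(path) {
  df <- read_csv_commented(path)
  if (!all(c("time_s", "com") %in% names(df))) {
    ft_abort("Series CSV must have time_s and com columns.", "flytube_io_error")
  }
  cadence <- if (nrow(df) > 1) df$time_s[2] - df$time_s[1] else 1
  new_com_series(df, cadence_s = cadence)
}
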