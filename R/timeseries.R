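#' Downsample a tracking series
#'
#' Video is captured at 1 frame/s but the CoM is conventionally analyzed at
#' 1 frame/10 s; this keeps every k-th sample starting at the first frame
#' (t = 0), where k = `interval_s / cadence`. The interval must be a
#' positive multiple of the input cadence — no interpolation is ever done.
#'
#' @param series A `com_series` tibble (from [track_stack()] or
#'   [track_trajectories()]).
#' @param interval_s New sampling interval in seconds.
#' @return A `com_series` with updated cadence.
#' @examples
#' s <- track_trajectories(simulate_trajectories(
#'   assay_sim_config(n_flies = 4, duration_s = 60, seed = 1)))
#' nrow(downsample_series(s, 10))
#' @export
downsample_series <- function(series, interval_s) {
  cadence <- attr(series, "cadence_s")
  if (is.null(cadence)) {
    ft_abort("`series` has no cadence attribute; build it with track_stack().",
             "flytube_bad_argument")
  }
  assert_scalar_number(interval_s, "interval_s")
  k <- interval_s / cadence
  if (interval_s <= 0 || abs(k - round(k)) > 1e-9) {
    ft_abort("`interval_s` must be a positive multiple of the series cadence.",
             "flytube_bad_interval")
  }
  k <- round(k)
  out <- series[seq(1, nrow(series), by = k), , drop = FALSE]
  new_com_series(tibble::as_tibble(out), cadence_s = interval_s)
}

#' Average a series over a steady-state window
#'
#' The summary statistic of an assay run: the arithmetic mean of the
#' per-frame CoM (and AI, when present) over the odor-specific steady-state
#' window, missing frames excluded. Window endpoints are inclusive on both
#' sides.
#'
#' @param series A `com_series`, or any data frame with `time_s` and `com`
#'   columns (an `ai` column is averaged too if present).
#' @param window An [odor_window()], or an odor name to look up with
#'   [default_window()].
#' @return A one-row tibble: `odor`, `start_min`, `end_min`, `n_used`,
#'   `mean_com` (and `mean_ai` if available). If the window contains no
#'   non-missing sample, `mean_com` is `NA` and a warning is raised.
#' @examples
#' s <- tibble::tibble(time_s = 0:3600, com = 0.7)
#' window_average(s, odor_window("custom", 20, 60))
#' @export
window_average <- function(series, window) {
  if (is.character(window)) window <- default_window(window)
  if (!inherits(window, "odor_window")) {
    ft_abort("`window` must be an odor_window() or an odor name.",
             "flytube_bad_argument")
  }
  stopifnot(all(c("time_s", "com") %in% names(series)))
  sel <- series$time_s >= window$start_min * 60 &
    series$time_s <= window$end_min * 60
  vals <- series$com[sel]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) {
    warn("No non-missing samples in the averaging window.",
         class = "flytube_empty_window")
  }
  out <- tibble::tibble(
    odor = window$odor,
    start_min = window$start_min,
    end_min = window$end_min,
    n_used = length(vals),
    mean_com = if (length(vals)) mean(vals) else NA_real_
  )
  if ("ai" %in% names(series)) {
    ai <- series$ai[sel]
    ai <- ai[!is.na(ai)]
    out$mean_ai <- if (length(ai)) mean(ai) else NA_real_
  }
  out
}

#' Odor-specific steady-state window
#'
#' @param odor Odor name (label only).
#' @param start_min,end_min Window bounds in minutes from odor application,
#'   with `0 <= start_min < end_min <= 60`.
#' @return An `odor_window` object.
#' @export
odor_window <- function(odor, start_min, end_min) {
  assert_scalar_number(start_min, "start_min")
  assert_scalar_number(end_min, "end_min")
  if (start_min < 0 || start_min >= end_min || end_min > 60) {
    ft_abort("Need 0 <= start_min < end_min <= 60.", "flytube_bad_window")
  }
  structure(list(odor = as.character(odor), start_min = start_min,
                 end_min = end_min),
            class = "odor_window")
}

#' @export
print.odor_window <- function(x, ...) {
  cat(sprintf("<odor_window> %s: %g - %g min\n", x$odor, x$start_min, x$end_min))
  invisible(x)
}

#' Look up the standard steady-state window for an odor
#'
#' The response time course is odor-specific, so each odor has its own
#' averaging window (shipped as a YAML table, see
#' `system.file("extdata", "odor_windows.yaml", package = "flytube")`):
#' propionic acid and isovaleric acid 5-25 min, R-limonene 0-60 min,
#' AITC / citronellal / lemongrass / benzaldehyde 20-60 min. Unknown odors
#' are rejected — supply an explicit [odor_window()] instead.
#'
#' @param odor Odor name (case-insensitive; `"BA"` is accepted for
#'   benzaldehyde).
#' @param table Optional user window table (named list of
#'   `c(start_min, end_min)`) overriding the packaged one.
#' @return An [odor_window()].
#' @examples
#' default_window("AITC")
#' @export
default_window <- function(odor, table = NULL) {
  if (is.null(table)) table <- .load_window_table()
  key <- names(table)[match(tolower(odor), tolower(names(table)))]
  if (is.na(key) && tolower(odor) == "ba") key <- "benzaldehyde"
  if (is.na(key) || !key %in% names(table)) {
    ft_abort(
      sprintf("No standard window for odor '%s'; supply an explicit odor_window().",
              odor),
      "flytube_unknown_odor"
    )
  }
  w <- table[[key]]
  odor_window(key, w[1], w[2])
}

.load_window_table <- function() {
  path <- system.file("extdata", "odor_windows.yaml", package = "flytube")
  yaml::read_yaml(path)
}
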