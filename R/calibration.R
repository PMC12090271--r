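#' Variance of replicate-mean CoMs
#'
#' Unbiased (n - 1) sample variance of the window-averaged CoM across
#' replicate tubes — the per-group-size variability statistic of the
#' flies-per-tube calibration.
#'
#' @param means Numeric vector of replicate means (each in \[0, 1\]), with
#'   at least 2 values.
#' @return A single variance.
#' @examples
#' variance_of_means(c(0.6, 0.8)) # 0.02
#' @export
variance_of_means <- function(means) {
  if (!is.numeric(means) || length(means) < 2 || any(!is.finite(means))) {
    ft_abort("Need >= 2 finite replicate means.", "flytube_bad_argument")
  }
  var(means)
}

#' Cohen's d between two replicate sets
#'
#' Standardized effect size between treated (odor) and control (solvent)
#' replicate-mean CoMs: difference of group means divided by the pooled
#' standard deviation (pooled with n - 1 weights). With a null treatment
#' the expected value is 0.
#'
#' @param treated,control Numeric vectors of replicate means, each with at
#'   least 2 values.
#' @return Cohen's d, or `NA` (with a warning) if the pooled SD is zero.
#' @examples
#' effect_size(c(0.7, 0.8, 0.9), c(0.5, 0.5, 0.6))
#' @export
effect_size <- function(treated, control) {
  for (v in list(treated, control)) {
    if (!is.numeric(v) || length(v) < 2 || any(!is.finite(v))) {
      ft_abort("Each group needs >= 2 finite replicate means.",
               "flytube_bad_argument")
    }
  }
  n1 <- length(treated); n2 <- length(control)
  sp2 <- ((n1 - 1) * var(treated) + (n2 - 1) * var(control)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    warn("Zero pooled SD: effect size undefined.", class = "flytube_zero_sd")
    return(NA_real_)
  }
  (mean(treated) - mean(control)) / sqrt(sp2)
}

#' Calibrate assay variability against flies per tube
#'
#' Re-creates the group-size calibration on synthetic data: for each group
#' size it simulates `n_reps` odor-arm replicates (drift as in
#' `sim_config_base`) and `n_reps` matched solvent-control replicates
#' (drift 0), reduces every run to its window-averaged CoM, and summarizes
#' each size by the replicate variance of the odor arm, the Cohen's d
#' between arms, and the arm means. Replicate seeds are derived
#' deterministically from `sim_config_base$seed`, so a fixed base seed
#' gives a bitwise-identical result.
#'
#' Per-frame CoMs are taken directly from the simulated positions
#' (point-mass CoM); the rasterization step is validated separately by the
#' render-track roundtrip and only adds sub-pixel error.
#'
#' @param sim_config_base An [assay_sim_config()]; `n_flies` and `seed` are
#'   overridden per size/replicate.
#' @param group_sizes Integer vector of flies-per-tube values.
#' @param n_reps Replicates per size and arm (>= 2).
#' @param window An [odor_window()] (or odor name) over which each run is
#'   averaged.
#' @param analysis_interval_s Downsampling interval before averaging.
#'   Default 10 s.
#' @return A `fly_calibration` tibble: one row per group size with columns
#'   `group_size`, `n_reps`, `variance`, `effect_size`, `mean_com`,
#'   `mean_com_control`, `variance_control`, plus a `replicates` attribute
#'   holding the per-replicate means.
#' @examples
#' \donttest{
#' cal <- calibrate_group_size(
#'   assay_sim_config(duration_s = 600, seed = 1),
#'   group_sizes = c(2, 8), n_reps = 4,
#'   window = odor_window("synthetic", 5, 10))
#' cal
#' }
#' @export
calibrate_group_size <- function(sim_config_base,
                                 group_sizes = c(1, 2, 4, 8, 16, 32, 64),
                                 n_reps = 6,
                                 window = odor_window("synthetic", 20, 60),
                                 analysis_interval_s = 10) {
  if (!inherits(sim_config_base, "assay_sim_config")) {
    ft_abort("`sim_config_base` must be an assay_sim_config().",
             "flytube_bad_argument")
  }
  if (n_reps < 2) {
    ft_abort("`n_reps` must be >= 2 for a variance.", "flytube_bad_argument")
  }
  if (is.character(window)) window <- default_window(window)

  run_arm <- function(n, rep, drift, arm_id) {
    cfg <- sim_config_base
    cfg$n_flies <- as.integer(n)
    cfg$drift_mm_s <- drift
    # deterministic substream per (size, replicate, arm), kept below 2^31
    cfg$seed <- (sim_config_base$seed + 7919L * as.integer(n) +
                   104729L * rep + 15485863L * arm_id) %% 2147483647L
    series <- track_trajectories(simulate_trajectories(cfg))
    series <- downsample_series(series, analysis_interval_s)
    window_average(series, window)$mean_com
  }

  rows <- purrr::map(group_sizes, function(n) {
    odor <- purrr::map_dbl(seq_len(n_reps), run_arm, n = n,
                           drift = sim_config_base$drift_mm_s, arm_id = 1L)
    ctrl <- purrr::map_dbl(seq_len(n_reps), run_arm, n = n,
                           drift = 0, arm_id = 2L)
    tibble::tibble(
      group_size = as.integer(n),
      n_reps = as.integer(n_reps),
      variance = variance_of_means(odor),
      effect_size = effect_size(odor, ctrl),
      mean_com = mean(odor),
      mean_com_control = mean(ctrl),
      variance_control = variance_of_means(ctrl),
      odor_means = list(odor),
      control_means = list(ctrl)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fly_calibration", class(out))
  out
}

#' Within-replicate temporal variance of a series
#'
#' Secondary variability measure: the variance of the per-frame CoM over
#' the steady-state window within a single run (as opposed to the
#' across-replicate variance of [variance_of_means()]).
#'
#' @inheritParams window_average
#' @return A single variance (NA if < 2 usable samples).
#' @export
temporal_variance <- function(series, window) {
  if (is.character(window)) window <- default_window(window)
  sel <- series$time_s >= window$start_min * 60 &
    series$time_s <= window$end_min * 60
  vals <- series$com[sel]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2) return(NA_real_)
  var(vals)
}

#' @export
#' @method tidy fly_calibration
#' @rdname calibrate_group_size
#' @param x,... A `fly_calibration` and unused arguments, for methods.
tidy.fly_calibration <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$odor_means <- NULL
  out$control_means <- NULL
  out
}

#' @export
#' @method glance fly_calibration
#' @rdname calibrate_group_size
glance.fly_calibration <- function(x, ...) {
  tibble::tibble(
    n_sizes = nrow(x),
    best_size_variance = x$group_size[which.min(x$variance)],
    best_size_effect = x$group_size[which.max(x$effect_size)],
    variance_monotone = all(diff(x$variance[order(x$group_size)]) <= 0)
  )
}
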