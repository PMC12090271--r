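#' Simulate fly trajectories in a two-choice assay tube
#'
#' Runs the agent-based model described in [assay_sim_config()]: an
#' Euler-discretized biased random walk
#' \deqn{x_{t+\Delta} = x_t + \kappa(1 - e^{-t/\tau})\Delta + \sigma\sqrt{\Delta}\,\xi}
#' with reflecting boundaries at 0 and the tube length, plus pairwise
#' soft-core repulsion for flies closer than the crowding radius. Initial
#' positions are uniform along the tube (flies are distributed homogeneously
#' before odor application). The odorant end is at 0 mm; positive drift
#' models aversion.
#'
#' Randomness is governed entirely by `config$seed`: the seed is set once,
#' then the replicate-level drift factor, the initial positions and the
#' walk noise are drawn in that order, so identical configs give identical
#' trajectories. If `drift_cv > 0` the run's drift is
#' `drift_mm_s * exp(sd * z - sd^2 / 2)` with `sd = sqrt(log(1 + cv^2))`
#' (a lognormal factor with unit mean and the requested CV), modelling
#' tube-to-tube differences in effective odor drive.
#'
#' @param config An [assay_sim_config()].
#' @return A `fly_trajectory` object: a numeric matrix with one row per fly
#'   and one column per frame (`duration_s * fps + 1` columns, including
#'   t = 0), positions in mm, with a `times` attribute in seconds.
#' @examples
#' traj <- simulate_trajectories(assay_sim_config(n_flies = 4, duration_s = 60, seed = 7))
#' dim(traj)
#' @seealso [track_trajectories()] to reduce a trajectory to a CoM series,
#'   [render_frames()] to rasterize it into image frames.
#' @export
simulate_trajectories <- function(config) {
  if (!inherits(config, "assay_sim_config")) {
    ft_abort("`config` must be created by assay_sim_config().", "flytube_bad_argument")
  }
  steps <- round(config$duration_s * config$fps)
  dt <- 1 / config$fps
  set.seed(config$seed)
  kappa <- config$drift_mm_s
  cv <- config$drift_cv %||% 0
  if (cv > 0) {
    sdl <- sqrt(log(1 + cv^2))
    kappa <- kappa * exp(rnorm(1, 0, sdl) - sdl^2 / 2)
  }
  x0 <- runif(config$n_flies, 0, config$tube_length_mm)
  pos <- .walk_core(x0, as.integer(steps), dt,
                    kappa, config$onset_tau_s,
                    config$diffusion_mm_sqrt_s,
                    config$tube_length_mm,
                    config$crowding_radius_mm, config$crowding_strength)
  rownames(pos) <- paste0("fly", seq_len(config$n_flies))
  structure(pos,
            times = seq(0, by = dt, length.out = steps + 1),
            tube_length_mm = config$tube_length_mm,
            class = c("fly_trajectory", "matrix", "array"))
}

#' Tidy a trajectory into a long tibble
#'
#' @param x A `fly_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `fly_id`, `x_mm`.
#' @export
#' @method tidy fly_trajectory
tidy.fly_trajectory <- function(x, ...) {
  times <- attr(x, "times")
  tibble::tibble(
    time_s = rep(times, each = nrow(x)),
    fly_id = rep(seq_len(nrow(x)), times = ncol(x)),
    x_mm = as.vector(unclass(x))
  )
}

#' Reduce a trajectory to a point-mass CoM / AI series
#'
#' Computes, per frame, the normalized center of mass of the true fly
#' positions (mean position divided by tube length; 0 = odorant end) and the
#' point-mass avoidance index ((flies in odorant half - flies in solvent
#' half) / all flies). This is the idealized, rasterization-free counterpart
#' of [track_stack()]; the render-then-track pipeline agrees with it to
#' within one fly radius in normalized units.
#'
#' @param traj A `fly_trajectory`.
#' @return A `com_series` tibble with columns `frame`, `time_s`, `com`,
#'   `ai`, `n_pixels` (here the number of flies).
#' @export
track_trajectories <- function(traj) {
  if (!inherits(traj, "fly_trajectory")) {
    ft_abort("`traj` must be a fly_trajectory.", "flytube_bad_argument")
  }
  L <- attr(traj, "tube_length_mm")
  times <- attr(traj, "times")
  pos <- unclass(traj)
  com <- colMeans(pos) / L
  half <- L / 2
  n_odor <- colSums(pos < half)
  n_solv <- colSums(pos > half)
  ai <- (n_odor - n_solv) / nrow(pos)
  new_com_series(
    tibble::tibble(
      frame = seq_along(times),
      time_s = times,
      com = com,
      ai = ai,
      n_pixels = nrow(pos)
    ),
    cadence_s = if (length(times) > 1) times[2] - times[1] else 1
  )
}

# canonical pattern support table (normalized tube coordinate; 0 = odorant/left end)
.canonical_patterns <- list(
  homogeneous       = c(0.0, 1.0),
  left_cluster      = c(0.0, 0.1),
  left_bias         = c(0.0, 0.5),
  slight_left_bias  = c(0.3, 0.5),
  slight_right_bias = c(0.5, 0.7),
  right_bias        = c(0.5, 1.0),
  right_cluster     = c(0.9, 1.0)
)

#' Canonical fly-distribution patterns
#'
#' Draws `n` normalized tube positions from one of the canonical
#' distribution shapes used to anchor the CoM statistic: flies clustered at
#' one end, biased toward one half, slightly biased, or homogeneous.
#' Positions are uniform on the pattern's support:
#'
#' | pattern            | support     |
#' |--------------------|-------------|
#' | `homogeneous`      | \[0, 1\]    |
#' | `left_cluster`     | \[0, 0.1\]  |
#' | `left_bias`        | \[0, 0.5\]  |
#' | `slight_left_bias` | \[0.3, 0.5\]|
#' | `slight_right_bias`| \[0.5, 0.7\]|
#' | `right_bias`       | \[0.5, 1\]  |
#' | `right_cluster`    | \[0.9, 1\]  |
#'
#' The odorant end is at 0, so "right" patterns (support in the solvent
#' half) have CoM above 0.5 and "left" patterns below 0.5.
#'
#' @param name Pattern name (see table).
#' @param n Number of positions.
#' @param seed Integer seed.
#' @return A `canonical_pattern` object: a list with `name` and `positions`
#'   (numeric vector in \[0, 1\]).
#' @examples
#' canonical_positions("right_cluster", 5, seed = 1)$positions
#' @export
canonical_positions <- function(name, n, seed = 1L) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.canonical_patterns)) {
    ft_abort(
      sprintf("Unknown pattern name. Choose one of: %s.",
              paste(names(.canonical_patterns), collapse = ", ")),
      "flytube_bad_pattern"
    )
  }
  assert_scalar_number(n, "n")
  if (n < 1 || n != round(n)) {
    ft_abort("`n` must be a positive integer.", "flytube_bad_argument")
  }
  supp <- .canonical_patterns[[name]]
  set.seed(seed)
  structure(
    list(name = name, positions = runif(n, supp[1], supp[2])),
    class = "canonical_pattern"
  )
}

#' Estimate the drift parameter from a CoM time course
#'
#' Fits the saturating-exponential rise
#' \eqn{c(t) = c_\infty - (c_\infty - c_0) e^{-t/\tau}} to an observed CoM
#' series, then inverts the stationary mean of the reflected, tilted walk
#' (density \eqn{\propto e^{a x}} on \[0, L\], \eqn{a = 2\kappa/\sigma^2})
#' to recover the drift speed kappa from the fitted plateau. The diffusion
#' scale sigma must be supplied (it is not identifiable from the mean
#' alone).
#'
#' @param series A `com_series` tibble (or any data frame with `time_s` and
#'   `com` columns), typically the average of several replicates.
#' @param tube_length_mm Tube length in mm.
#' @param diffusion_mm_sqrt_s The sigma used in the simulation/assay model.
#' @return A one-row tibble with `drift_mm_s`, `onset_tau_s`,
#'   `com_steady_state`.
#' @export
estimate_drift <- function(series, tube_length_mm = 150, diffusion_mm_sqrt_s = 2) {
  stopifnot(all(c("time_s", "com") %in% names(series)))
  dat <- series[stats::complete.cases(series[c("time_s", "com")]), ]
  fit <- stats::nls(
    com ~ css - (css - c0) * exp(-time_s / tau),
    data = dat,
    start = list(css = mean(tail(dat$com, 20)), c0 = dat$com[1], tau = 300),
    control = stats::nls.control(warnOnly = TRUE)
  )
  cf <- stats::coef(fit)
  kappa <- .invert_stationary_mean(unname(cf[["css"]]), tube_length_mm,
                                   diffusion_mm_sqrt_s)
  tibble::tibble(
    drift_mm_s = kappa,
    onset_tau_s = unname(cf[["tau"]]),
    com_steady_state = unname(cf[["css"]])
  )
}

# mean of density exp(a x) on [0, L], normalized to [0, 1]; stable for
# large |a * L|
.tilted_mean <- function(a, L) {
  u <- a * L
  if (abs(u) < 1e-8) return(0.5)
  if (u > 50) return(1 - 1 / u)
  if (u < -50) return(-1 / u)
  exp(u) / expm1(u) - 1 / u
}

.invert_stationary_mean <- function(com_ss, L, sigma) {
  if (com_ss <= 0 || com_ss >= 1) {
    ft_abort("Steady-state CoM must lie strictly in (0, 1) to invert.",
             "flytube_bad_argument")
  }
  if (abs(com_ss - 0.5) < 1e-10) return(0)
  f <- function(a) .tilted_mean(a, L) - com_ss
  a_hat <- uniroot(f, interval = c(-2, 2), tol = 1e-10)$root
  a_hat * sigma^2 / 2
}
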