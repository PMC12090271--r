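#' Configuration for the synthetic tube-assay simulator
#'
#' Bundles the parameters of the agent-based model used to emulate a
#' two-choice tube assay: `n_flies` walkers move along a 1-D tube of length
#' `tube_length_mm` as a biased random walk with reflecting boundaries.
#' The drift toward the solvent end ramps up with an exponential time
#' constant `onset_tau_s`, emulating the gradual build-up of odor aversion
#' to an approximately steady state within the first ~20 min of an assay.
#' Flies closer together than `crowding_radius_mm` repel each other with a
#' soft-core force, which at high densities pushes part of the group back
#' toward the odorant end (the crowding effect seen at 32-64 flies per
#' tube).
#'
#' Default parameter rationale:
#' * `drift_mm_s` (kappa) and `diffusion_mm_sqrt_s` (sigma) jointly set the
#'   stationary distribution of a non-interacting walker, which is the
#'   exponentially tilted density \eqn{\propto e^{2\kappa x/\sigma^2}} on
#'   `[0, L]`. The defaults (0.05 mm/s, 2 mm/sqrt(s)) put the stationary
#'   mean CoM near 0.75, i.e. clear but non-ceiling aversion.
#' * `onset_tau_s = 420` s makes the drift >94% of maximal by 20 min.
#' * `crowding_radius_mm = 5` is about two fly body lengths (soft social
#'   spacing, not hard body exclusion): at 32-64 flies the summed exclusion
#'   length exceeds the tube and part of the group is pushed back toward
#'   the odorant end.
#' * `drift_cv = 0.2`: tubes are not statistical clones — odor loading,
#'   fly batch and microclimate vary between replicates — so each
#'   replicate's drift is scaled by a lognormal factor with ~20%
#'   coefficient of variation. This puts a realistic floor under the
#'   replicate-to-replicate variance at large group sizes.
#'
#' A positive `drift_mm_s` pushes flies toward the solvent end; the odorant
#' end is at coordinate 0 mm by convention.
#'
#' @param n_flies Number of flies in the tube (1-64).
#' @param duration_s Assay duration in seconds. Default 3600 (60 min).
#' @param fps Frames (= simulation steps) per second. Default 1.
#' @param tube_length_mm Tube length in mm. Default 150.
#' @param drift_mm_s Signed maximal drift speed kappa in mm/s; positive =
#'   toward the solvent (high-coordinate) end. Default 0.25.
#' @param onset_tau_s Exponential ramp time constant tau of the drift, in
#'   seconds. Default 420.
#' @param diffusion_mm_sqrt_s Diffusive step scale sigma in mm/sqrt(s).
#'   Default 4.
#' @param crowding_radius_mm Soft-core exclusion distance d_ex in mm; 0
#'   disables crowding. Default 5.
#' @param drift_cv Between-replicate coefficient of variation of the drift
#'   (each run multiplies kappa by a lognormal factor with this CV; 0 =
#'   clonal replicates). Default 0.2.
#' @param crowding_strength Fraction of the pairwise overlap corrected per
#'   step (0-1). Default 0.5.
#' @param seed Integer seed governing initial positions and walk noise
#'   (and, downstream, rendering noise) via documented substreams.
#'
#' @return An object of class `assay_sim_config` (a named list).
#' @examples
#' cfg <- assay_sim_config(n_flies = 8, duration_s = 600, seed = 1)
#' cfg
#' @export
assay_sim_config <- function(n_flies = 16,
                             duration_s = 3600,
                             fps = 1,
                             tube_length_mm = 150,
                             drift_mm_s = 0.25,
                             onset_tau_s = 420,
                             diffusion_mm_sqrt_s = 4,
                             crowding_radius_mm = 5,
                             crowding_strength = 0.5,
                             drift_cv = 0.2,
                             seed = 1L) {
  assert_scalar_number(n_flies, "n_flies")
  assert_scalar_number(duration_s, "duration_s")
  assert_scalar_number(fps, "fps")
  assert_scalar_number(tube_length_mm, "tube_length_mm")
  assert_scalar_number(drift_mm_s, "drift_mm_s")
  assert_scalar_number(onset_tau_s, "onset_tau_s")
  assert_scalar_number(diffusion_mm_sqrt_s, "diffusion_mm_sqrt_s")
  assert_scalar_number(crowding_radius_mm, "crowding_radius_mm")
  assert_scalar_number(crowding_strength, "crowding_strength")
  assert_scalar_number(drift_cv, "drift_cv")
  assert_scalar_number(seed, "seed")
  if (n_flies < 1 || n_flies != round(n_flies)) {
    ft_abort("`n_flies` must be a positive integer.", "flytube_bad_argument")
  }
  if (duration_s <= 0 || fps <= 0 || tube_length_mm <= 0) {
    ft_abort("`duration_s`, `fps` and `tube_length_mm` must be positive.",
             "flytube_bad_argument")
  }
  if (diffusion_mm_sqrt_s < 0 || crowding_radius_mm < 0 || onset_tau_s < 0 ||
      drift_cv < 0) {
    ft_abort("`diffusion_mm_sqrt_s`, `crowding_radius_mm`, `onset_tau_s` and `drift_cv` must be non-negative.",
             "flytube_bad_argument")
  }
  structure(
    list(
      n_flies = as.integer(n_flies),
      duration_s = duration_s,
      fps = fps,
      tube_length_mm = tube_length_mm,
      drift_mm_s = drift_mm_s,
      onset_tau_s = onset_tau_s,
      diffusion_mm_sqrt_s = diffusion_mm_sqrt_s,
      crowding_radius_mm = crowding_radius_mm,
      crowding_strength = crowding_strength,
      drift_cv = drift_cv,
      seed = as.integer(seed)
    ),
    class = "assay_sim_config"
  )
}

#' @export
print.assay_sim_config <- function(x, ...) {
  cat("<assay_sim_config>\n")
  cat(sprintf("  %d flies, %g s at %g fps, tube %g mm\n",
              x$n_flies, x$duration_s, x$fps, x$tube_length_mm))
  cat(sprintf("  drift %g mm/s (tau %g s, cv %g), diffusion %g mm/sqrt(s)\n",
              x$drift_mm_s, x$onset_tau_s, x$drift_cv, x$diffusion_mm_sqrt_s))
  cat(sprintf("  crowding radius %g mm (strength %g), seed %d\n",
              x$crowding_radius_mm, x$crowding_strength, x$seed))
  invisible(x)
}
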