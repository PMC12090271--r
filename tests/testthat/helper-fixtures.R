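# Programmatic fixtures shared across test files.

# a frame with given bright pixels (list of c(row, col)) on a dark background
frame_with_pixels <- function(H, W, pixels, fly = 1, bg = 0) {
  fr <- matrix(bg, H, W)
  for (p in pixels) fr[p[1], p[2]] <- fly
  fr
}

# a random mask over a random tube width, returning both the mask and the
# flagged offsets for oracle checks
random_mask <- function(W = NULL) {
  if (is.null(W)) W <- sample(2:500, 1)
  counts <- rpois(W, lambda = 0.2)
  if (sum(counts) == 0) counts[sample(W, 1)] <- 1L
  list(mask = mask_from_counts(counts),
       offsets = rep(seq_len(W) - 1L, counts),
       W = W)
}

# a flat trace with one square deflection, for peak-quantification checks
pulse_trace <- function(baseline = 0, peak = 5, stim = 10, modality = "dcfda",
                        direction = 1, t_end = 40, dt = 0.5) {
  tt <- seq(0, t_end, by = dt)
  sig <- rep(baseline, length(tt))
  sig[tt >= stim + 2 & tt <= stim + 4] <- baseline + direction * peak
  evoked_trace(tt, sig, stim_time = stim, modality = modality)
}

quick_sim <- function(..., duration_s = 300) {
  simulate_trajectories(assay_sim_config(..., duration_s = duration_s))
}
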