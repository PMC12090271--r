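test_that("simulator config validates its inputs", {
  expect_error(assay_sim_config(n_flies = 0), class = "flytube_bad_argument")
  expect_error(assay_sim_config(n_flies = 2.5), class = "flytube_bad_argument")
  expect_error(assay_sim_config(duration_s = -1), class = "flytube_bad_argument")
  expect_error(assay_sim_config(diffusion_mm_sqrt_s = -1), class = "flytube_bad_argument")
  expect_error(assay_sim_config(drift_mm_s = Inf), class = "flytube_bad_argument")
  expect_error(assay_sim_config(drift_mm_s = NA), class = "flytube_bad_argument")
})

test_that("trajectories are reproducible, bounded, and correctly shaped", {
  cfg <- assay_sim_config(n_flies = 5, duration_s = 120, seed = 99)
  t1 <- simulate_trajectories(cfg)
  t2 <- simulate_trajectories(cfg)
  expect_identical(unclass(t1), unclass(t2))
  expect_equal(dim(t1), c(5, 121))
  expect_true(all(t1 >= 0 & t1 <= cfg$tube_length_mm))
  # a different seed gives different paths
  t3 <- simulate_trajectories(assay_sim_config(n_flies = 5, duration_s = 120, seed = 100))
  expect_false(identical(unclass(t1), unclass(t3)))
})

test_that("unbiased walks settle around 0.5 and drift sets the CoM side", {
  # kappa = 0: grand mean of final-window CoM within 3 SE of 0.5
  finals <- purrr::map_dbl(1:100, function(r) {
    traj <- quick_sim(n_flies = 16, drift_mm_s = 0, seed = r, duration_s = 300)
    s <- track_trajectories(traj)
    mean(s$com[s$time_s >= 150])
  })
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.5), 3 * se)

  # kappa > 0: steady-state mean CoM above 0.5
  aversive <- purrr::map_dbl(1:20, function(r) {
    traj <- simulate_trajectories(
      assay_sim_config(n_flies = 16, duration_s = 1500, seed = r))
    s <- track_trajectories(traj)
    mean(s$com[s$time_s >= 900])
  })
  expect_gt(mean(aversive), 0.55)
})

test_that("mirror symmetry: negating the drift reflects the CoM distribution", {
  ss_mean <- function(kappa) {
    mean(purrr::map_dbl(1:100, function(r) {
      traj <- simulate_trajectories(assay_sim_config(
        n_flies = 8, duration_s = 1200, drift_mm_s = kappa, seed = r))
      s <- track_trajectories(traj)
      mean(s$com[s$time_s >= 600])
    }))
  }
  m_pos <- ss_mean(0.25)
  m_neg <- ss_mean(-0.25)
  expect_equal(m_pos, 1 - m_neg, tolerance = 0.02)
})

test_that("replicate variance of mean CoM is non-increasing in group size for independent flies", {
  sizes <- c(1, 4, 16, 64)
  vars <- purrr::map_dbl(sizes, function(n) {
    reps <- purrr::map_dbl(1:30, function(r) {
      traj <- simulate_trajectories(assay_sim_config(
        n_flies = n, duration_s = 900, crowding_radius_mm = 0, drift_cv = 0,
        seed = 1000 * n + r))
      s <- track_trajectories(traj)
      mean(s$com[s$time_s >= 450])
    })
    var(reps)
  })
  # monotone within sampling error: each variance below 1.75x the running min
  running_min <- cummin(vars)
  expect_true(all(vars[-1] <= 1.75 * running_min[-length(vars)]))
  expect_lt(vars[length(vars)], vars[1] / 2)
})

test_that("crowding pushes the steady-state CoM back toward the odorant end", {
  ss <- function(d_ex) {
    mean(purrr::map_dbl(1:15, function(r) {
      traj <- simulate_trajectories(assay_sim_config(
        n_flies = 64, duration_s = 1200, crowding_radius_mm = d_ex,
        drift_cv = 0, seed = 50 + r))
      s <- track_trajectories(traj)
      mean(s$com[s$time_s >= 600])
    }))
  }
  expect_lt(ss(5), ss(0))
})

test_that("drift sign and magnitude are recoverable from the CoM time course", {
  kappa_true <- 0.25
  series <- purrr::map(1:20, function(r) {
    traj <- simulate_trajectories(assay_sim_config(
      n_flies = 16, drift_mm_s = kappa_true, crowding_radius_mm = 0,
      drift_cv = 0, seed = 400 + r))
    track_trajectories(traj)$com
  })
  avg <- tibble::tibble(time_s = 0:3600, com = rowMeans(do.call(cbind, series)))
  est <- estimate_drift(avg, tube_length_mm = 150, diffusion_mm_sqrt_s = 4)
  expect_gt(est$drift_mm_s, 0)
  expect_lt(abs(est$drift_mm_s - kappa_true) / kappa_true, 0.25)
})

test_that("canonical patterns respect their documented supports", {
  p <- canonical_positions("right_cluster", 200, seed = 5)
  expect_true(all(p$positions >= 0.9 & p$positions <= 1))
  expect_true(all(canonical_positions("left_bias", 100, seed = 6)$positions <= 0.5))
  expect_true(all(canonical_positions("slight_left_bias", 100, seed = 6)$positions >= 0.3))
  hom <- canonical_positions("homogeneous", 1e4, seed = 7)$positions
  se <- sqrt(1 / 12) / sqrt(1e4)
  expect_lt(abs(mean(hom) - 0.5), 3 * se)
  expect_error(canonical_positions("diagonal_bias", 10), class = "flytube_bad_pattern")
})

test_that("rendering draws flies where the trajectory says and survives tracking", {
  geom <- tube_geometry(1, 201)
  spec <- threshold_spec(level = 0.5)

  # one fly pinned at the midpoint: rendered CoM at 0.5 within one pixel
  traj <- quick_sim(n_flies = 1, drift_mm_s = 0, diffusion_mm_sqrt_s = 0,
                    crowding_radius_mm = 0, duration_s = 2, seed = 1)
  traj[] <- 75
  fr <- render_frames(traj, geom, seed = 1)
  com <- compute_com(threshold_frame(fr[[1]], spec, geom))
  expect_lt(abs(com - 0.5), 1 / 200)

  # zero noise margin or equal intensities are rejected with a diagnostic
  expect_error(render_frames(traj, geom, fly_intensity = 0.5, background = 0.5),
               class = "flytube_bad_render")
  expect_error(render_frames(traj, geom, noise_sd = 0.2),
               class = "flytube_bad_render")
})

test_that("render-then-track recovers the point-mass CoM within a fly radius", {
  set.seed(123)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    W <- sample(150:400, 1)
    r_px <- sample(1:3, 1)
    traj <- quick_sim(n_flies = n, seed = i, duration_s = 5)
    geom <- tube_geometry(1, W)
    frames <- render_frames(traj, geom, fly_radius_px = r_px, seed = i)
    tracked <- track_stack(frames, threshold_spec(level = 0.5), geom)
    truth <- track_trajectories(traj)
    expect_true(all(abs(tracked$com - truth$com) <= r_px / (W - 1) + 1e-12))
  }
})

test_that("rendering noise never crosses the segmentation threshold", {
  traj <- quick_sim(n_flies = 1, duration_s = 2, seed = 1)
  frames <- render_frames(traj, tube_geometry(1, 150), fly_intensity = 1,
                          background = 0, noise_sd = 0.02, seed = 1)
  blank <- frames[[1]]
  blank[blank > 0.5] <- 0 # remove the fly, keep the noise field
  expect_equal(sum(blank > 0.5), 0)
})
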