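test_that("thresholding flags the right pixels and respects the tube span", {
  geom <- tube_geometry(3, 12, "left")
  spec <- threshold_spec(level = 0.5)

  # uniform background: empty mask
  m <- threshold_frame(matrix(0.1, 6, 15), spec, geom)
  expect_equal(m$M, 0)

  # exactly 5 bright pixels inside the span are counted
  fr <- frame_with_pixels(6, 15, list(c(1, 3), c(2, 5), c(3, 7), c(4, 9), c(5, 12)))
  expect_equal(threshold_frame(fr, spec, geom)$M, 5)

  # bright pixels outside the span are never flagged
  fr_out <- frame_with_pixels(6, 15, list(c(1, 1), c(2, 2), c(3, 14), c(1, 5)))
  expect_equal(threshold_frame(fr_out, spec, geom)$M, 1)

  # polarity contract: bright flies are invisible to a dark_flies threshold
  spec_dark <- threshold_spec(level = 0.5, polarity = "dark_flies")
  expect_equal(threshold_frame(fr, spec_dark, geom)$M, 6 * 10 - 5)

  # geometry outside the frame is rejected
  expect_error(threshold_frame(matrix(0, 4, 8), spec, tube_geometry(1, 20)),
               class = "flytube_bad_geometry")
})

test_that("CoM hits the distribution anchors and the worked example", {
  # all mass in the farthest column / odorant column / homogeneous
  expect_identical(compute_com(mask_from_counts(c(0, 0, 0, 4))), 1)
  expect_identical(compute_com(mask_from_counts(c(4, 0, 0, 0))), 0)
  expect_identical(compute_com(mask_from_counts(rep(3, 11))), 0.5)

  # L = 11, offsets {2, 2, 8}: (2 + 2 + 8) / (3 * 10)
  counts <- integer(11); counts[3] <- 2; counts[9] <- 1
  expect_equal(compute_com(mask_from_counts(counts)), 0.4)

  # empty mask is missing, flagged, never silently zero
  geom <- tube_geometry(1, 10)
  empty <- threshold_frame(matrix(0, 3, 10), threshold_spec(level = 0.5), geom)
  expect_warning(v <- compute_com(empty), class = "flytube_empty_mask")
  expect_true(is.na(v))
})

test_that("avoidance index counts halves, with the odd-width midline rule", {
  expect_identical(compute_ai(mask_from_counts(c(2, 3, 0, 0))), 1)
  expect_identical(compute_ai(mask_from_counts(c(2, 1, 1, 2))), 0)
  # 3 odorant-half vs 1 solvent-half pixels
  expect_equal(compute_ai(mask_from_counts(c(3, 0, 0, 1))), 0.5)
  # odd width: middle column in neither half but in the denominator
  expect_equal(compute_ai(mask_from_counts(c(1, 2, 1))), 0)
  expect_equal(compute_ai(mask_from_counts(c(3, 2, 1))), (3 - 1) / 6)
  # sign-flip option reports avoidance as positive
  m <- mask_from_counts(c(0, 0, 0, 4))
  expect_equal(compute_ai(m), -1)
  expect_equal(compute_ai(m, flip_sign = TRUE), 1)
  # all mass exactly on the odd-width midline: neither half, AI 0
  expect_equal(compute_ai(mask_from_positions(0.5, 3)), 0)
})

test_that("CoM and AI match brute-force oracles on randomized masks", {
  set.seed(42)
  for (i in 1:300) {
    rm_ <- random_mask()
    expect_equal(compute_com(rm_$mask),
                 brute_force_com(rm_$offsets, rm_$W), tolerance = 1e-12)
    expect_identical(compute_ai(rm_$mask), brute_force_ai(rm_$offsets, rm_$W))
  }
})

test_that("mask statistics are invariant to monotone intensity rescaling", {
  set.seed(7)
  fr <- matrix(runif(30 * 80), 30, 80)
  geom <- tube_geometry(5, 76)
  m1 <- threshold_frame(fr, threshold_spec(level = 0.7), geom)
  # monotone rescale preserving crossings of 0.7 -> crossings of 0.7^2
  m2 <- threshold_frame(fr^2, threshold_spec(level = 0.49), geom)
  expect_identical(compute_com(m1), compute_com(m2))
  expect_identical(compute_ai(m1), compute_ai(m2))
})

test_that("mirroring a mask reflects CoM and negates AI", {
  set.seed(11)
  for (i in 1:50) {
    W <- sample(2:60, 1)
    counts <- rpois(W, 0.5)
    if (sum(counts) == 0) counts[1] <- 1
    m <- mask_from_counts(counts)
    m_ref <- mask_from_counts(rev(counts))
    expect_equal(compute_com(m_ref), 1 - compute_com(m), tolerance = 1e-12)
    expect_equal(compute_ai(m_ref), -compute_ai(m))
    expect_true(compute_com(m) >= 0 && compute_com(m) <= 1)
    expect_true(abs(compute_ai(m)) <= 1)
  }
})

test_that("odorant-end orientation measures offsets from the correct side", {
  fr <- frame_with_pixels(3, 10, list(c(1, 9)))
  spec <- threshold_spec(level = 0.5)
  com_left <- compute_com(threshold_frame(fr, spec, tube_geometry(1, 10, "left")))
  com_right <- compute_com(threshold_frame(fr, spec, tube_geometry(1, 10, "right")))
  expect_equal(com_left, 8 / 9)
  expect_equal(com_right, 1 / 9)
})

test_that("track_stack produces a timestamped series and carries empties as NA", {
  spec <- threshold_spec(level = 0.5)
  geom <- tube_geometry(1, 11)
  far <- frame_with_pixels(3, 11, list(c(1, 11)))          # CoM 1.0
  counts_fr <- frame_with_pixels(3, 11, list(c(1, 3), c(2, 3), c(1, 9))) # CoM 0.4
  blank <- matrix(0, 3, 11)

  s <- track_stack(list(far, counts_fr), spec, geom, fps = 1)
  expect_s3_class(s, "com_series")
  expect_equal(s$com, c(1, 0.4))
  expect_equal(s$time_s, c(0, 1))

  s2 <- track_stack(list(far, blank, counts_fr), spec, geom)
  expect_true(is.na(s2$com[2]) && !anyNA(s2$com[-2]))
  expect_equal(s2$n_pixels, c(1L, 0L, 3L))

  # identical frames give a constant series
  s3 <- track_stack(list(counts_fr, counts_fr, counts_fr), spec, geom, fps = 0.1)
  expect_equal(unique(s3$com), 0.4)
  expect_equal(s3$time_s, c(0, 10, 20))

  expect_error(track_stack(list(), spec, geom), class = "flytube_empty_stack")
})
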