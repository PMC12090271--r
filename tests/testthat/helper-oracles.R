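# Independent oracles, deliberately brute-force and free of any package code.

# mean of normalized flagged-pixel coordinates, by explicit loop over the
# pixel list
brute_force_com <- function(x_offsets, L) {
  total <- 0
  for (x in x_offsets) total <- total + x / (L - 1)
  total / length(x_offsets)
}

# direct half-counts (odd L: middle column in neither half, still in the
# denominator)
brute_force_ai <- function(x_offsets, L) {
  n_odor <- 0; n_solv <- 0
  for (x in x_offsets) {
    if (L %% 2 == 0) {
      if (x <= L / 2 - 1) n_odor <- n_odor + 1 else n_solv <- n_solv + 1
    } else {
      mid <- (L - 1) / 2
      if (x < mid) n_odor <- n_odor + 1
      if (x > mid) n_solv <- n_solv + 1
    }
  }
  (n_odor - n_solv) / length(x_offsets)
}

# exact two-sided Mann-Whitney p by full enumeration of all
# choose(n1 + n2, n1) group labelings (no ties assumed)
enumerate_mw <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    ra <- rank(pooled)[idx]
    sum(ra) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  labelings <- utils::combn(n1 + n2, n1)
  u_all <- apply(labelings, 2, u_of)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
enumerate_signed_rank <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p_lo <- mean(v_all <= v_obs)
  p_hi <- mean(v_all >= v_obs)
  list(v = v_obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# hand-rolled Cohen's d with (n-1)-weighted pooled SD
hand_cohens_d <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}
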