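test_that("Mann-Whitney matches the enumeration oracle on small samples", {
  # fully separated, 3 vs 3: exact two-sided p from all 20 labelings
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  or <- enumerate_mw(a, b)
  expect_equal(or$p, 0.1)
  res <- mann_whitney(a, b)
  expect_true(res$exact)
  expect_equal(res$statistic, or$u)
  expect_equal(res$p.value, or$p)

  # randomized small samples, no ties
  set.seed(14)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.5)
    or <- enumerate_mw(x, y)
    res <- mann_whitney(x, y)
    expect_equal(res$statistic, or$u)
    expect_equal(res$p.value, or$p, tolerance = 1e-12)
  }

  # identical samples: midranks give U = n1 * n2 / 2
  expect_equal(mann_whitney(rep(1, 4), rep(1, 5))$statistic, 10)
  expect_error(mann_whitney(numeric(0), 1:3), class = "flytube_bad_argument")
})

test_that("paired Wilcoxon matches sign-pattern enumeration and is antisymmetric", {
  a <- c(3.1, 4.2, 5.0, 6.3, 7.7, 8.1)
  b <- a + c(1, 1.1, 0.9, 1.2, 0.8, 1.05) # all-positive, untied shifts, n = 6
  or <- enumerate_signed_rank(b, a)
  expect_equal(or$p, 0.03125)
  res <- wilcoxon_paired(b, a)
  expect_true(res$exact)
  expect_equal(res$p.value, 0.03125)

  # swapping the arguments mirrors the statistic, p unchanged
  res_sw <- wilcoxon_paired(a, b)
  n_eff <- 6
  expect_equal(res_sw$statistic, n_eff * (n_eff + 1) / 2 - res$statistic)
  expect_equal(res_sw$p.value, res$p.value)

  # randomized paired samples, no zero or tied differences
  set.seed(9)
  for (i in 1:25) {
    n <- sample(4:9, 1)
    x <- rnorm(n); y <- x + rnorm(n, 0.3)
    or <- enumerate_signed_rank(x, y)
    expect_equal(wilcoxon_paired(x, y)$p.value, or$p, tolerance = 1e-12)
  }

  expect_warning(out <- wilcoxon_paired(c(1, 2), c(1, 2)),
                 class = "flytube_degenerate_test")
  expect_true(is.na(out$p.value))
  expect_error(wilcoxon_paired(1:3, 1:4), class = "flytube_bad_argument")
})

test_that("rank tests are invariant under monotone transformation of the data", {
  set.seed(77)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(6, 1)
    f <- function(v) exp(v) + v^3 / 10 # strictly increasing
    expect_equal(mann_whitney(x, y)$p.value, mann_whitney(f(x), f(y))$p.value)
    g <- list(a = rnorm(5), b = rnorm(5, 1), c = rnorm(5, 2))
    kd1 <- kruskal_dunn(g)
    kd2 <- kruskal_dunn(lapply(g, f))
    expect_equal(kd1$omnibus$p.value, kd2$omnibus$p.value)
    expect_equal(kd1$pairwise$p_adjusted, kd2$pairwise$p_adjusted)
  }
})

test_that("exact and normal-approximation branches agree near the branch boundary", {
  # exhaustive comparison over every attainable U at n1 = n2 = 8
  n1 <- 8; n2 <- 8
  u <- 0:(n1 * n2)
  p_exact <- vapply(u, function(x) {
    min(1, 2 * min(pwilcox(x, n1, n2), 1 - pwilcox(x - 1, n1, n2)))
  }, 1)
  mu <- n1 * n2 / 2
  sdev <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  p_norm <- pmin(1, 2 * pnorm(-(abs(u - mu) - 0.5) / sdev))
  # discreteness at these sizes caps the attainable gap just above 1%
  expect_lt(max(abs(p_exact - p_norm)), 0.012)
  # in the decision-relevant tail (p <= 0.10) the branches agree to < 0.5%
  tail_region <- pmin(p_exact, p_norm) <= 0.10
  expect_lt(max(abs(p_exact - p_norm)[tail_region]), 0.005)
})

test_that("null Monte-Carlo rejection rates sit at the nominal 5% level", {
  set.seed(2024)
  n_mc <- 10000
  rej_mw <- mean(replicate(n_mc, {
    mann_whitney(rnorm(8), rnorm(8))$p.value <= 0.05
  }))
  expect_gte(rej_mw, 0.04)
  expect_lte(rej_mw, 0.06)

  rej_sr <- mean(replicate(n_mc, {
    wilcoxon_paired(rnorm(14), rnorm(14))$p.value <= 0.05
  }))
  expect_gte(rej_sr, 0.04)
  expect_lte(rej_sr, 0.06)
})

test_that("Kruskal-Wallis with Dunn's post hoc isolates the shifted group", {
  set.seed(8)
  g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8, 4))
  kd <- kruskal_dunn(g)
  expect_lt(kd$omnibus$p.value, 0.01)
  pw <- kd$pairwise
  involves_c <- pw$group1 == "c" | pw$group2 == "c"
  expect_true(max(pw$p_adjusted[involves_c]) < min(pw$p_adjusted[!involves_c]))
  expect_true(all(pw$p_adjusted >= pw$p_raw))
  expect_true(all(pw$p_adjusted <= 1))

  # two-group degenerate call ranks datasets like Mann-Whitney does
  set.seed(12)
  p_kd <- c(); p_mw <- c()
  for (i in 1:8) {
    x <- rnorm(6); y <- rnorm(6, runif(1, 0, 2))
    p_kd[i] <- kruskal_dunn(list(x = x, y = y))$pairwise$p_raw
    p_mw[i] <- mann_whitney(x, y)$p.value
  }
  expect_equal(order(p_kd), order(p_mw))

  # null calibration of the adjusted p-values
  set.seed(99)
  rej <- mean(replicate(400, {
    kd <- kruskal_dunn(list(a = rnorm(6), b = rnorm(6), c = rnorm(6)))
    min(kd$pairwise$p_adjusted) <= 0.05
  }))
  expect_lt(rej, 0.08) # Bonferroni keeps the family-wise rate at or below ~5%

  expect_error(kruskal_dunn(list(a = 1:3, b = numeric(0))),
               class = "flytube_bad_argument")
})
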