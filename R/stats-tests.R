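#' Mann-Whitney U test (two independent samples)
#'
#' Rank-sum comparison of two groups, reported as the U statistic with a
#' two-sided p value. Without ties and with small samples the p value is
#' exact (full enumeration of rank assignments); with ties or larger
#' samples a normal approximation with the midrank tie correction is used.
#' This is the standard two-group comparison for replicate-mean CoMs.
#'
#' @param a,b Numeric samples, each with >= 1 value.
#' @return A one-row tibble: `statistic` (U for `a` vs `b`), `p.value`,
#'   `n_a`, `n_b`, `exact` (logical), `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(a, b) {
  .check_sample(a, "a"); .check_sample(b, "b")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && min(length(a), length(b)) <= 8 && max(length(a), length(b)) < 50
  ht <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = !exact, alternative = "two.sided")
  )
  tibble::tibble(
    statistic = unname(ht$statistic),
    p.value = ht$p.value,
    n_a = length(a), n_b = length(b),
    exact = exact,
    method = "Mann-Whitney U"
  )
}

#' Paired Wilcoxon signed-rank test
#'
#' @param a,b Paired numeric samples of equal length; at least one nonzero
#'   difference is required.
#' @return A one-row tibble: `statistic` (V, signed-rank sum of positive
#'   differences of `a - b`), `p.value`, `n`, `exact`, `method`.
#' @examples
#' wilcoxon_paired(1:6 + 1, 1:6)
#' @export
wilcoxon_paired <- function(a, b) {
  .check_sample(a, "a"); .check_sample(b, "b")
  if (length(a) != length(b)) {
    ft_abort("Paired samples must have equal length.", "flytube_bad_argument")
  }
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) {
    warn("All paired differences are zero: test undefined.",
         class = "flytube_degenerate_test")
    return(tibble::tibble(statistic = NA_real_, p.value = NA_real_,
                          n = length(a), exact = FALSE,
                          method = "paired Wilcoxon signed-rank"))
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- !ties && length(d) <= 15
  ht <- suppressWarnings(
    wilcox.test(a, b, paired = TRUE, exact = exact, correct = !exact,
                alternative = "two.sided")
  )
  tibble::tibble(
    statistic = unname(ht$statistic),
    p.value = ht$p.value,
    n = length(a),
    exact = exact,
    method = "paired Wilcoxon signed-rank"
  )
}

#' Kruskal-Wallis omnibus with Dunn's post hoc comparisons
#'
#' The multi-group workflow for replicate-mean CoMs: a Kruskal-Wallis
#' rank test across all groups, followed by Dunn's z-tests on every pair
#' using the pooled midranks with tie correction, Bonferroni-adjusted over
#' the tested pairs.
#'
#' @param data A data frame with the value and group columns, or a named
#'   list of numeric vectors.
#' @param value,group Column names (used when `data` is a data frame).
#' @return A `kruskal_dunn` object: list with `omnibus` (one-row tibble:
#'   `statistic`, `df`, `p.value`) and `pairwise` (tibble: `group1`,
#'   `group2`, `z`, `p_raw`, `p_adjusted`). `tidy()` returns the pairwise
#'   table; `glance()` the omnibus row.
#' @examples
#' kruskal_dunn(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(9, 10, 11)))
#' @export
kruskal_dunn <- function(data, value = "value", group = "group") {
  if (is.data.frame(data)) {
    groups <- split(data[[value]], data[[group]])
  } else if (is.list(data)) {
    groups <- data
  } else {
    ft_abort("`data` must be a data frame or a named list of samples.",
             "flytube_bad_argument")
  }
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    ft_abort("Need >= 2 non-empty groups.", "flytube_bad_argument")
  }
  purrr::walk(groups, .check_sample, name = "group sample")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }

  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  omni <- kruskal.test(x, g)

  # Dunn's z-tests on pooled midranks with tie correction
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  tie_sizes <- table(x)
  tie_corr <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  pw <- purrr::map(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[g1]] + 1 / n[[g2]]))
    z <- (rbar[[g1]] - rbar[[g2]]) / se
    tibble::tibble(group1 = g1, group2 = g2, z = z,
                   p_raw = 2 * pnorm(-abs(z)))
  })
  pw <- dplyr::bind_rows(pw)
  pw$p_adjusted <- pmin(1, pw$p_raw * nrow(pw))

  structure(
    list(
      omnibus = tibble::tibble(statistic = unname(omni$statistic),
                               df = unname(omni$parameter),
                               p.value = omni$p.value),
      pairwise = pw
    ),
    class = "kruskal_dunn"
  )
}

#' @export
#' @method tidy kruskal_dunn
#' @rdname kruskal_dunn
#' @param x,... A `kruskal_dunn` object and unused arguments, for methods.
tidy.kruskal_dunn <- function(x, ...) x$pairwise

#' @export
#' @method glance kruskal_dunn
#' @rdname kruskal_dunn
glance.kruskal_dunn <- function(x, ...) x$omnibus

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.4g, df = %d, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p.value))
  cat("Dunn's pairwise comparisons (Bonferroni-adjusted):\n")
  print(x$pairwise)
  invisible(x)
}

.check_sample <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1 || any(!is.finite(x))) {
    ft_abort(sprintf("Sample `%s` must be non-empty finite numeric.", name),
             "flytube_bad_argument")
  }
}
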