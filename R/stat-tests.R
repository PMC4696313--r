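# P-value machinery: pooled permutation test for differential Shannon
# entropy, Fligner-Killeen on log-transformed data for differential CV,
# Welch t-test for differential expression, multiplicity adjustment.

# normalized base-2 entropy of each column of a positive matrix;
# hot loop of the permutation test, so no per-column validation here
.col_entropy <- function(m) {
  p <- sweep(m, 2L, colSums(m), "/")
  -colSums(p * log2(p)) / log2(nrow(m))
}

#' Permutation p-value for differential Shannon entropy
#'
#' No standard reference distribution fits differential Shannon entropy,
#' so its p-value is obtained by resampling.  The observed
#' `DSE = |SE1 - SE2|` is computed on the original grouping; all
#' `n1 + n2` values are then pooled, and in each of `nperm` iterations
#' the pooled vector is randomly permuted, the first `n1` elements taken
#' as group 1 and the last `n2` as group 2, and DSE recomputed.  The raw
#' p-value is the proportion of recomputed DSE values at least as large
#' as the observed one; DSE is nonnegative, so the test is one-tailed in
#' the absolute entropy difference.
#'
#' With the default estimator `count / nperm` a p-value of exactly 0 is
#' possible.  `bias_correct = TRUE` switches to
#' `(count + 1) / (nperm + 1)`, which is never 0 and is the usual
#' finite-sample-valid estimator.
#'
#' Internally the pooled vector is put into a canonical (sorted) order
#' and each permutation assigns the first `min(n1, n2)` elements to one
#' group and the rest to the other.  A random split into groups of
#' sizes `n1` and `n2` has the same distribution whichever group is
#' listed first, so this changes nothing statistically, but it makes
#' the seeded result invariant to swapping the two conditions and to
#' the sample order within each condition.
#'
#' @param list1,list2 Strictly positive numeric vectors, each of length
#'   at least 2.
#' @param nperm Number of permutations (default 1000).
#' @param seed Optional integer seed; with a seed the result is
#'   deterministic.
#' @param bias_correct Use the add-one estimator (default `FALSE`).
#' @return A list with `statistic` (the observed DSE) and `p.value`.
#' @examples
#' set.seed(1)
#' dse_permutation_pvalue(rlnorm(10), rlnorm(10), nperm = 200, seed = 7)
#' @export
dse_permutation_pvalue <- function(list1, list2, nperm = 1000L,
                                   seed = NULL, bias_correct = FALSE) {
  check_values(list1, min_n = 2L, positive = TRUE, what = "list1")
  check_values(list2, min_n = 2L, positive = TRUE, what = "list2")
  if (!is.numeric(nperm) || length(nperm) != 1L || nperm < 1) {
    stop("nperm must be a positive integer", call. = FALSE)
  }
  nperm <- as.integer(nperm)
  obs <- abs(shannon_entropy(list1) - shannon_entropy(list2))

  k <- min(length(list1), length(list2))
  pooled <- sort(c(list1, list2))
  n <- length(pooled)
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
  }
  # one permutation per column; entropy of the two blocks is vectorized
  idx <- vapply(seq_len(nperm), function(i) sample.int(n), integer(n))
  perm <- matrix(pooled[idx], nrow = n, ncol = nperm)
  dse_perm <- abs(.col_entropy(perm[seq_len(k), , drop = FALSE]) -
                    .col_entropy(perm[-seq_len(k), , drop = FALSE]))
  count <- sum(dse_perm >= obs)
  p <- if (bias_correct) (count + 1) / (nperm + 1) else count / nperm
  list(statistic = obs, p.value = p)
}

#' Fligner-Killeen p-value for differential coefficient of variation
#'
#' Tests homogeneity of variances between the two groups after a log
#' transform, which turns differences in relative variability (CV) into
#' differences in log-scale spread.  The Fligner-Killeen test is
#' rank-based and median-centered, hence robust to non-normality, and is
#' invariant to the base of the logarithm (a change of base rescales all
#' absolute deviations by a common factor, leaving ranks unchanged);
#' the natural log is used.  The statistic is referred to a chi-square
#' distribution with one degree of freedom (two groups).
#'
#' @param list1,list2 Strictly positive numeric vectors, each of length
#'   at least 2.
#' @return A list with `statistic` (the chi-square statistic) and
#'   `p.value`.  When both groups are constant on the log scale every
#'   pooled absolute deviation is zero; the statistic is then undefined
#'   and `p.value = 1` is returned with a warning.
#' @export
fligner_killeen_pvalue <- function(list1, list2) {
  check_values(list1, min_n = 2L, positive = TRUE, what = "list1")
  check_values(list2, min_n = 2L, positive = TRUE, what = "list2")
  l1 <- log(list1)
  l2 <- log(list2)
  dev <- c(abs(l1 - stats::median(l1)), abs(l2 - stats::median(l2)))
  if (stats::var(dev) == 0) {
    # all normal scores coincide, zero score variance: no evidence of
    # heterogeneity at all
    warning("all median-centered absolute deviations are equal; ",
            "Fligner-Killeen statistic undefined, returning p = 1")
    return(list(statistic = 0, p.value = 1))
  }
  ft <- stats::fligner.test(
    x = c(l1, l2),
    g = factor(rep.int(c(1L, 2L), c(length(l1), length(l2))))
  )
  list(statistic = unname(ft$statistic), p.value = ft$p.value)
}

#' Welch t-test p-value for differential expression
#'
#' Two-sided two-sample t-test without the equal-variance assumption.
#' Included as a simple magnitude-difference companion to the two
#' variability metrics, not as a replacement for moderated differential
#' expression models.
#'
#' @param list1,list2 Numeric vectors, each of length at least 2.
#' @return A list with `statistic` (the t statistic, `NA` in the
#'   degenerate all-constant cases) and `p.value`.  When both groups are
#'   constant the test is undefined: `p.value` is 1 when the two
#'   constants agree and 0 when they differ, each with a warning.
#' @export
de_ttest_pvalue <- function(list1, list2) {
  check_values(list1, min_n = 2L, what = "list1")
  check_values(list2, min_n = 2L, what = "list2")
  if (stats::sd(list1) == 0 && stats::sd(list2) == 0) {
    if (mean(list1) == mean(list2)) {
      warning("both groups constant and equal; returning p = 1")
      return(list(statistic = NA_real_, p.value = 1))
    }
    warning("both groups constant with different values; returning p = 0")
    return(list(statistic = NA_real_, p.value = 0))
  }
  tt <- stats::t.test(list1, list2)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Multiple-testing adjustment of raw p-values
#'
#' Position-preserving adjusted p-values for the Bonferroni, Holm,
#' Hochberg, Benjamini-Hochberg (`"bh"`) and Benjamini-Yekutieli
#' (`"by"`) procedures, clipped to 1.  The number of hypotheses is the
#' length of `p` (`NA` entries are not counted and stay `NA`).
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (`NA` allowed).
#' @param method One of `"bonferroni"`, `"holm"`, `"hochberg"`, `"bh"`,
#'   `"by"` (case-insensitive).
#' @return Numeric vector of adjusted p-values, same length and order as
#'   `p`.
#' @examples
#' adjust_pvalues(c(0.01, 0.04), "bonferroni")        # 0.02 0.08
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh")    # all 0.04
#' @export
adjust_pvalues <- function(p, method = "bh") {
  valid <- c("bonferroni", "holm", "hochberg", "bh", "by")
  if (!is.character(method) || length(method) != 1L ||
      !(tolower(method) %in% valid)) {
    stop("unknown adjustment method ",
         if (is.character(method)) paste0("\"", method, "\""),
         "; valid methods: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(p) || length(p) < 1L) {
    stop("p must be a non-empty numeric vector", call. = FALSE)
  }
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("raw p-values must lie in [0, 1]", call. = FALSE)
  }
  method <- switch(tolower(method),
                   bh = "BH", by = "BY", tolower(method))
  # count only tested hypotheses: NA rows carry no test
  stats::p.adjust(p, method = method, n = sum(ok))
}
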