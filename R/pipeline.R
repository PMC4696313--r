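# Orchestration: validation, shifting, per-row statistics and p-values,
# adjustment, sorting, top-n filtering.

.metrics <- c("dse", "dcv", "de")
.otypes <- c("v", "bv", "p", "pa", "bp", "bpa")

.stat_names <- function(metric) {
  switch(metric,
         dse = c("SE1", "SE2", "DSE"),
         dcv = c("CV1", "CV2", "DCV"),
         de  = c("mean1", "mean2", "DE"))
}

# coerce matrix / data.frame (optionally with a label column) to a
# row-labeled numeric matrix
as_expression_matrix <- function(x, name = "matrix") {
  if (is.data.frame(x)) {
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(name, " must be a numeric matrix or data frame", call. = FALSE)
  }
  if (is.null(rownames(x))) {
    stop(name, " must carry row labels (rownames)", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop(name, " has duplicate row labels: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]),
               collapse = ", "), call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 2L) {
    stop(name, " must have at least 1 row and 2 columns", call. = FALSE)
  }
  x
}

#' Validate and align a pair of condition matrices
#'
#' Confirms that the two matrices carry identical row labels in
#' identical order and that, after any shifts have been applied, every
#' finite entry is strictly positive (logarithms are taken downstream).
#'
#' @param m1,m2 Row-labeled numeric matrices (or data frames), one per
#'   condition.
#' @param require_positive Check positivity (default `TRUE`).
#' @return Invisibly, `list(m1, m2)` as numeric matrices.
#' @export
validate_and_align <- function(m1, m2, require_positive = TRUE) {
  m1 <- as_expression_matrix(m1, "m1")
  m2 <- as_expression_matrix(m2, "m2")
  l1 <- rownames(m1)
  l2 <- rownames(m2)
  if (length(l1) != length(l2) || any(l1 != l2)) {
    bad <- if (length(l1) != length(l2)) {
      min(length(l1), length(l2)) + 1L
    } else {
      which(l1 != l2)[1L]
    }
    stop("row labels differ between the two matrices, first at row ", bad,
         " (\"", if (bad <= length(l1)) l1[bad] else "<absent>", "\" vs \"",
         if (bad <= length(l2)) l2[bad] else "<absent>", "\"); ",
         "both matrices must carry identical labels in identical order",
         call. = FALSE)
  }
  if (require_positive) {
    for (k in 1:2) {
      m <- if (k == 1L) m1 else m2
      bad <- which(is.finite(m) & m <= 0, arr.ind = TRUE)
      if (nrow(bad)) {
        stop("matrix m", k, " contains a non-positive entry at row \"",
             rownames(m)[bad[1L, 1L]], "\", column ", bad[1L, 2L],
             " (value ", m[bad[1L, , drop = FALSE]], "); entropy and the ",
             "log-based variance test require positive data -- consider ",
             "the shift argument (e.g. shift = c(\"auto\", \"auto\"))",
             call. = FALSE)
      }
    }
  }
  invisible(list(m1 = m1, m2 = m2))
}

# deterministic per-row RNG substream: results do not depend on the
# order in which rows are evaluated (Lehmer-style mix, stays < 2^31)
derive_row_seed <- function(seed, row) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + row * 16807) %%
               2147483647)
}

#' Differential-variability analysis of two condition matrices
#'
#' The single entry point of the package.  For every row (feature) of
#' the two label-aligned matrices it computes a per-condition statistic
#' and its absolute difference -- normalized Shannon entropy and DSE
#' (`metric = "dse"`), coefficient of variation and DCV (`"dcv"`), or
#' mean and DE (`"de"`) -- and, for the p-value output types, a raw
#' p-value (pooled permutation test, Fligner-Killeen test on
#' log-transformed data, or Welch t-test respectively) plus a
#' multiplicity-adjusted p-value computed over all tested rows.
#'
#' Output types (`otype`) control the column schema and sort key:
#' \describe{
#'   \item{`"v"`}{2 columns (`stat1`, `stat2`), sorted by decreasing
#'     absolute difference.}
#'   \item{`"bv"`}{3 columns (`stat1`, `stat2`, `diff`), sorted by
#'     decreasing `diff`.}
#'   \item{`"p"` / `"pa"`}{5 columns (`stat1`, `stat2`, `diff`,
#'     `p.value`, `adj.p.value`), sorted by increasing raw / adjusted
#'     p-value.}
#'   \item{`"bp"` / `"bpa"`}{the same 5 columns, sorted by decreasing
#'     `diff`.}
#' }
#' Ties are broken by row label (C-locale lexicographic) so output is
#' fully deterministic.  Rows left with fewer than two finite values in
#' either condition after missing-value removal are reported as `NA`,
#' sorted last, and excluded from the adjustment's hypothesis count.
#'
#' Non-finite entries (`NA`, `NaN`, `Inf`) are dropped per row and per
#' condition before any statistic is computed; the entropy normalization
#' uses the number of values actually retained.
#'
#' @param m1,m2 Row-labeled numeric matrices (or data frames) for
#'   condition 1 (e.g. case) and condition 2 (e.g. control); identical
#'   row labels in identical order.
#' @param metric `"dse"`, `"dcv"` or `"de"`.
#' @param otype Output type, see Details (default `"bv"`).
#' @param ntop Number of top rows to return; `NULL` (default) keeps all.
#' @param nperm Permutations for the DSE test (default 1000).
#' @param shift Length-2 specification of additive biases for `m1` and
#'   `m2`: each element a nonnegative number or `"auto"` (see
#'   [resolve_shift()]).  Default `c(0, 0)`.
#' @param padjust Adjustment method, see [adjust_pvalues()] (default
#'   `"bh"`).
#' @param seed Optional integer seed governing all per-row permutation
#'   streams (substreams are derived from the seed and the row index).
#' @param bias_correct Passed to [dse_permutation_pvalue()].
#' @return A data frame with the rows described above, feature labels as
#'   row names, and attributes `metric`, `otype`, `sort_key` and
#'   `shift` (the two resolved shifts).
#' @examples
#' sim <- generate_pair(sim_spec(n_rows = 20, seed = 1))
#' head(run_analysis(sim$case, sim$control, metric = "dcv",
#'                   otype = "bv", ntop = 5))
#' @export
run_analysis <- function(m1, m2, metric = c("dse", "dcv", "de"),
                         otype = "bv", ntop = NULL, nperm = 1000L,
                         shift = c(0, 0), padjust = "bh", seed = NULL,
                         bias_correct = FALSE) {
  metric <- match.arg(metric)
  if (!is.character(otype) || length(otype) != 1L ||
      !(otype %in% .otypes)) {
    stop("otype must be one of: ", paste(.otypes, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(ntop) &&
      (!is.numeric(ntop) || length(ntop) != 1L || ntop < 1)) {
    stop("ntop must be NULL or a positive integer", call. = FALSE)
  }
  m1 <- as_expression_matrix(m1, "m1")
  m2 <- as_expression_matrix(m2, "m2")
  if (length(shift) != 2L) {
    stop("shift must have two elements (one per matrix)", call. = FALSE)
  }
  s1 <- resolve_shift(m1, if (is.list(shift)) shift[[1L]] else shift[1L])
  s2 <- resolve_shift(m2, if (is.list(shift)) shift[[2L]] else shift[2L])
  m1 <- apply_shift(m1, s1)
  m2 <- apply_shift(m2, s2)
  validate_and_align(m1, m2)

  want_p <- otype %in% c("p", "pa", "bp", "bpa")
  n_rows <- nrow(m1)
  labels <- rownames(m1)
  stat1 <- stat2 <- diff <- p_raw <- rep(NA_real_, n_rows)
  n_dropped <- 0L

  for (i in seq_len(n_rows)) {
    v1 <- m1[i, ]
    v2 <- m2[i, ]
    v1 <- v1[is.finite(v1)]
    v2 <- v2[is.finite(v2)]
    if (length(v1) < 2L || length(v2) < 2L) {
      n_dropped <- n_dropped + 1L
      next
    }
    tr <- diff_metric(v1, v2, metric)
    stat1[i] <- tr$stat1
    stat2[i] <- tr$stat2
    diff[i] <- tr$diff
    if (want_p) {
      p_raw[i] <- switch(
        metric,
        dse = dse_permutation_pvalue(
          v1, v2, nperm = nperm,
          seed = if (is.null(seed)) NULL else derive_row_seed(seed, i),
          bias_correct = bias_correct)$p.value,
        dcv = fligner_killeen_pvalue(v1, v2)$p.value,
        de  = de_ttest_pvalue(v1, v2)$p.value
      )
    }
  }
  if (n_dropped > 0L) {
    warning(n_dropped, " row(s) had fewer than 2 finite values in at ",
            "least one condition; reported as NA and excluded from the ",
            "multiple-testing correction")
  }

  nm <- .stat_names(metric)
  out <- data.frame(stat1, stat2, row.names = labels)
  names(out) <- nm[1:2]
  if (otype != "v") {
    out[[nm[3L]]] <- diff
  }
  sort_key <- "value"
  key <- diff
  decreasing <- TRUE
  if (want_p) {
    p_adj <- adjust_pvalues(p_raw, padjust)
    out[["p.value"]] <- p_raw
    out[["adj.p.value"]] <- p_adj
    if (otype == "p") {
      sort_key <- "p_raw"
      key <- p_raw
      decreasing <- FALSE
    } else if (otype == "pa") {
      sort_key <- "p_adjusted"
      key <- p_adj
      decreasing <- FALSE
    }
  }
  ord <- order(is.na(key), if (decreasing) -key else key, labels,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  if (!is.null(ntop)) {
    out <- out[seq_len(min(as.integer(ntop), nrow(out))), , drop = FALSE]
  }
  attr(out, "metric") <- metric
  attr(out, "otype") <- otype
  attr(out, "sort_key") <- sort_key
  attr(out, "shift") <- c(s1, s2)
  out
}
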