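# Per-row dispersion statistics and their case/control differences.

check_values <- function(values, min_n = 2L, positive = FALSE,
                         what = "values") {
  if (!is.numeric(values)) {
    stop(what, " must be numeric", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop(what, " contains non-finite entries at position(s) ",
         paste(which(!is.finite(values)), collapse = ", "),
         call. = FALSE)
  }
  if (length(values) < min_n) {
    stop(what, " has ", length(values), " value(s); at least ", min_n,
         " required", call. = FALSE)
  }
  if (positive && any(values <= 0)) {
    stop(what, " contains non-positive entries at position(s) ",
         paste(which(values <= 0), collapse = ", "),
         "; all values must be strictly positive", call. = FALSE)
  }
  invisible(values)
}

#' Normalized Shannon entropy of a positive vector
#'
#' Treats the values as an unnormalized discrete distribution: each value
#' is divided by the vector sum to give a proportion, and the base-2
#' Shannon entropy of those proportions is divided by `log2(n)` so that
#' the result lies in `[0, 1]`.  A constant vector has entropy exactly 1
#' (uniform proportions); entropy approaches 0 as a single value comes to
#' dominate the sum.  Note the resulting convention: *lower* entropy
#' corresponds to *more* dispersion among the values.
#'
#' The statistic is invariant to multiplying all values by a positive
#' constant (proportions are unchanged) but not to additive shifts.
#'
#' @param values Numeric vector of at least two strictly positive, finite
#'   values.
#' @return A single number in `[0, 1]`.
#' @examples
#' shannon_entropy(c(4, 4, 4, 4))  # 1
#' shannon_entropy(c(1, 3))        # 0.8112781
#' @seealso [coefficient_of_variation()], [diff_metric()]
#' @export
shannon_entropy <- function(values) {
  check_values(values, min_n = 2L, positive = TRUE)
  # uniform proportions give exactly log2(n)/log2(n); return 1 without
  # trusting floating-point division to round all proportions identically
  if (max(values) == min(values)) {
    return(1)
  }
  p <- values / sum(values)
  se <- -sum(p * log2(p)) / log2(length(values))
  min(max(se, 0), 1)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the absolute
#' value of the sample mean.  Scale-invariant, translation-variant,
#' range `[0, Inf)`.
#'
#' @param values Numeric vector of at least two finite values with
#'   nonzero mean.
#' @return A single nonnegative number.
#' @examples
#' coefficient_of_variation(c(2, 4, 6))  # 0.5
#' @export
coefficient_of_variation <- function(values) {
  check_values(values, min_n = 2L)
  m <- mean(values)
  if (m == 0) {
    stop("coefficient of variation undefined: mean of values is zero",
         call. = FALSE)
  }
  stats::sd(values) / abs(m)
}

#' Arithmetic mean of a vector
#'
#' @param values Numeric vector with at least one finite value.
#' @return The arithmetic mean.
#' @export
row_mean <- function(values) {
  check_values(values, min_n = 1L)
  mean(values)
}

#' Per-feature difference statistic between two conditions
#'
#' Computes the chosen per-condition statistic for each of two value
#' lists and the absolute difference between them: `"dse"` is the
#' differential Shannon entropy `|SE1 - SE2|`, `"dcv"` the differential
#' coefficient of variation `|CV1 - CV2|`, and `"de"` the differential
#' expression `|mean1 - mean2|`.  The two lists may have different
#' lengths; the result is symmetric in the list arguments up to the
#' swapping of `stat1` and `stat2`.
#'
#' @param list1,list2 Numeric vectors (one feature, one condition each).
#'   For `"dse"` both must be strictly positive with length at least 2.
#' @param metric One of `"dse"`, `"dcv"`, `"de"`.
#' @return A list with components `stat1`, `stat2` and
#'   `diff = abs(stat1 - stat2)`.
#' @examples
#' diff_metric(c(4, 4), c(1, 3), "dse")$diff  # 0.1887219
#' diff_metric(c(2, 4, 6), c(1, 3), "de")$diff  # 2
#' @export
diff_metric <- function(list1, list2, metric = c("dse", "dcv", "de")) {
  metric <- match.arg(metric)
  f <- switch(metric,
              dse = shannon_entropy,
              dcv = coefficient_of_variation,
              de  = row_mean)
  s1 <- f(list1)
  s2 <- f(list2)
  list(stat1 = s1, stat2 = s2, diff = abs(s1 - s2))
}
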