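# Additive shifts that repair non-positive matrix entries before
# logarithm-based statistics are computed.

#' Resolve an additive shift for one matrix
#'
#' Entropy and the log-based variance test require strictly positive
#' data, but preprocessed expression matrices often contain zeros or
#' small negative values.  A shift specification is either a fixed
#' nonnegative number, returned unchanged, or the string `"auto"`: if the
#' matrix minimum `m` is already positive the automatic shift is 0;
#' otherwise it is `|m| + d`, where `d` is the smallest strictly positive
#' entry of the matrix (1 when no positive entry exists).  The automatic
#' rule guarantees a strictly positive post-shift minimum with a
#' data-scaled margin.  Results of entropy-based analyses depend on the
#' shift, so the resolved value should be reported alongside any result.
#'
#' @param mat Numeric matrix (non-finite entries are ignored when
#'   determining the automatic shift).
#' @param shift A single nonnegative number, or `"auto"`.
#' @return The resolved shift, a single nonnegative number.
#' @examples
#' resolve_shift(matrix(c(-2, 0.5, 3, 1), 2), "auto")  # 2.5
#' resolve_shift(matrix(1:4, 2), "auto")               # 0
#' @export
resolve_shift <- function(mat, shift) {
  if (is.character(shift)) {
    if (!identical(tolower(shift), "auto")) {
      # tolerate numeric strings: c("auto", 0) coerces both to character
      num <- suppressWarnings(as.numeric(shift))
      if (length(shift) == 1L && !is.na(num)) {
        return(resolve_shift(mat, num))
      }
      stop("shift must be a nonnegative number or \"auto\", got \"",
           shift, "\"", call. = FALSE)
    }
    v <- mat[is.finite(mat)]
    if (length(v) == 0L) {
      stop("cannot auto-resolve a shift: matrix has no finite entries",
           call. = FALSE)
    }
    m <- min(v)
    if (m > 0) {
      return(0)
    }
    pos <- v[v > 0]
    delta <- if (length(pos)) min(pos) else 1
    return(abs(m) + delta)
  }
  if (!is.numeric(shift) || length(shift) != 1L || !is.finite(shift) ||
      shift < 0) {
    stop("shift must be a single nonnegative number or \"auto\"",
         call. = FALSE)
  }
  as.numeric(shift)
}

#' Apply a resolved shift to a matrix
#'
#' @param mat Numeric matrix.
#' @param shift Nonnegative number, typically from [resolve_shift()].
#' @return `mat + shift`.
#' @export
apply_shift <- function(mat, shift) {
  mat + shift
}
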