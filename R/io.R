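# Delimited-file reading of condition matrices and writing of result
# tables.

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    stop("file is empty: ", path, call. = FALSE)
  }
  if (grepl("\t", first)) "\t" else ","
}

#' Read a row-labeled expression matrix from a delimited file
#'
#' Expects one feature per line with the label in `label_column`
#' (default: first) and numeric sample values in the remaining columns.
#' Recognized missing-value tokens are `NA`, `NaN` and the empty cell;
#' any other non-numeric cell is a parse error reported with its file
#' line and column.  Duplicate row labels are an error.
#'
#' @param path Path to a TSV or CSV file.
#' @param delimiter `"auto"` (default; tab if the first line contains
#'   one, comma otherwise), `"tab"` or `"comma"`.
#' @param header Whether the first line is a header (default `TRUE`).
#' @param label_column Index of the label column (default 1).
#' @return A numeric matrix with feature labels as row names.
#' @export
read_matrix <- function(path, delimiter = c("auto", "tab", "comma"),
                        header = TRUE, label_column = 1L) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  sep <- switch(delimiter, auto = .detect_sep(path), tab = "\t",
                comma = ",")
  raw <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE,
                           blank.lines.skip = FALSE)
  if (ncol(raw) < 3L) {
    stop("file ", path, " has fewer than 3 columns; need a label column ",
         "and at least 2 sample columns", call. = FALSE)
  }
  labels <- trimws(raw[[label_column]])
  if (anyDuplicated(labels)) {
    stop("duplicate row label(s) in ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- raw[, -label_column, drop = FALSE]
  cells <- trimws(as.matrix(vals))
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(raw),
                                 dimnames = list(labels, colnames(vals))))
  # read.table already maps the "NA" token to a true NA; empty and NaN
  # cells are the other recognized missing-value spellings
  missing_tok <- is.na(cells) | cells %in% c("", "NA", "NaN")
  bad <- which(is.na(num) & !missing_tok, arr.ind = TRUE)
  if (nrow(bad)) {
    line <- bad[1L, 1L] + if (header) 1L else 0L
    stop("cannot parse cell \"", cells[bad[1L, , drop = FALSE]],
         "\" at line ", line, ", data column ", bad[1L, 2L], " of ",
         path, call. = FALSE)
  }
  num[cells == "NaN" & !is.na(cells)] <- NA_real_
  num
}

#' Write a result table to a delimited file
#'
#' Writes a header line followed by one line per feature: the label
#' under the column name `feature`, then the result columns with
#' numbers rendered to `digits` significant digits and missing values
#' rendered as `NA`.  Reading the file back reproduces the table values
#' to the rendered precision.
#'
#' @param table A data frame as returned by [run_analysis()].
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param digits Significant digits for numeric rendering (default 6).
#' @export
write_result <- function(table, path, format = c("tsv", "csv"),
                         digits = 6L) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  txt <- data.frame(feature = rownames(table),
                    lapply(table, function(col) {
                      ifelse(is.na(col), "NA",
                             formatC(col, digits = digits, format = "g"))
                    }),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(txt, file = path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
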