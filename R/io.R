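#' Read a delimited numeric matrix
#'
#' Reads a TSV (or CSV) file into a numeric matrix, rows as data points.
#' The file must be rectangular and every cell must parse as a finite
#' number; violations are reported with the offending line or cell.
#'
#' @param path file path.
#' @param delim field delimiter, \code{"\t"} (default) or \code{","}.
#' @param header logical; if \code{TRUE} the first line holds column names.
#' @return numeric matrix (with column names if \code{header}).
#' @export
read_matrix <- function(path, delim = "\t", header = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("empty matrix file: %s", path))
  cells <- strsplit(lines, delim, fixed = TRUE)
  cn <- NULL
  first_data <- 1L
  if (header) {
    cn <- cells[[1L]]
    first_data <- 2L
    if (length(cells) < 2L) stop("header present but no data rows")
  }
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                 path, bad, widths[bad], widths[1L]))
  }
  data_cells <- cells[first_data:length(cells)]
  m <- matrix(NA_real_, length(data_cells), widths[1L])
  for (i in seq_along(data_cells)) {
    vals <- suppressWarnings(as.numeric(data_cells[[i]]))
    if (anyNA(vals) || any(!is.finite(vals))) {
      j <- which(is.na(vals) | !is.finite(vals))[1L]
      stop(sprintf("non-numeric cell in %s at row %d, column %d: '%s'",
                   path, i, j, data_cells[[i]][j]))
    }
    m[i, ] <- vals
  }
  if (!is.null(cn)) colnames(m) <- cn
  m
}

#' Write a numeric matrix as delimited text
#'
#' Values are written with 15 significant digits so a read/write
#' round-trip preserves them to (better than) 12 significant digits.
#'
#' @param m numeric matrix.
#' @param path output file path.
#' @param delim field delimiter.
#' @param col_names logical; write a header line from \code{colnames(m)}.
#' @export
write_matrix <- function(m, path, delim = "\t", col_names = FALSE) {
  m <- as.matrix(m)
  lines <- apply(m, 1L, function(r)
    paste(sprintf("%.15g", r), collapse = delim))
  if (col_names && !is.null(colnames(m)))
    lines <- c(paste(colnames(m), collapse = delim), lines)
  writeLines(lines, path)
  invisible(path)
}
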