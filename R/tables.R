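#' Build a contingency table
#'
#' Wraps an I x J matrix of non-negative integer counts together with its row
#' margins, column margins and grand total. Rows are the groups whose totals
#' \eqn{m_i} are treated as public (e.g. case/control counts in a GWAS
#' contingency table); columns are the conditions. This orientation matters:
#' the global sensitivity of the chi-squared statistic is defined relative to
#' public row totals, so transposing a table changes
#' [randchidist_sensitivity()].
#'
#' @param counts numeric matrix with at least 2 rows and 2 columns, all
#'   entries non-negative integers, grand total at least 1.
#' @return An object of class `contingency_table`: a list with elements
#'   `counts`, `row_margins`, `col_margins`, `total`, `n_rows`, `n_cols`.
#' @examples
#' tab <- contingency_table(matrix(c(25, 20, 30, 25), 2, 2))
#' tab$row_margins  # 55 45
#' @export
contingency_table <- function(counts) {
  if (!is.matrix(counts)) {
    counts <- as.matrix(counts)
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("contingency table must have at least 2 rows and 2 columns, got ",
         nrow(counts), "x", ncol(counts), call. = FALSE)
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("counts must be a numeric matrix without missing values",
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("all counts must be non-negative integers", call. = FALSE)
  }
  counts <- matrix(as.numeric(counts), nrow(counts), ncol(counts))
  n <- sum(counts)
  if (n < 1) {
    stop("all-zero contingency table: grand total must be at least 1",
         call. = FALSE)
  }
  structure(
    list(
      counts = counts,
      row_margins = rowSums(counts),
      col_margins = colSums(counts),
      total = n,
      n_rows = nrow(counts),
      n_cols = ncol(counts)
    ),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("%dx%d contingency table (n = %d)\n",
              x$n_rows, x$n_cols, as.integer(x$total)))
  m <- cbind(x$counts, Total = x$row_margins)
  m <- rbind(m, Total = c(x$col_margins, x$total))
  print(m)
  invisible(x)
}

# Internal: chi-squared pieces for a (possibly real-valued) count matrix with
# strictly positive margins. Used both for ContingencyTable objects and for
# the noisy real-valued tables inside mechanisms.
chi_squared_stat <- function(counts, row_margins = rowSums(counts),
                             col_margins = colSums(counts),
                             total = sum(row_margins)) {
  expected <- outer(row_margins, col_margins) / total
  contributions <- (expected - counts)^2 / expected
  list(
    statistic = sum(contributions),
    contributions = contributions,
    expected = expected,
    dof = (nrow(counts) - 1L) * (ncol(counts) - 1L)
  )
}

#' Pearson chi-squared statistic of independence
#'
#' Computes the classical statistic
#' \deqn{\chi^2 = \sum_{i,j} (E_{ij} - O_{ij})^2 / E_{ij}, \quad
#'       E_{ij} = s_j m_i / n,}
#' with \eqn{(I-1)(J-1)} degrees of freedom. All row and column margins must
#' be strictly positive, otherwise some expected count is zero and the
#' statistic is undefined.
#'
#' @param table a [contingency_table()].
#' @return An object of class `chisq_result`: list with `statistic`,
#'   `contributions` (per-cell terms), `expected`, `dof`.
#' @examples
#' chi_squared(contingency_table(matrix(c(25, 20, 30, 25), 2, 2)))$statistic
#' @export
chi_squared <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  zr <- which(table$row_margins == 0)
  if (length(zr)) {
    stop("row ", zr[1L], " has zero margin; chi-squared is undefined",
         call. = FALSE)
  }
  zc <- which(table$col_margins == 0)
  if (length(zc)) {
    stop("column ", zc[1L], " has zero margin; chi-squared is undefined",
         call. = FALSE)
  }
  res <- chi_squared_stat(table$counts, table$row_margins,
                          table$col_margins, table$total)
  structure(res, class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("chi-squared = %.6g on %d degrees of freedom\n",
              x$statistic, x$dof))
  invisible(x)
}

#' Rule-of-thumb cell-size check
#'
#' The chi-squared approximation is conventionally considered unreliable when
#' any cell count falls below five. Returns `TRUE` iff every entry of the
#' matrix is at least `threshold` (inclusive: a cell equal to the threshold
#' passes).
#'
#' @param counts numeric matrix (may be real-valued, e.g. a noise-perturbed
#'   table).
#' @param threshold numeric scalar, default 5.
#' @return logical scalar.
#' @export
min_cell_ok <- function(counts, threshold = 5) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("empty matrix", call. = FALSE)
  all(counts >= threshold)
}

#' Read a contingency table from CSV
#'
#' Rows of the CSV are the groups (the dimension whose totals are public),
#' columns are the conditions. An optional single header row and an optional
#' leading row-label column are auto-detected: a row or column whose fields
#' are not all numeric is treated as labels and dropped.
#'
#' @param path path to a CSV file of integer counts.
#' @return a [contingency_table()].
#' @export
read_table_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("empty CSV file: ", path, call. = FALSE)
  fields <- lapply(keep, function(i) trimws(strsplit(lines[i], ",")[[1L]]))

  is_num <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  has_header <- !all(is_num(fields[[1L]]))
  data_idx <- if (has_header) seq_along(fields)[-1L] else seq_along(fields)
  if (length(data_idx) < 2L) {
    stop("malformed CSV: fewer than 2 data rows in ", path, call. = FALSE)
  }
  widths <- vapply(fields[data_idx], length, integer(1L))
  if (length(unique(widths)) != 1L) {
    bad <- data_idx[which(widths != widths[1L])[1L]]
    stop("ragged row at line ", keep[bad], " of ", path,
         ": expected ", widths[1L], " fields, found ",
         length(fields[[bad]]), call. = FALSE)
  }
  rows <- fields[data_idx]
  has_labels <- !all(vapply(rows, function(r) is_num(r[1L]), logical(1L)))
  if (has_labels) rows <- lapply(rows, function(r) r[-1L])
  for (k in seq_along(rows)) {
    if (!all(is_num(rows[[k]]))) {
      stop("malformed CSV: non-numeric entry at line ", keep[data_idx[k]],
           " of ", path, call. = FALSE)
    }
  }
  counts <- do.call(rbind, lapply(rows, as.numeric))
  contingency_table(counts)
}

#' Write a contingency table to CSV
#'
#' Plain integer CSV, no header, no row labels; a write-then-read round trip
#' preserves the counts exactly.
#'
#' @param table a [contingency_table()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table_csv <- function(table, path) {
  stopifnot(inherits(table, "contingency_table"))
  utils::write.table(table$counts, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Serialize a test outcome as JSON
#'
#' Writes the mechanism name, decision, noisy statistic, threshold, p-value,
#' epsilon, alpha and seed of a [rand_chi_dist()]-style outcome to a JSON
#' file, floats at full precision.
#'
#' @param path output path.
#' @param outcome a `dp_test_outcome`, e.g. from [rand_chi_dist()].
#' @return invisibly, `path`.
#' @export
write_outcome <- function(path, outcome) {
  stopifnot(inherits(outcome, "dp_test_outcome"))
  rec <- outcome[!vapply(outcome, is.null, logical(1L))]
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
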