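new_sensitivity_spec <- function(value, variant, row_margins = NULL,
                                 n_cols = NA_integer_, total = NA_real_,
                                 min_margin = NA_real_,
                                 second_min_margin = NA_real_) {
  structure(
    list(
      value = value,
      variant = variant,
      row_margins = row_margins,
      n_cols = n_cols,
      total = total,
      min_margin = min_margin,
      second_min_margin = second_min_margin
    ),
    class = "sensitivity_spec"
  )
}

#' @export
print.sensitivity_spec <- function(x, ...) {
  cat(sprintf("global sensitivity (%s): %.10g\n", x$variant, x$value))
  invisible(x)
}

#' Global sensitivity of the chi-squared statistic with public row margins
#'
#' The largest possible change of the Pearson chi-squared statistic between
#' two neighboring I x J tables (tables differing by moving one unit between
#' two columns within one row, row totals fixed and public). With
#' \eqn{m_\alpha} the smallest and \eqn{m_\beta} the second-smallest row
#' margin and \eqn{n} the grand total:
#' \deqn{\Delta_R = \frac{(m_\alpha + m_\beta)\,n}{m_\alpha (1 + m_\beta)}
#'       \quad (J \ge 3), \qquad
#'       \Delta_R = \frac{n^2}{m_\alpha (n - m_\alpha + 1)} \quad (J = 2).}
#' Laplace noise of scale \eqn{\Delta_R/\epsilon} added to the statistic then
#' yields an \eqn{\epsilon}-differentially private release. Ties among
#' margins are broken by the smallest row index; the value is invariant under
#' permutation of the margins.
#'
#' @param row_margins vector of positive integer row totals (length I >= 2).
#' @param n_cols number of columns J >= 2.
#' @return a `sensitivity_spec` with `value` = \eqn{\Delta_R}.
#' @examples
#' randchidist_sensitivity(c(55, 45), 2)$value  # 3.968254
#' @seealso [brute_force_sensitivity()] for the exhaustive check,
#'   [yu_sensitivity()] and [fienberg_sensitivity()] for the 2-row special
#'   cases.
#' @export
randchidist_sensitivity <- function(row_margins, n_cols) {
  check_margins(row_margins, n_cols)
  n <- sum(row_margins)
  ord <- order(row_margins)      # stable: ties broken by smallest index
  m_a <- row_margins[ord[1L]]
  m_b <- row_margins[ord[2L]]
  value <- if (n_cols >= 3L) {
    (m_a + m_b) * n / (m_a * (1 + m_b))
  } else {
    n^2 / (m_a * (n - m_a + 1))
  }
  new_sensitivity_spec(value, "randchidist", row_margins, as.integer(n_cols),
                       n, m_a, m_b)
}

#' Global sensitivity for 2-row tables with both margins public
#'
#' The classical bound for 2 x 2 and 2 x 3 tables:
#' \deqn{\Delta_Y = \frac{n^2}{m_1 m_2}
#'       \left(1 - \frac{1}{\max(m_1, m_2) + 1}\right), \quad n = m_1 + m_2.}
#' Algebraically identical to [randchidist_sensitivity()] for two rows with
#' \eqn{J \ge 3}.
#'
#' @param m1,m2 positive integer row totals.
#' @return a `sensitivity_spec`.
#' @export
yu_sensitivity <- function(m1, m2) {
  if (m1 < 1 || m2 < 1 || m1 != round(m1) || m2 != round(m2)) {
    stop("row margins must be positive integers", call. = FALSE)
  }
  n <- m1 + m2
  value <- n^2 / (m1 * m2) * (1 - 1 / (max(m1, m2) + 1))
  new_sensitivity_spec(value, "yu", c(m1, m2), NA_integer_, n,
                       min(m1, m2), max(m1, m2))
}

#' Global sensitivity for balanced 2-row tables
#'
#' Under the equal-margins premise \eqn{m_1 = m_2 = n/2}:
#' \deqn{\Delta_F = \frac{4n}{n + 2}.}
#'
#' @param n positive even grand total.
#' @return a `sensitivity_spec`.
#' @export
fienberg_sensitivity <- function(n) {
  if (n < 2 || n != round(n)) {
    stop("n must be an integer >= 2", call. = FALSE)
  }
  if (n %% 2 != 0) {
    stop("n must be even: equal row margins m1 = m2 = n/2 are impossible ",
         "for odd n", call. = FALSE)
  }
  new_sensitivity_spec(4 * n / (n + 2), "fienberg", c(n / 2, n / 2),
                       NA_integer_, n, n / 2, n / 2)
}

check_margins <- function(row_margins, n_cols) {
  if (length(row_margins) < 2L) {
    stop("need at least 2 row margins", call. = FALSE)
  }
  if (any(row_margins < 1) || any(row_margins != round(row_margins))) {
    stop("all row margins must be positive integers", call. = FALSE)
  }
  if (n_cols < 2L || n_cols != round(n_cols)) {
    stop("number of columns must be an integer >= 2", call. = FALSE)
  }
  invisible(TRUE)
}

#' Brute-force global sensitivity by exhaustive enumeration
#'
#' Independent oracle for [randchidist_sensitivity()]. Enumerates every table
#' with the given row margins and every neighbor reachable by moving one unit
#' between two columns within one row, and returns the maximum absolute
#' change of the chi-squared statistic over all such pairs. Exponential in
#' the table size; guarded by an enumeration budget.
#'
#' A column whose total is zero has all its cells zero, and its contribution
#' to the statistic is taken as the continuous limit of \eqn{(E - O)^2/E} as
#' \eqn{E \to 0} with \eqn{O = 0}, namely 0 (`zero_columns = "drop_term"`,
#' the default): the sensitivity-maximizing neighbor pairs concentrate whole
#' rows into single columns and routinely empty the remaining columns, so
#' this extension is the domain over which the closed-form sensitivity is
#' tight. `zero_columns = "skip_table"` instead restricts the enumeration to
#' pairs where both tables have all column totals positive, which can give a
#' strictly smaller maximum for small margins.
#'
#' @param row_margins vector of positive integer row totals.
#' @param n_cols number of columns J >= 2.
#' @param guard maximum number of tables to enumerate (default 1e7).
#' @param zero_columns handling of zero-total columns, see Details.
#' @return a `sensitivity_spec` with attributes `n_tables` (tables
#'   enumerated), `n_valid` (tables in the statistic's domain) and `n_pairs`
#'   (neighbor pairs examined).
#' @examples
#' brute_force_sensitivity(c(3, 3), 2)$value  # 3, matching the formula
#' @export
brute_force_sensitivity <- function(row_margins, n_cols, guard = 1e7,
                                    zero_columns = c("drop_term",
                                                     "skip_table")) {
  check_margins(row_margins, n_cols)
  zero_columns <- match.arg(zero_columns)
  n_tables <- prod(choose(row_margins + n_cols - 1, n_cols - 1))
  if (n_tables > guard) {
    stop("enumeration budget exceeded: ", format(n_tables, big.mark = ","),
         " tables with these margins, guard is ",
         format(guard, big.mark = ","), call. = FALSE)
  }
  res <- bf_sensitivity_cpp(as.integer(row_margins), as.integer(n_cols),
                            zero_columns == "skip_table")
  if (res$n_pairs == 0L) {
    stop("no valid neighbor pairs exist for these margins", call. = FALSE)
  }
  ord <- order(row_margins)
  spec <- new_sensitivity_spec(res$max_delta, "brute_force", row_margins,
                               as.integer(n_cols), sum(row_margins),
                               row_margins[ord[1L]], row_margins[ord[2L]])
  attr(spec, "n_tables") <- res$n_tables
  attr(spec, "n_valid") <- res$n_valid
  attr(spec, "n_pairs") <- res$n_pairs
  spec
}
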