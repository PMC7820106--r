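#' Seeded zero-mean Laplace variates
#'
#' Inverse-CDF sampling on uniform draws from R's global random stream, so
#' results are reproducible under `set.seed()`.
#'
#' @param n number of variates.
#' @param scale positive scale parameter b; the density is
#'   \eqn{e^{-|x|/b} / (2b)} (variance \eqn{2b^2}).
#' @return numeric vector of length `n`.
#' @export
sample_laplace <- function(n, scale) {
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

new_outcome <- function(mechanism, decision, noisy_statistic = NULL,
                        threshold = NULL, p_value = NULL, epsilon = NULL,
                        alpha, seed = NULL, degenerate = FALSE,
                        rule_of_thumb_failed = FALSE) {
  structure(
    list(mechanism = mechanism, decision = decision,
         noisy_statistic = noisy_statistic, threshold = threshold,
         p_value = p_value, epsilon = epsilon, alpha = alpha, seed = seed,
         degenerate = degenerate,
         rule_of_thumb_failed = rule_of_thumb_failed),
    class = "dp_test_outcome"
  )
}

#' @export
print.dp_test_outcome <- function(x, ...) {
  cat(sprintf("%s: %s (alpha = %g", x$mechanism, x$decision, x$alpha))
  if (!is.null(x$epsilon)) cat(sprintf(", epsilon = %g", x$epsilon))
  cat(")\n")
  if (!is.null(x$noisy_statistic)) {
    cat(sprintf("  statistic = %.6g", x$noisy_statistic))
    if (!is.null(x$threshold)) cat(sprintf(", threshold = %.6g", x$threshold))
    if (!is.null(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
    cat("\n")
  }
  invisible(x)
}

maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
}

#' RandChiDist: differentially private chi-squared test with a calibrated
#' threshold
#'
#' Releases \eqn{\chi^{2*} = \chi^2 + \mathrm{Laplace}(\Delta_R/\epsilon)}
#' where \eqn{\Delta_R} is the global sensitivity of the statistic given the
#' public row margins ([randchidist_sensitivity()]). The decision compares
#' the noisy statistic not against the classical percentage point, but
#' against the threshold calibrated on the privatized null distribution
#' ([critical_value()]), so that the type-I error stays at the nominal level
#' despite the added noise. A private p-value — the privatized null's upper
#' tail at the noisy statistic — is returned alongside. The whole release
#' consumes one \eqn{\epsilon}.
#'
#' @param table a [contingency_table()] with positive row and column margins.
#' @param epsilon privacy budget (> 0).
#' @param alpha significance level in (0, 1).
#' @param seed optional integer; if given, the global RNG is seeded before
#'   drawing the noise so the outcome is reproducible.
#' @return a `dp_test_outcome` with fields `decision` ("reject" or
#'   "fail_to_reject"), `noisy_statistic`, `threshold`, `p_value`, `epsilon`,
#'   `alpha`, `seed`.
#' @export
rand_chi_dist <- function(table, epsilon, alpha, seed = NULL) {
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  res <- chi_squared(table)
  delta <- randchidist_sensitivity(table$row_margins, table$n_cols)$value
  null <- private_null(res$dof, delta, epsilon)
  maybe_seed(seed)
  stat <- res$statistic + sample_laplace(1L, null$scale)
  t <- critical_value(null, alpha)
  p <- noisy_null_upper_tail(stat, null)
  new_outcome("randchidist",
              if (stat >= t) "reject" else "fail_to_reject",
              noisy_statistic = stat, threshold = t, p_value = p,
              epsilon = epsilon, alpha = alpha, seed = seed)
}

#' RandChi: noisy statistic against the classical percentage point
#'
#' Baseline that adds the same calibrated Laplace noise as [rand_chi_dist()]
#' but keeps the classical chi-squared rejection threshold and p-value,
#' ignoring the noise when deciding. Private, but the noise inflates the
#' statistic's spread, so its type-I error exceeds the nominal level at small
#' privacy budgets.
#'
#' @inheritParams rand_chi_dist
#' @return a `dp_test_outcome`.
#' @export
rand_chi <- function(table, epsilon, alpha, seed = NULL) {
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  res <- chi_squared(table)
  delta <- randchidist_sensitivity(table$row_margins, table$n_cols)$value
  maybe_seed(seed)
  stat <- res$statistic + sample_laplace(1L, delta / epsilon)
  t <- stats::qchisq(1 - alpha, df = res$dof)
  p <- stats::pchisq(stat, df = res$dof, lower.tail = FALSE)
  new_outcome("randchi",
              if (stat >= t) "reject" else "fail_to_reject",
              noisy_statistic = stat, threshold = t, p_value = p,
              epsilon = epsilon, alpha = alpha, seed = seed)
}

#' RandCell: per-cell Laplace noise
#'
#' Baseline that privatizes the table itself: independent
#' \eqn{\mathrm{Laplace}(2/\epsilon)} noise on every cell (global sensitivity
#' 2, since one record changes two cells by one each). If any noisy cell
#' falls below the rule-of-thumb threshold of 5 the mechanism fails to
#' reject, since the chi-squared approximation is untrustworthy there.
#' Otherwise the statistic is computed on the noisy real-valued table, with
#' its noisy margins, and compared against the classical percentage point.
#'
#' @inheritParams rand_chi_dist
#' @param cell_threshold rule-of-thumb minimum noisy cell value (default 5).
#' @return a `dp_test_outcome`; `rule_of_thumb_failed` is set when the noisy
#'   table failed the cell check, `degenerate` when a noisy margin was
#'   non-positive.
#' @export
rand_cell <- function(table, epsilon, alpha, seed = NULL,
                      cell_threshold = 5) {
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  maybe_seed(seed)
  noisy <- table$counts +
    matrix(sample_laplace(length(table$counts), 2 / epsilon),
           table$n_rows, table$n_cols)
  if (!min_cell_ok(noisy, cell_threshold)) {
    return(new_outcome("randcell", "fail_to_reject", epsilon = epsilon,
                       alpha = alpha, seed = seed,
                       rule_of_thumb_failed = TRUE))
  }
  rm_ <- rowSums(noisy)
  cm_ <- colSums(noisy)
  if (any(rm_ <= 0) || any(cm_ <= 0)) {
    return(new_outcome("randcell", "fail_to_reject", epsilon = epsilon,
                       alpha = alpha, seed = seed, degenerate = TRUE))
  }
  res <- chi_squared_stat(noisy, rm_, cm_, sum(rm_))
  t <- stats::qchisq(1 - alpha, df = res$dof)
  p <- stats::pchisq(res$statistic, df = res$dof, lower.tail = FALSE)
  new_outcome("randcell",
              if (res$statistic >= t) "reject" else "fail_to_reject",
              noisy_statistic = res$statistic, threshold = t, p_value = p,
              epsilon = epsilon, alpha = alpha, seed = seed)
}

#' MCIndep: Monte-Carlo independence test on the privatized table
#'
#' Baseline following the Monte-Carlo approach: (1) privatize the observed
#' table with per-cell \eqn{\mathrm{Laplace}(2/\epsilon)} noise; (2) estimate
#' an independence multinomial from the noisy margins (negative noisy margins
#' floored at zero and renormalized, the effective total rounded and floored
#' at one); (3) draw `n_mc_tables` reference tables from that multinomial,
#' each perturbed with fresh same-scale Laplace noise so reference and
#' observed statistics are comparable; (4) if any reference table has a noisy
#' cell below 5, fail to reject outright (rule of thumb); (5) otherwise
#' reject iff the observed noisy statistic exceeds the empirical
#' \eqn{(1-\alpha)} quantile of the reference statistics.
#'
#' @inheritParams rand_chi_dist
#' @param n_mc_tables number of reference tables, at least `ceiling(1/alpha)`;
#'   default `max(ceiling(2/alpha), 1000)`.
#' @param cell_threshold rule-of-thumb minimum (default 5).
#' @return a `dp_test_outcome`.
#' @export
mc_indep <- function(table, epsilon, alpha, seed = NULL,
                     n_mc_tables = max(ceiling(2 / alpha), 1000L),
                     cell_threshold = 5) {
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (n_mc_tables < ceiling(1 / alpha)) {
    stop("n_mc_tables must be at least ceiling(1/alpha) = ",
         ceiling(1 / alpha), call. = FALSE)
  }
  I <- table$n_rows
  J <- table$n_cols
  maybe_seed(seed)
  b <- 2 / epsilon
  noisy <- table$counts + matrix(sample_laplace(I * J, b), I, J)

  rm_ <- pmax(rowSums(noisy), 0)
  cm_ <- pmax(colSums(noisy), 0)
  n_tilde <- max(round(sum(noisy)), 1)
  if (sum(rm_) <= 0 || sum(cm_) <= 0) {
    return(new_outcome("mcindep", "fail_to_reject", epsilon = epsilon,
                       alpha = alpha, seed = seed, degenerate = TRUE))
  }
  p_hat <- outer(rm_ / sum(rm_), cm_ / sum(cm_))

  # statistic of the observed noisy table (noisy margins); degenerate noisy
  # margins mean the statistic does not exist
  orm <- rowSums(noisy)
  ocm <- colSums(noisy)
  if (any(orm <= 0) || any(ocm <= 0)) {
    return(new_outcome("mcindep", "fail_to_reject", epsilon = epsilon,
                       alpha = alpha, seed = seed, degenerate = TRUE))
  }
  obs <- chi_squared_stat(noisy, orm, ocm, sum(orm))$statistic

  draws <- stats::rmultinom(n_mc_tables, n_tilde, as.vector(p_hat))
  ref_noisy <- draws + matrix(sample_laplace(length(draws), b),
                              nrow(draws), ncol(draws))
  if (any(ref_noisy < cell_threshold)) {
    return(new_outcome("mcindep", "fail_to_reject", epsilon = epsilon,
                       alpha = alpha, seed = seed,
                       rule_of_thumb_failed = TRUE))
  }
  ref_stats <- apply(ref_noisy, 2L, function(cells) {
    m <- matrix(cells, I, J)
    chi_squared_stat(m)$statistic
  })
  thr <- stats::quantile(ref_stats, 1 - alpha, names = FALSE, type = 7)
  p <- mean(ref_stats >= obs)
  new_outcome("mcindep",
              if (obs > thr) "reject" else "fail_to_reject",
              noisy_statistic = obs, threshold = thr, p_value = p,
              epsilon = epsilon, alpha = alpha, seed = seed)
}

#' Classical (non-private) chi-squared test of independence
#'
#' @param table a [contingency_table()].
#' @param alpha significance level in (0, 1).
#' @return a `dp_test_outcome` with the exact statistic, classical threshold
#'   and p-value; no privacy budget is consumed.
#' @export
non_private_test <- function(table, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  res <- chi_squared(table)
  t <- stats::qchisq(1 - alpha, df = res$dof)
  p <- stats::pchisq(res$statistic, df = res$dof, lower.tail = FALSE)
  new_outcome("nonprivate",
              if (res$statistic >= t) "reject" else "fail_to_reject",
              noisy_statistic = res$statistic, threshold = t, p_value = p,
              alpha = alpha)
}

# registry used by the simulation harness and the CLI
mechanism_registry <- function() {
  list(
    nonprivate = function(table, epsilon, alpha, seed, ...)
      non_private_test(table, alpha),
    randchidist = function(table, epsilon, alpha, seed, ...)
      rand_chi_dist(table, epsilon, alpha, seed),
    randchi = function(table, epsilon, alpha, seed, ...)
      rand_chi(table, epsilon, alpha, seed),
    randcell = function(table, epsilon, alpha, seed, ...)
      rand_cell(table, epsilon, alpha, seed),
    mcindep = function(table, epsilon, alpha, seed, ...)
      mc_indep(table, epsilon, alpha, seed, ...)
  )
}
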