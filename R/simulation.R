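#' Draw a contingency table from a multinomial design
#'
#' One table with cells distributed Multinomial(n, `cell_probs`), conditioned
#' on all row and column margins being positive: draws with a zero margin are
#' resampled (the statistic is undefined there), and the number of resamples
#' is recorded so the conditioning is visible.
#'
#' @param cell_probs I x J matrix of cell probabilities summing to 1.
#' @param n sample size (>= 1).
#' @param min_cell_filter if `TRUE`, additionally resample until every cell
#'   passes the rule-of-thumb minimum of 5 (off by default).
#' @param max_resamples resample budget before erroring out on a degenerate
#'   design.
#' @return a [contingency_table()] with attribute `resamples`.
#' @export
sample_multinomial_table <- function(cell_probs, n, min_cell_filter = FALSE,
                                     max_resamples = 10000L) {
  check_prob_matrix(cell_probs)
  if (n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  I <- nrow(cell_probs)
  J <- ncol(cell_probs)
  resamples <- 0L
  repeat {
    counts <- matrix(stats::rmultinom(1L, n, as.vector(cell_probs)), I, J)
    ok <- all(rowSums(counts) > 0) && all(colSums(counts) > 0) &&
      (!min_cell_filter || min_cell_ok(counts, 5))
    if (ok) break
    resamples <- resamples + 1L
    if (resamples > max_resamples) {
      stop("resample limit reached: design is degenerate at n = ", n,
           call. = FALSE)
    }
  }
  tab <- contingency_table(counts)
  attr(tab, "resamples") <- resamples
  tab
}

check_prob_matrix <- function(p) {
  if (!is.matrix(p) || !is.numeric(p)) {
    stop("cell_probs must be a numeric matrix", call. = FALSE)
  }
  if (any(p < 0) || any(p > 1)) {
    stop("cell probabilities must lie in [0,1]", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop("cell probabilities must sum to 1 (got ", format(sum(p), digits = 17),
         ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Additively perturbed cell probabilities
#'
#' Builds an alternative design `base + delta * pattern`, the standard way of
#' planting a signal of controlled size: e.g. the uniform 2 x 2 base with a
#' diagonal +/-1 pattern and delta = 0.01 gives (0.26, 0.24, 0.24, 0.26).
#' The pattern must not change the total probability.
#'
#' @param base probability matrix summing to 1.
#' @param delta perturbation magnitude.
#' @param pattern matrix of the same shape with entries in \{-1, 0, 1\}
#'   summing to 0.
#' @return a probability matrix.
#' @export
effect_probs <- function(base, delta, pattern) {
  check_prob_matrix(base)
  pattern <- as.matrix(pattern)
  if (!all(dim(pattern) == dim(base))) {
    stop("pattern must have the same shape as base", call. = FALSE)
  }
  if (!all(pattern %in% c(-1, 0, 1))) {
    stop("pattern entries must be -1, 0 or 1", call. = FALSE)
  }
  if (sum(pattern) != 0) {
    stop("pattern must sum to 0 so the total probability is preserved",
         call. = FALSE)
  }
  out <- base + delta * pattern
  if (any(out < 0) || any(out > 1)) {
    stop("perturbed probabilities fall outside [0,1]", call. = FALSE)
  }
  out
}

#' Correlated-pair cell probabilities
#'
#' Synthetic stand-in for contingency tables of associated variable pairs
#' (e.g. two loci in linkage disequilibrium): a mixture of the independence
#' outer product and a diagonal concentration of the row marginal,
#' \deqn{p_{ij} \propto (1 - \lambda)\, r_i c_j + \lambda\, [i = j]\, r_i.}
#' `mixing = 0` gives exact independence; `mixing = 1` with uniform marginals
#' gives a diagonal table.
#'
#' @param row_marginal,col_marginal probability vectors.
#' @param mixing association strength between 0 and 1; requires equal lengths of
#'   the marginals when positive.
#' @return a probability matrix.
#' @export
correlated_pair_probs <- function(row_marginal, col_marginal, mixing) {
  if (any(row_marginal < 0) || abs(sum(row_marginal) - 1) > 1e-12 ||
      any(col_marginal < 0) || abs(sum(col_marginal) - 1) > 1e-12) {
    stop("marginals must be probability vectors summing to 1", call. = FALSE)
  }
  if (mixing < 0 || mixing > 1) stop("mixing must be in [0,1]", call. = FALSE)
  I <- length(row_marginal)
  J <- length(col_marginal)
  if (mixing > 0 && I != J) {
    stop("diagonal association requires equally many rows and columns",
         call. = FALSE)
  }
  p <- (1 - mixing) * outer(row_marginal, col_marginal)
  if (mixing > 0) p <- p + mixing * diag(row_marginal, I, J)
  p / sum(p)
}

#' Declare a significance/power experiment
#'
#' Describes one simulation design: a multinomial cell-probability matrix,
#' a grid of sample sizes, the test level and privacy budget, the mechanisms
#' to compare, the number of replicates and a master seed. Whether the design
#' is a null or an alternative is derived from the probabilities themselves
#' (null iff they factorize into their margins); an explicit `truth` label
#' contradicting the derivation is an error.
#'
#' @param cell_probs I x J probability matrix summing to 1.
#' @param sample_sizes grid of n values (default `c(100, 300, 500, 700,
#'   900)`).
#' @param alpha significance level.
#' @param epsilon privacy budget passed to the private mechanisms.
#' @param replicates Monte-Carlo replicates per grid point (default 1000).
#' @param master_seed integer seed from which per-replicate substreams are
#'   derived.
#' @param mechanisms character vector among "nonprivate", "randchidist",
#'   "randchi", "randcell", "mcindep".
#' @param truth optional "null"/"alternative" label; checked against the
#'   probabilities.
#' @param min_cell_filter apply the rule-of-thumb filter when drawing tables
#'   (default `FALSE`).
#' @param n_mc_tables reference-table count for "mcindep" (default as in
#'   [mc_indep()]).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(cell_probs,
                              sample_sizes = c(100L, 300L, 500L, 700L, 900L),
                              alpha = 0.05, epsilon = 0.1,
                              replicates = 1000L, master_seed = 1L,
                              mechanisms = c("nonprivate", "randchidist"),
                              truth = NULL, min_cell_filter = FALSE,
                              n_mc_tables = NULL) {
  check_prob_matrix(cell_probs)
  if (any(sample_sizes < 1)) stop("sample sizes must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  known <- names(mechanism_registry())
  bad <- setdiff(mechanisms, known)
  if (length(bad)) {
    stop("unknown mechanism(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")", call. = FALSE)
  }
  indep <- outer(rowSums(cell_probs), colSums(cell_probs))
  derived <- if (max(abs(cell_probs - indep)) <= 1e-12) "null" else
    "alternative"
  if (!is.null(truth) && !identical(truth, derived)) {
    stop("declared truth '", truth, "' contradicts the cell probabilities, ",
         "which describe a ", derived, " design", call. = FALSE)
  }
  structure(
    list(cell_probs = cell_probs, sample_sizes = as.integer(sample_sizes),
         alpha = alpha, epsilon = epsilon,
         replicates = as.integer(replicates),
         master_seed = as.integer(master_seed), mechanisms = mechanisms,
         truth = derived, min_cell_filter = min_cell_filter,
         n_mc_tables = n_mc_tables),
    class = "simulation_config"
  )
}

# Substream derivation. Table seeds depend only on (master_seed, n, replicate)
# so the table sequence is identical whatever mechanisms are requested;
# mechanism seeds add a fixed per-mechanism offset.
derive_seeds <- function(master_seed, n_points, replicates) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  matrix(sample.int(2147483000L, n_points * replicates), replicates, n_points)
}

mechanism_seed <- function(table_seed, mechanism) {
  id <- match(mechanism, names(mechanism_registry()))
  as.integer((as.numeric(table_seed) + id * 104729) %% 2147483000 + 1)
}

#' Run a significance/power experiment
#'
#' For each sample size and replicate, draws one multinomial table and runs
#' every requested mechanism on the same table (a paired design: mechanisms
#' see identical data, which removes between-table noise from their
#' comparison). A decision is correct when it matches the design's truth:
#' "fail_to_reject" under a null design (so the correct rate is the empirical
#' significance), "reject" under an alternative (empirical power). Fully
#' deterministic given `master_seed`.
#'
#' @param config a [simulation_config()].
#' @return a data frame of class `dp_sim_summary` with one row per
#'   (mechanism, n): `correct_rate`, `mc_se` (binomial standard error),
#'   `reject_count`, `replicate_count`, `resamples`, `failures`. The config
#'   is attached as attribute `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ns <- config$sample_sizes
  R <- config$replicates
  mechs <- config$mechanisms
  seeds <- derive_seeds(config$master_seed, length(ns), R)
  registry <- mechanism_registry()
  extra <- if (is.null(config$n_mc_tables)) list() else
    list(n_mc_tables = config$n_mc_tables)

  rows <- list()
  for (j in seq_along(ns)) {
    n <- ns[j]
    rejects <- stats::setNames(integer(length(mechs)), mechs)
    failures <- stats::setNames(integer(length(mechs)), mechs)
    resamples <- 0L
    for (r in seq_len(R)) {
      set.seed(seeds[r, j])
      tab <- sample_multinomial_table(config$cell_probs, n,
                                      config$min_cell_filter)
      resamples <- resamples + attr(tab, "resamples")
      for (mech in mechs) {
        out <- tryCatch(
          do.call(registry[[mech]],
                  c(list(tab, config$epsilon, config$alpha,
                         mechanism_seed(seeds[r, j], mech)), extra)),
          error = function(e) e
        )
        if (inherits(out, "error")) {
          failures[mech] <- failures[mech] + 1L
        } else if (out$decision == "reject") {
          rejects[mech] <- rejects[mech] + 1L
        }
      }
    }
    correct <- if (config$truth == "null") R - rejects - failures else rejects
    rate <- correct / R
    rows[[j]] <- data.frame(
      mechanism = mechs, n = n, correct_rate = as.numeric(rate),
      mc_se = sqrt(pmax(rate * (1 - rate), 0) / R),
      reject_count = as.integer(rejects), replicate_count = R,
      resamples = resamples, failures = as.integer(failures),
      row.names = NULL
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  class(out) <- c("dp_sim_summary", "data.frame")
  out
}

#' @export
print.dp_sim_summary <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "%s design (%dx%d), alpha = %g, epsilon = %g, %d replicates/point\n",
    cfg$truth, nrow(cfg$cell_probs), ncol(cfg$cell_probs), cfg$alpha,
    cfg$epsilon, cfg$replicates))
  print.data.frame(x)
  invisible(x)
}
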