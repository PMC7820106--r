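test_that("sample_laplace is deterministic given a seed and has Laplace
           moments", {
  set.seed(42)
  a <- sample_laplace(5, 2)
  set.seed(42)
  expect_identical(sample_laplace(5, 2), a)
  expect_error(sample_laplace(1, 0), "positive")

  set.seed(7)
  x <- sample_laplace(1e6, 1)
  expect_lt(abs(mean(x)), 3 * sqrt(2 / 1e6))
  expect_lt(abs(stats::var(x) - 2) / 2, 0.02)
})

test_that("sample_laplace passes a goodness-of-fit test", {
  set.seed(1234)
  x <- sample_laplace(1e5, 3)
  ks <- suppressWarnings(stats::ks.test(x, function(q) plaplace(q, 3)))
  expect_gt(ks$p.value, 0.01)
})

test_that("rand_chi_dist matches the non-private decision in the zero-noise
           limit and is reproducible", {
  out <- rand_chi_dist(table2(), epsilon = 1e9, alpha = 0.05, seed = 1L)
  ref <- non_private_test(table2(), alpha = 0.05)
  expect_equal(out$decision, ref$decision)
  expect_equal(out$decision, "fail_to_reject")
  expect_equal(out$noisy_statistic, 0.01020304, tolerance = 1e-4)
  expect_equal(out$threshold, stats::qchisq(0.95, 1), tolerance = 1e-4)

  again <- rand_chi_dist(table2(), epsilon = 1e9, alpha = 0.05, seed = 1L)
  expect_identical(out, again)
})

test_that("rand_chi_dist rejection frequency equals alpha when the statistic
           is exactly chi-squared", {
  # draw the 'statistic' from its null distribution, privatize, and compare
  # to the calibrated threshold: rejection rate must be alpha by construction
  v <- 1L; delta <- 4; eps <- 0.1; alpha <- 0.05
  pn <- private_null(v, delta, eps)
  t <- critical_value(pn, alpha)
  set.seed(88)
  n <- 1e5
  stat <- stats::rchisq(n, v) + sample_laplace(n, pn$scale)
  rate <- mean(stat >= t)
  expect_lt(abs(rate - alpha), 3 * sqrt(alpha * (1 - alpha) / n))
})

test_that("rand_chi_dist decision and private p-value are coherent", {
  set.seed(31)
  for (i in 1:1000) {
    tab <- random_table(max_dim = 3L, max_cell = 15L)
    eps <- sample(c(0.1, 1, 10), 1L)
    alpha <- sample(c(0.01, 0.05, 0.2), 1L)
    out <- rand_chi_dist(tab, eps, alpha, seed = i)
    expect_equal(out$decision == "reject", out$p_value <= alpha)
    expect_equal(out$decision == "reject",
                 out$noisy_statistic >= out$threshold)
  }
})

test_that("rand_chi_dist thresholds dominate as the budget shrinks", {
  tabs <- list(table2(), contingency_table(matrix(c(9, 7, 5, 11), 2, 2)))
  for (tab in tabs) {
    eps <- c(0.05, 0.1, 1, 10)
    ts <- vapply(eps, function(e) {
      rand_chi_dist(tab, e, 0.05, seed = 1L)$threshold
    }, numeric(1L))
    expect_true(all(diff(ts) < 0))
  }
})

test_that("output distributions of neighboring tables stay within the privacy
           ratio", {
  # fixed neighbor pair: one unit moved between columns within row 1
  d1 <- contingency_table(matrix(c(6, 10, 6, 10), 2, 2))
  d2 <- contingency_table(matrix(c(7, 10, 5, 10), 2, 2))
  eps <- 0.5
  s1 <- chi_squared(d1)$statistic
  s2 <- chi_squared(d2)$statistic
  b <- randchidist_sensitivity(d1$row_margins, 2)$value / eps
  set.seed(500)
  n <- 1e6
  o1 <- s1 + sample_laplace(n, b)
  o2 <- s2 + sample_laplace(n, b)
  breaks <- c(-Inf, seq(-15, 15, by = 1.5), Inf)
  h1 <- tabulate(findInterval(o1, breaks), length(breaks) - 1L) / n
  h2 <- tabulate(findInterval(o2, breaks), length(breaks) - 1L) / n
  mass <- pmin(h1, h2) > 200 / n   # only bins with enough mass to estimate
  ratio <- pmax(h1 / h2, h2 / h1)[mass]
  expect_true(all(ratio <= exp(eps) * 1.1))
})

test_that("rand_chi keeps the classical threshold", {
  out <- rand_chi(table2(), epsilon = 1e9, alpha = 0.05, seed = 2L)
  expect_equal(out$threshold, stats::qchisq(0.95, 1))
  expect_equal(out$decision, non_private_test(table2(), 0.05)$decision)
  out2 <- rand_chi(contingency_table(50 * diag(2)), 1e9, 0.05, seed = 2L)
  expect_equal(out2$decision, "reject")
})

test_that("rand_cell applies the rule of thumb to the noisy cells", {
  # a true cell below 5 with negligible noise forces fail-to-reject
  tab <- contingency_table(matrix(c(4, 50, 50, 50), 2, 2))
  out <- rand_cell(tab, epsilon = 1e9, alpha = 0.05, seed = 1L)
  expect_equal(out$decision, "fail_to_reject")
  expect_true(out$rule_of_thumb_failed)
  expect_null(out$noisy_statistic)

  # all cells comfortably above 5, negligible noise: non-private decision
  big <- contingency_table(matrix(c(50, 10, 10, 50), 2, 2))
  out2 <- rand_cell(big, epsilon = 1e9, alpha = 0.05, seed = 1L)
  expect_equal(out2$decision, non_private_test(big, 0.05)$decision)
  expect_equal(out2$decision, "reject")
  expect_equal(out2$noisy_statistic, chi_squared(big)$statistic,
               tolerance = 1e-4)
})

test_that("mc_indep rejects strong association at high budget and fails to
           reject when reference tables break the rule of thumb", {
  strong <- contingency_table(50 * diag(2))
  out <- mc_indep(strong, epsilon = 1e9, alpha = 0.05, seed = 9L,
                  n_mc_tables = 1e4)
  expect_equal(out$decision, "reject")

  # tiny table: sampled cells routinely fall below 5
  small <- contingency_table(matrix(6, 2, 2))
  out2 <- mc_indep(small, epsilon = 1e9, alpha = 0.05, seed = 9L)
  expect_equal(out2$decision, "fail_to_reject")
  expect_true(out2$rule_of_thumb_failed)

  expect_identical(mc_indep(strong, 1, 0.05, seed = 4L),
                   mc_indep(strong, 1, 0.05, seed = 4L))
  expect_error(mc_indep(strong, 1, 0.05, seed = 1L, n_mc_tables = 10),
               "ceiling")
})

test_that("non_private_test matches the classical chi-squared test", {
  out <- non_private_test(table2(), 0.05)
  expect_equal(out$decision, "fail_to_reject")
  expect_equal(out$p_value,
               stats::pchisq(0.01020304, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(non_private_test(contingency_table(50 * diag(2)),
                                0.05)$decision, "reject")
  # threshold near zero rejects any positive statistic
  expect_equal(non_private_test(table2(), 0.9999)$decision, "reject")
})
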