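test_that("sample_multinomial_table conserves totals and is reproducible", {
  p <- matrix(0.25, 2, 2)
  set.seed(10)
  for (i in 1:20) {
    tab <- sample_multinomial_table(p, 100)
    expect_equal(tab$total, 100)
    expect_equal(sum(tab$row_margins), 100)
  }
  set.seed(3)
  a <- sample_multinomial_table(p, 50)
  set.seed(3)
  expect_identical(sample_multinomial_table(p, 50)$counts, a$counts)

  expect_error(sample_multinomial_table(matrix(0.3, 2, 2), 100), "sum to 1")
})

test_that("multinomial cell means match the design", {
  p <- matrix(0.25, 2, 2)
  set.seed(77)
  m11 <- mean(replicate(1e4, sample_multinomial_table(p, 100)$counts[1, 1]))
  se <- sqrt(100 * 0.25 * 0.75 / 1e4)
  expect_lt(abs(m11 - 25), 3 * se)
})

test_that("the rule-of-thumb filter conditions draws on cell minima", {
  p <- matrix(c(0.55, 0.15, 0.15, 0.15), 2, 2)
  set.seed(21)
  for (i in 1:20) {
    tab <- sample_multinomial_table(p, 40, min_cell_filter = TRUE)
    expect_true(min_cell_ok(tab$counts, 5))
  }
})

test_that("effect_probs builds the perturbed designs", {
  base2 <- matrix(0.25, 2, 2)
  diagpat <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_equal(effect_probs(base2, 0.01, diagpat),
               matrix(c(0.26, 0.24, 0.24, 0.26), 2, 2))
  expect_equal(effect_probs(base2, 0, diagpat), base2)

  base34 <- matrix(1 / 12, 3, 4)
  pat34 <- matrix(0, 3, 4)
  pat34[1, 1] <- 1; pat34[1, 2] <- -1
  pat34[2, 1] <- -1; pat34[2, 2] <- 1
  out <- effect_probs(base34, 0.07, pat34)
  expect_equal(out[1, 1], 1 / 12 + 0.07)
  expect_equal(out[2, 1], 1 / 12 - 0.07)
  expect_equal(out[3, ], rep(1 / 12, 4))
  expect_equal(sum(out), 1)

  expect_error(effect_probs(base2, 0.3, diagpat), "outside")
  expect_error(effect_probs(base2, 0.01, matrix(2, 2, 2)), "entries")
})

test_that("correlated_pair_probs spans independence to full association", {
  r <- rep(0.25, 4)
  expect_equal(correlated_pair_probs(r, r, 0), outer(r, r))
  expect_equal(correlated_pair_probs(r, r, 1), diag(0.25, 4))
  p <- correlated_pair_probs(r, r, 0.3)
  indep <- outer(rowSums(p), colSums(p))
  expect_gt(sum((p - indep)^2 / indep), 0)   # positive noncentrality
  expect_error(correlated_pair_probs(rep(0.25, 4), rep(0.5, 2), 0.3),
               "equally many")
})

test_that("simulation_config derives the truth label and rejects
           contradictions", {
  null_cfg <- simulation_config(matrix(0.25, 2, 2))
  expect_equal(null_cfg$truth, "null")
  alt <- effect_probs(matrix(0.25, 2, 2), 0.15, matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(simulation_config(alt)$truth, "alternative")
  expect_error(simulation_config(matrix(0.25, 2, 2), truth = "alternative"),
               "contradicts")
  expect_error(simulation_config(matrix(0.25, 2, 2), mechanisms = "magic"),
               "unknown mechanism")
})

test_that("the harness is deterministic and pairs tables across mechanism
           lists", {
  cfg1 <- simulation_config(matrix(0.25, 2, 2), sample_sizes = c(50, 100),
                            replicates = 30, master_seed = 42,
                            mechanisms = "nonprivate")
  cfg2 <- simulation_config(matrix(0.25, 2, 2), sample_sizes = c(50, 100),
                            replicates = 30, master_seed = 42,
                            mechanisms = c("randchidist", "nonprivate"))
  s1 <- run_experiment(cfg1)
  s2 <- run_experiment(cfg2)
  np1 <- s1[s1$mechanism == "nonprivate", c("n", "reject_count")]
  np2 <- s2[s2$mechanism == "nonprivate", c("n", "reject_count")]
  rownames(np1) <- rownames(np2) <- NULL
  expect_identical(np1, np2)   # same tables, same decisions
  expect_identical(run_experiment(cfg2), run_experiment(cfg2))
})

test_that("non-private significance under the null approaches 1 - alpha", {
  cfg <- simulation_config(matrix(0.25, 2, 2), sample_sizes = 500,
                           alpha = 0.05, replicates = 1000, master_seed = 11,
                           mechanisms = "nonprivate")
  s <- run_experiment(cfg)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(s$correct_rate - 0.95), 3 * se)
})

test_that("non-private power is near one for the strong 2x2 alternative at
           large n", {
  alt <- effect_probs(matrix(0.25, 2, 2), 0.15, matrix(c(1, -1, -1, 1), 2, 2))
  cfg <- simulation_config(alt, sample_sizes = 900, alpha = 0.05,
                           replicates = 200, master_seed = 13,
                           mechanisms = "nonprivate")
  s <- run_experiment(cfg)
  expect_gte(s$correct_rate, 0.99)
})
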