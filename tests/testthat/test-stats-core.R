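test_that("fisher_exact_2x2 reproduces printed enrichment statistics", {
  # placenta-predominant genes among DE genes: 38/119 vs 1371/14411
  res <- fisher_exact_2x2(38, 119, 1371, 14411)
  expect_equal(round(res$odds_ratio, 1), 3.4)
  expect_equal(res$p_value, 6.897121e-09, tolerance = 1e-4)
  expect_equal(res$p_value, oracle_fisher_p(38, 119, 1371, 14411),
               tolerance = 1e-12)

  # opposite-direction regulation: 15/17 preterm vs 9/17 term genes
  res2 <- fisher_exact_2x2(15, 2, 9, 8)
  expect_equal(round(res2$p_value, 3), 0.057)
  expect_equal(res2$p_value, oracle_fisher_p(15, 2, 9, 8), tolerance = 1e-12)

  # symmetric table carries no signal
  res3 <- fisher_exact_2x2(5, 5, 5, 5)
  expect_equal(res3$odds_ratio, 1)
  expect_equal(res3$p_value, 1)
})

test_that("fisher_exact_2x2 agrees with stats::fisher.test and is margin-swap invariant", {
  set.seed(11)
  for (i in 1:30) {
    tb <- as.integer(rpois(4, 8))
    if (sum(tb) == 0) next
    mine <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
    ref <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-7)
    # simultaneous row and column swap leaves OR and p unchanged
    swapped <- fisher_exact_2x2(tb[4], tb[3], tb[2], tb[1])
    expect_equal(mine$odds_ratio, swapped$odds_ratio)
    expect_equal(mine$p_value, swapped$p_value)
    for (alt in c("greater", "less")) {
      expect_equal(fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4], alt)$p_value,
                   oracle_fisher_p(tb[1], tb[2], tb[3], tb[4], alt),
                   tolerance = 1e-12)
    }
  }
})

test_that("fisher_exact_2x2 handles degenerate and invalid tables", {
  expect_equal(fisher_exact_2x2(5, 0, 3, 4)$odds_ratio, Inf)
  expect_true(is.finite(fisher_exact_2x2(5, 0, 3, 4)$p_value))
  # empty column margin: no association information
  expect_equal(fisher_exact_2x2(10, 0, 5, 0)$odds_ratio, 1)
  expect_equal(fisher_exact_2x2(10, 0, 5, 0)$p_value, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "margin")
})

test_that("bh_adjust matches the step-up definition", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_equal(q, oracle_bh(p))
  # adjusted values dominate raw values, and readjustment never shrinks
  expect_true(all(q >= p))
  expect_true(all(bh_adjust(q) >= q))
})

test_that("kendall_tau computes tie-corrected rank correlation", {
  expect_equal(kendall_tau(1:3, 1:3)$tau, 1)
  expect_equal(kendall_tau(1:3, 3:1)$tau, -1)
  # 6 pairs, one discordant: (5 - 1) / 6
  expect_equal(kendall_tau(1:4, c(1, 3, 2, 4))$tau, 2 / 3)
  # ties: agreement with R's tau-b
  x <- c(1, 1, 2, 3, 3, 4); y <- c(2, 1, 1, 3, 4, 4)
  expect_equal(kendall_tau(x, y)$tau, cor(x, y, method = "kendall"))
  expect_error(kendall_tau(rep(1, 5), 1:5), "undefined correlation")
  expect_error(kendall_tau(1:2, 1:2), "at least 3")
})

test_that("permutation_pvalue enumerates exhaustively and is seed independent", {
  vals <- c(10, 10, 0, 0)
  labs <- c("A", "A", "B", "B")
  stat <- function(v, l) mean(v[l == "A"]) - mean(v[l == "B"])
  res <- permutation_pvalue(vals, labs, stat, tail = "greater")
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, 6)
  expect_equal(res$p_value, 1 / 6)
  expect_equal(sort(res$null_statistics), c(-10, 0, 0, 0, 0, 10))
  # exhaustive result ignores the seed entirely
  res2 <- permutation_pvalue(vals, labs, stat, seed = 99, tail = "greater")
  expect_equal(res2$p_value, res$p_value)
  expect_equal(sort(res2$null_statistics), sort(res$null_statistics))
})

test_that("sampled permutation p uses +1 smoothing and stays positive", {
  set.seed(3)
  vals <- rnorm(12)
  labs <- rep(c("A", "B"), each = 6)
  stat <- function(v, l) mean(v[l == "A"]) - mean(v[l == "B"])
  res <- permutation_pvalue(vals, labs, stat, max_exhaustive = 10,
                            n_random = 200, seed = 42)
  expect_false(res$exhaustive)
  expect_equal(res$n_permutations, 200)
  expect_gt(res$p_value, 0)
  expect_equal(res$p_value,
               (1 + sum(res$null_statistics >= res$observed_statistic)) / 201)
  # same seed reproduces the sampled null
  res2 <- permutation_pvalue(vals, labs, stat, max_exhaustive = 10,
                             n_random = 200, seed = 42)
  expect_equal(res$null_statistics, res2$null_statistics)
  expect_error(permutation_pvalue(vals, rep("A", 12), stat), "two groups")
})

test_that("exhaustive permutation test is calibrated under the null", {
  set.seed(17)
  stat <- function(v, l) mean(v[l == "A"]) - mean(v[l == "B"])
  labs <- rep(c("A", "B"), each = 4)
  rejections <- replicate(500, {
    v <- rnorm(8)
    permutation_pvalue(v, sample(labs), stat, tail = "greater")$p_value <= 0.05
  })
  rate <- mean(rejections)
  # binomial 99% band around the attainable level 3/70 with 500 repeats
  level <- 3 / 70
  half <- 2.576 * sqrt(level * (1 - level) / 500)
  expect_gt(rate, level - half)
  expect_lt(rate, level + half)
})

test_that("power_simulation applies the >25% acceptance rule", {
  # deterministic 3-in-10 successes via a crafted generator: large effect in
  # 3 repeats, none otherwise
  counter <- new.env(); counter$i <- 0
  gen <- gen_k_of_n_successes(3, counter)
  res <- power_simulation(c(5, 5), gen, n_repeats = 10, tests = "paired_t")
  expect_equal(res$success_fraction, 0.3)
  expect_true(res$accepted)

  # very large planted effect: every repeat succeeds
  res_hi <- power_simulation(c(6, 6), list(delta = 10, sd = 0.5),
                             n_repeats = 20, seed = 1)
  expect_equal(res_hi$success_fraction[res_hi$test == "mann_whitney"], 1)
  expect_true(all(res_hi$accepted))

  # null effect: success fraction near alpha, below the acceptance cut
  res_null <- power_simulation(c(6, 6), list(delta = 0, sd = 1),
                               n_repeats = 400, tests = "paired_t", seed = 2)
  expect_lt(res_null$success_fraction, 0.12)
  expect_false(res_null$accepted)

  expect_error(power_simulation(c(5, 5), list(delta = 0, sd = 1),
                                n_repeats = 0), "at least 1")
  expect_error(power_simulation(c(5, 6), list(delta = 0, sd = 1),
                                tests = "paired_t"), "equal group sizes")
})
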