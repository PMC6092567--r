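two_group_samples <- function(n1, n2, batch = NULL) {
  n <- n1 + n2
  tibble::tibble(
    sample = sprintf("s%02d", seq_len(n)),
    group = c(rep("case", n1), rep("control", n2)),
    batch = batch %||% rep("B1", n)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("intensity filter drops genes that never clear the floor", {
  # each column is a permutation of the same values, so quantile
  # normalization is the identity and the rule applies to the constructed
  # values directly
  m <- cbind(
    s01 = c(low = 5.0, mid = 6.0, fill = 5.2, high = 7.0),
    s02 = c(5.2, 6.0, 5.0, 7.0),
    s03 = c(5.0, 5.2, 6.0, 7.0),
    s04 = c(5.2, 5.0, 6.0, 7.0)
  )
  st <- preprocess_filter(m, two_group_samples(2, 2), log2_input = TRUE)
  expect_false("low" %in% rownames(st$exprs))  # never exceeds log2(50) ~ 5.64
  expect_true("mid" %in% rownames(st$exprs))   # floor cleared in 2 samples
  expect_true("high" %in% rownames(st$exprs))
  expect_equal(attr(st, "n_retained"), 3)
  expect_error(preprocess_filter(m[, 1, drop = FALSE],
                                 two_group_samples(1, 0)), "2 samples")
})

test_that("quantile normalization preserves within-sample ranks", {
  set.seed(9)
  m <- matrix(2^rnorm(200, 8, 2), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:4)))
  st <- preprocess_filter(m, two_group_samples(2, 2), intensity_floor = -Inf)
  raw_log <- log2(m + 1)
  for (j in 1:4) {
    expect_equal(rank(st$exprs[, j]), rank(raw_log[, j]))
  }
  # columns with identical rank orders become identical after normalization
  m2 <- cbind(s01 = sort(2^rnorm(30, 8, 1)), s02 = sort(2^rnorm(30, 9, 1)))
  rownames(m2) <- sprintf("g%02d", 1:30)
  st2 <- preprocess_filter(m2, two_group_samples(1, 1),
                           intensity_floor = -Inf)
  expect_equal(st2$exprs[, 1], st2$exprs[, 2])
})

test_that("de_linear_model recovers a planted shift and calls nothing under the null", {
  st <- simulate_study(
    n_genes = 200, modules = list(module_spec(30, 0.8, direction = "up")),
    noise_sd = 0.2, seed = 13
  )
  de <- de_linear_model(st)
  truth <- st$genes$is_de_truth
  expect_gte(mean(de$de[truth]), 0.9)
  expect_true(all(de$direction[de$de & truth] == "up"))

  null_st <- simulate_study(n_genes = 200, modules = list(), seed = 14)
  de_null <- de_linear_model(null_st)
  expect_lte(sum(de_null$de), 2)

  # identical groups (case samples duplicate control samples exactly):
  # zero fold change by construction
  set.seed(20)
  half <- matrix(rnorm(8, 8, 1), 4, 2)
  m <- cbind(half, half)
  dimnames(m) <- list(paste0("g", 1:4), sprintf("s%02d", 1:4))
  st_id <- expression_study(m, two_group_samples(2, 2))
  de_id <- de_linear_model(st_id, design = ~ group)
  expect_equal(de_id$log2fc, rep(0, 4))
  expect_equal(sum(de_id$de), 0)
})

test_that("disabling shrinkage gives the ordinary least-squares t", {
  st <- simulate_study(n_genes = 40, n_cases = 6, n_controls = 6,
                       modules = list(), batch_levels = 1, seed = 15)
  de <- de_linear_model(st, design = ~ group, shrink = FALSE)
  # closed-form two-group t per gene
  grp <- st$samples$group
  for (g in sample(rownames(st$exprs), 5)) {
    y <- st$exprs[g, ]
    fit <- summary(lm(y ~ relevel(factor(grp), "control")))
    expect_equal(de$t[de$gene == g], fit$coefficients[2, "t value"],
                 tolerance = 1e-10)
  }
})

test_that("fold changes are antisymmetric under group-label swap", {
  st <- simulate_study(n_genes = 50, modules = list(
    module_spec(20, 0.8, direction = "up")), seed = 16)
  de <- de_linear_model(st)
  swapped <- st
  swapped$samples$group <- ifelse(st$samples$group == "case",
                                  "control", "case")
  de_sw <- de_linear_model(swapped)
  expect_equal(de_sw$log2fc, -de$log2fc)
  expect_equal(abs(de_sw$t), abs(de$t))
  # calls are invariant to gene ordering
  perm <- sample(nrow(st$exprs))
  st_perm <- expression_study(st$exprs[perm, ], st$samples,
                              st$genes[perm, ])
  de_perm <- de_linear_model(st_perm)
  expect_equal(de_perm$de[match(de$gene, de_perm$gene)], de$de)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  st <- simulate_study(n_genes = 20, modules = list(), seed = 17)
  st$samples$dup <- st$samples$MAP
  expect_error(
    de_linear_model(st, design = ~ group + MAP + dup),
    "dup"
  )
})

test_that("-dCt follows the reference-normalization formula", {
  ct <- tibble::tibble(
    sample = c("a", "a"), gene = c("RPLP0", "GENE1"), ct = c(20, 25)
  )
  out <- qpcr_delta_ct(ct)
  expect_equal(out$neg_delta_ct, -5)

  # a -dCt difference of 1 is a 2-fold expression difference
  ct2 <- tibble::tibble(
    sample = c("a", "a", "b", "b"),
    gene = rep(c("RPLP0", "GENE1"), 2), ct = c(20, 25, 20, 24)
  )
  out2 <- qpcr_delta_ct(ct2)
  expect_equal(2^diff(out2$neg_delta_ct), 2)

  expect_warning(
    qpcr_delta_ct(tibble::tibble(
      sample = c("a", "a", "b"),
      gene = c("RPLP0", "G1", "G1"), ct = c(20, 24, 25)
    )),
    "dropped"
  )
})

test_that("calibrator samples equalize -dCt across batches", {
  ct <- tibble::tibble(
    sample = c("cal", "cal", "x", "cal", "cal", "y"),
    batch = c("B1", "B1", "B1", "B2", "B2", "B2"),
    gene = c("RPLP0", "G1", "G1", "RPLP0", "G1", "G1"),
    ct = c(20, 25, 24, 20, 25.7, 24.7)
  )
  ct <- tibble::add_row(ct, sample = c("x", "y"), batch = c("B1", "B2"),
                        gene = "RPLP0", ct = 20)
  out <- qpcr_delta_ct(ct, calibrators = "cal")
  cal_vals <- out$neg_delta_ct[out$sample == "cal"]
  expect_equal(cal_vals[1], cal_vals[2])
  # the batch-2 sample received the same correction as its calibrator
  expect_equal(out$neg_delta_ct[out$sample == "y"],
               out$neg_delta_ct[out$sample == "x"] - 0.7 + 0.7)
})

test_that("qpcr_group_model separates stratum effects from the interaction", {
  set.seed(19)
  n_per <- 20
  grid <- tidyr::expand_grid(
    group = c("case", "control"), maturity = c("preterm", "term"),
    rep = seq_len(n_per)
  )
  grid$sample <- sprintf("s%03d", seq_len(nrow(grid)))
  # planted: preterm-only group shift of 1 -dCt unit
  d <- grid |>
    dplyr::mutate(
      gene = "G1",
      neg_delta_ct = rnorm(dplyr::n(), 0, 0.4) +
        ifelse(group == "case" & maturity == "preterm", 1, 0)
    )
  fit <- qpcr_group_model(d)
  expect_lt(fit$p_value[fit$term == "group@preterm"], 0.05)
  expect_lt(fit$p_value[fit$term == "interaction"], 0.05)
  expect_gt(fit$p_value[fit$term == "group@term"], 0.05)

  # identical shift in both strata: interaction coefficient near zero,
  # both stratum effects near the planted shift
  set.seed(190)
  d2 <- grid |>
    dplyr::mutate(
      gene = "G1",
      neg_delta_ct = rnorm(dplyr::n(), 0, 0.2) +
        ifelse(group == "case", 1, 0)
    )
  fit2 <- qpcr_group_model(d2)
  expect_lt(abs(fit2$estimate[fit2$term == "interaction"]), 0.4)
  expect_equal(fit2$estimate[grepl("group@", fit2$term)], c(1, 1),
               tolerance = 0.3)

  d3 <- dplyr::filter(d, !(group == "case" & maturity == "term"))
  expect_error(qpcr_group_model(d3), "stratum")
})
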