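test_that("soft thresholding and TOM follow the weighted-network formulas", {
  expect_equal(0.9^10, 0.3486784401) # adjacency of r = 0.9 at beta = 10
  st <- planted_two_module_study(seed = 41, n_genes = 30, size = 10)
  net1 <- build_network(st, beta = 1)
  expect_equal(net1$adjacency, net1$similarity) # beta = 1 identity
  net <- build_network(st, beta = 10)
  expect_equal(net$adjacency[1, 2], net$similarity[1, 2]^10)
  # direct-formula oracle: 3-gene toy with all off-diagonal a = 0.5
  toy <- matrix(0.5, 3, 3); diag(toy) <- 0
  expect_equal(oracle_tom(toy)[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5))
  # implementation against the oracle on random networks
  for (seed in 1:3) {
    stn <- simulate_study(n_genes = 10, modules = list(), seed = seed)
    netn <- build_network(stn, beta = 10)
    expect_equal(netn$tom, oracle_tom(netn$adjacency), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("network matrices satisfy their structural invariants", {
  st <- planted_two_module_study(seed = 42, n_genes = 60, size = 20)
  net <- build_network(st, beta = 10)
  expect_true(isSymmetric(net$tom))
  expect_true(all(net$tom >= 0 & net$tom <= 1 + 1e-12))
  expect_equal(unname(diag(net$tom)), rep(1, 60))
  # TOM dominates the normalized direct adjacency
  a <- net$adjacency; diag(a) <- 0
  k <- net$connectivity
  lower <- a / (outer(k, k, pmin) + 1 - a)
  off <- upper.tri(a)
  expect_true(all(net$tom[off] >= lower[off] - 1e-12))
  # raising beta weakly decreases every adjacency
  net20 <- build_network(st, beta = 20)
  expect_true(all(net20$adjacency <= net$adjacency + 1e-12))
  # constant gene: zero correlation with a warning
  m <- st$exprs[1:5, ]
  m[1, ] <- 3
  expect_warning(netc <- build_network(m, beta = 2), "constant")
  expect_equal(unname(netc$similarity[1, 2:5]), rep(0, 4))
})

test_that("planted modules are recovered exactly and noise stays unassigned", {
  skip_if_not_installed("mclust")
  st <- planted_two_module_study(seed = 43)
  mods <- detect_modules(build_network(st, beta = 10))
  ari <- mclust::adjustedRandIndex(mods$module, st$genes$module_truth)
  expect_equal(ari, 1)
  expect_equal(as.integer(sort(table(mods$module))), c(50L, 50L))

  noise <- simulate_study(n_genes = 100, modules = list(), seed = 44)
  mods_n <- detect_modules(build_network(noise, beta = 10))
  expect_gte(mean(mods_n$module == "unassigned"), 0.9)
})

test_that("undersized planted blocks are left unassigned", {
  st <- simulate_study(n_genes = 80,
                       modules = list(module_spec(20, 0.8)), seed = 45)
  mods <- detect_modules(build_network(st, beta = 10), min_module_size = 30)
  planted <- st$genes$module_truth == "M1"
  expect_true(all(mods$module[planted] == "unassigned"))
})

test_that("module detection is invariant to gene input order", {
  st <- planted_two_module_study(seed = 46)
  mods <- detect_modules(build_network(st, beta = 10))
  set.seed(1)
  perm <- sample(nrow(st$exprs))
  st_perm <- expression_study(st$exprs[perm, ], st$samples, st$genes[perm, ])
  mods_perm <- detect_modules(build_network(st_perm, beta = 10))
  reord <- mods_perm$module[match(mods$gene, mods_perm$gene)]
  expect_equal(reord, mods$module)
})

test_that("a degenerate all-equal distance matrix yields a single module", {
  net <- structure(
    list(tom = matrix(0.4, 20, 20,
                      dimnames = list(paste0("g", 1:20), paste0("g", 1:20)))),
    class = "coexpression_network"
  )
  diag(net$tom) <- 1
  expect_warning(mods <- detect_modules(net, min_module_size = 5), "equal")
  expect_true(all(mods$module == "M1"))
})

test_that("soft threshold 10 improves the scale-free topology fit over 1", {
  st <- simulate_study(
    n_genes = 150,
    modules = list(module_spec(50, 0.8), module_spec(50, 0.8)),
    seed = 47
  )
  fit10 <- scale_free_fit(build_network(st, beta = 10))
  fit1 <- scale_free_fit(build_network(st, beta = 1))
  expect_gt(fit10, fit1)
})

test_that("hub candidates are filtered and ranked by partner count", {
  # constructed study: hubA tracks 4 partner genes tightly, hubB tracks 1;
  # hubC sits below the intensity floor, hubD lacks the regulator flag
  set.seed(48)
  n <- 20
  sig <- rnorm(n)
  mk <- function(base, follow, noise) base + follow * sig + rnorm(n, 0, noise)
  m <- rbind(
    hubA = mk(10, 1, 0.1), hubB = mk(10, 1, 0.1),
    hubC = mk(8, 1, 0.1), # mean intensity below 9
    hubD = mk(10, 1, 0.1), # not flagged as regulator
    p1 = mk(9, 1, 0.1), p2 = mk(9, 1, 0.12), p3 = mk(9, 1, 0.15),
    q1 = mk(9, 0, 1), q2 = mk(9, 0, 1), q3 = mk(9, 0, 1)
  )
  # decorrelate hubB from the shared signal partners except p1
  m["hubB", ] <- 10 + rnorm(n, 0, 1)
  m["q1", ] <- 9 + 0.8 * m["hubB", ] - 8 + rnorm(n, 0, 0.1)
  colnames(m) <- sprintf("s%02d", seq_len(n))
  samples <- tibble::tibble(sample = colnames(m),
                            group = rep(c("case", "control"), each = n / 2))
  genes <- tibble::tibble(
    gene = rownames(m),
    is_tf = rownames(m) %in% c("hubA", "hubB", "hubC")
  )
  study <- expression_study(m, samples, genes)
  modules <- tibble::tibble(gene = rownames(m), module = "M1")
  hubs <- hub_candidates(study, modules)
  expect_false("hubC" %in% hubs$gene) # intensity gate
  expect_false("hubD" %in% hubs$gene) # regulator-flag gate
  expect_equal(hubs$gene[1], "hubA")  # most high-correlation partners
  expect_gt(hubs$n_partners[hubs$gene == "hubA"],
            hubs$n_partners[hubs$gene == "hubB"])
  expect_error(hub_candidates(study, modules, partner_set = character()),
               "empty partner set")
})

test_that("module_enrichment builds the correct 2x2 tables", {
  modules <- tibble::tibble(
    gene = sprintf("g%03d", 1:100),
    module = c(rep("M1", 10), rep("unassigned", 90))
  )
  # 8 of 10 module genes positive, 20 positives among all 100
  prop <- tibble::tibble(
    gene = modules$gene,
    property = c(rep(TRUE, 8), rep(FALSE, 2),
                 rep(TRUE, 12), rep(FALSE, 78))
  )
  res <- module_enrichment(modules, prop)
  expect_equal(res$a, 8)
  expect_equal(res$odds_ratio, 26) # (8/2) / (12/78)
  expect_equal(res$p_value, oracle_fisher_p(8, 2, 12, 78), tolerance = 1e-12)

  # equal proportions inside and out: OR = 1
  prop_eq <- tibble::tibble(
    gene = modules$gene,
    property = rep(c(TRUE, FALSE), 50)
  )
  expect_equal(module_enrichment(modules, prop_eq)$odds_ratio, 1)

  # property = membership itself: infinite OR
  prop_self <- tibble::tibble(
    gene = modules$gene, property = modules$module == "M1"
  )
  expect_equal(module_enrichment(modules, prop_self)$odds_ratio, Inf)
})
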