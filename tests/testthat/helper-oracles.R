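# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately avoid the code paths they verify.

# exact hypergeometric p for a 2x2 table via log-binomial coefficients;
# two-sided by the minimum-likelihood rule
oracle_fisher_p <- function(a, b, c, d, alternative = "two.sided") {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  p <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  switch(alternative,
    two.sided = sum(p[p <= p_obs * (1 + 1e-7)]),
    greater = sum(p[x >= a]),
    less = sum(p[x <= a])
  )
}

# step-up BH adjustment written directly from the definition:
# q_(i) = min over j >= i of p_(j) * m / j, in the sorted order
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(sorted[i:m] * m / (i:m))
  }
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}

# topological overlap from an adjacency matrix by direct triple loop
oracle_tom <- function(adj) {
  a <- adj
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
      tom[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# Poisson log-likelihood for a two-group rate model with exposure offset,
# maximized numerically; returns the fitted rate ratio group1 / group2.
# The likelihood separates over groups, so each rate is a 1-D maximization.
oracle_poisson_rate_ratio <- function(meth1, tot1, meth2, tot2) {
  rate <- function(meth, tot) {
    ll <- function(lam) sum(stats::dpois(meth, lam * tot, log = TRUE))
    stats::optimize(ll, c(1e-10, 1), maximum = TRUE, tol = 1e-12)$maximum
  }
  rate(meth1, tot1) / rate(meth2, tot2)
}

# deterministic paired-sample generator for the power-rule tests: the first
# k repeats carry a huge shift, the rest have exactly mean-zero non-constant
# paired differences (so the paired t is 0 and p = 1)
gen_k_of_n_successes <- function(k, counter) {
  function(n1, n2) {
    counter$i <- counter$i + 1
    delta <- if (counter$i <= k) 50 else 0
    x <- seq_len(n1) * 1e-3
    list(x = x, y = rev(x) + delta)
  }
}

# study with two planted trait-linked modules at the default 12-vs-5 design,
# shared by several recovery tests
planted_two_module_study <- function(seed, n_genes = 100, size = 50,
                                     n_cases = 12, n_controls = 5) {
  simulate_study(
    n_cases = n_cases, n_controls = n_controls, n_genes = n_genes,
    modules = list(
      module_spec(size, 0.8, trait_link = "BW", direction = "down"),
      module_spec(size, 0.8, trait_link = "MAP", direction = "up")
    ),
    seed = seed
  )
}

# small two-state pattern helper
pattern <- function(genes, states) {
  tibble::tibble(
    gene = genes,
    state = factor(states, levels = c("UP", "DN", "NS"))
  )
}
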