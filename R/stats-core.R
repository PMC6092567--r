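#' Fisher's exact test for a 2x2 contingency table
#'
#' Exact test of association for a 2x2 table of counts, as used throughout the
#' pipeline for gene-set and module enrichment. The odds ratio reported is the
#' sample (cross-product) odds ratio `ad / bc`, not the conditional maximum
#' likelihood estimate, so printed enrichment statistics such as "OR = 3.4"
#' can be reproduced directly from published counts. The p-value is computed
#' by hypergeometric enumeration over all tables with the observed margins;
#' the two-sided p follows the minimum-likelihood convention (sum of the
#' probabilities of all tables no more likely than the observed one).
#'
#' The table layout is: `a` = in-set & positive, `b` = in-set & negative,
#' `c` = out-of-set & positive, `d` = out-of-set & negative.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param alternative One of `"two.sided"`, `"greater"`, `"less"`. `"greater"`
#'   tests for enrichment of positives in the set (large `a`).
#' @return A one-row tibble with columns `odds_ratio`, `p_value`, `a`, `b`,
#'   `c`, `d` and `alternative`. `odds_ratio` is `Inf` when `b * c == 0`
#'   (and `a * d > 0`), and 1 for a table with an empty row or column
#'   margin (no association information).
#' @examples
#' # enrichment of placenta-predominant genes among differentially
#' # expressed genes (38 of 157 predominant, 1409 of 15939 DE overall)
#' fisher_exact_2x2(38, 119, 1371, 14411)
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) {
    stop("at least one margin must be positive", call. = FALSE)
  }
  # a zero row/column margin carries no association information: OR = 1
  or <- if (a * d == 0 && b * c == 0) 1 else (a * d) / (b * c)

  # hypergeometric enumeration conditional on the margins:
  # x = count in cell `a`, drawing (a+b) from an urn of (a+c) positives
  # and (b+d) negatives
  m <- a + c
  n <- b + d
  k <- a + b
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  rel_err <- 1 + 1e-7 # guards ties against floating-point noise
  p <- switch(alternative,
    two.sided = sum(dens[dens <= p_obs * rel_err]),
    greater   = sum(dens[support >= a]),
    less      = sum(dens[support <= a])
  )
  # new_tibble: this function is called in tight loops over many tables
  tibble::new_tibble(
    list(
      odds_ratio = or, p_value = min(p, 1),
      a = a, b = b, c = c, d = d, alternative = alternative
    ),
    nrow = 1L
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment, returning q-values in the order of
#' the input. Thin validated wrapper around [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Kendall rank correlation
#'
#' Tie-corrected Kendall tau (tau-b) with a two-sided p-value, used for
#' correlating CpG methylation ratios - which tie frequently - with clinical
#' and expression variables.
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither constant.
#' @return A one-row tibble with columns `tau`, `p_value` and `n`.
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall", alternative = "two.sided")
  )
  tibble::tibble(tau = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

# all distinct rearrangements of a two-group label vector, as a matrix with
# one arrangement per column (first group's positions chosen by combn)
.two_group_arrangements <- function(labels) {
  lev <- unique(labels)
  n <- length(labels)
  idx <- utils::combn(n, sum(labels == lev[1]))
  apply(idx, 2, function(i) {
    out <- rep(lev[2], n)
    out[i] <- lev[1]
    out
  })
}

#' Permutation p-value for a group-label statistic
#'
#' Generic permutation engine: the statistic is recomputed under rearranged
#' group labels, exhaustively when the number of distinct arrangements is
#' small enough, otherwise from a random sample of arrangements (default
#' 5,000). Exhaustive p is the raw proportion of arrangements at least as
#' extreme as the observed one (which is itself an arrangement, so p >= 1/P);
#' sampled p uses the standard +1 smoothing so p is never zero.
#'
#' @param values Data passed unchanged to `statistic`; typically a matrix
#'   with one column per labelled sample.
#' @param labels Vector of group labels with exactly two distinct values and
#'   at least two members per group.
#' @param statistic Function of `(values, labels)` returning a single number.
#' @param max_exhaustive Enumerate all arrangements when their count is at
#'   most this (default 20,000).
#' @param n_random Number of random arrangements otherwise (default 5,000).
#' @param seed Optional integer seed for the random-sampling branch.
#' @param tail `"greater"`, `"less"` or `"two.sided"` (extremity of the
#'   absolute statistic).
#' @return A `permutation_result`: list with `observed_statistic`,
#'   `null_statistics`, `p_value`, `exhaustive`, `n_permutations`, `seed`.
#' @export
permutation_pvalue <- function(values, labels, statistic,
                               max_exhaustive = 20000, n_random = 5000,
                               seed = NULL,
                               tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  labels <- as.vector(labels)
  tab <- table(labels)
  if (length(tab) != 2) stop("labels must contain exactly two groups", call. = FALSE)
  if (any(tab < 2)) stop("each group needs at least 2 members", call. = FALSE)
  n_arr <- choose(length(labels), tab[[1]])
  observed <- statistic(values, labels)

  exhaustive <- n_arr <= max_exhaustive
  if (exhaustive) {
    arr <- .two_group_arrangements(labels)
    null_stats <- apply(arr, 2, function(l) statistic(values, l))
    n_perm <- ncol(arr)
    extreme <- switch(tail,
      greater   = sum(null_stats >= observed),
      less      = sum(null_stats <= observed),
      two.sided = sum(abs(null_stats) >= abs(observed))
    )
    p <- extreme / n_perm
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    null_stats <- replicate(n_random, statistic(values, sample(labels)))
    n_perm <- n_random
    extreme <- switch(tail,
      greater   = sum(null_stats >= observed),
      less      = sum(null_stats <= observed),
      two.sided = sum(abs(null_stats) >= abs(observed))
    )
    p <- (1 + extreme) / (1 + n_random)
  }
  structure(
    list(
      observed_statistic = observed, null_statistics = null_stats,
      p_value = p, exhaustive = exhaustive, n_permutations = n_perm,
      seed = seed, tail = tail
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s null, %d arrangements)\n  observed = %.4g, p = %.4g (%s)\n",
    if (x$exhaustive) "exhaustive" else "sampled",
    x$n_permutations, x$observed_statistic, x$p_value, x$tail
  ))
  invisible(x)
}

#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(
    observed_statistic = x$observed_statistic, p_value = x$p_value,
    n_permutations = x$n_permutations, exhaustive = x$exhaustive
  )
}

#' Simulation-based power estimate with an acceptance rule
#'
#' Repeatedly simulates a two-group comparison and records the fraction of
#' repeats reaching `p < alpha` under paired t and/or Mann-Whitney tests.
#' The planned design is accepted when the success fraction exceeds the
#' acceptance threshold (default 25%), the rule used to green-light an
#' extended targeted-proteomics validation from pilot data.
#'
#' @param group_sizes Integer pair `(n1, n2)`, each at least 2; the paired t
#'   test requires `n1 == n2`.
#' @param effect Either a function `(n1, n2)` returning `list(x =, y =)`
#'   numeric vectors, or a list with elements `delta` (mean shift) and `sd`
#'   (noise standard deviation) for Gaussian samples.
#' @param n_repeats Number of simulation repeats (10, 100 or 1000 typical).
#' @param tests Character subset of `c("paired_t", "mann_whitney")`.
#' @param alpha Significance level counted as a success (default 0.05).
#' @param accept_threshold Acceptance cut on the success fraction (default 0.25).
#' @param seed Optional integer seed.
#' @return A tibble with one row per test: `test`, `success_fraction`,
#'   `accepted`, `n_repeats`.
#' @export
power_simulation <- function(group_sizes, effect, n_repeats = 100,
                             tests = c("paired_t", "mann_whitney"),
                             alpha = 0.05, accept_threshold = 0.25,
                             seed = NULL) {
  tests <- match.arg(tests, several.ok = TRUE)
  if (n_repeats < 1) stop("n_repeats must be at least 1", call. = FALSE)
  n1 <- group_sizes[[1]]; n2 <- group_sizes[[2]]
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2", call. = FALSE)
  if ("paired_t" %in% tests && n1 != n2) {
    stop("paired_t requires equal group sizes", call. = FALSE)
  }
  gen <- if (is.function(effect)) {
    effect
  } else {
    function(n1, n2) list(
      x = stats::rnorm(n1, 0, effect$sd),
      y = stats::rnorm(n2, effect$delta, effect$sd)
    )
  }
  if (!is.null(seed)) set.seed(seed)
  hits <- matrix(FALSE, n_repeats, length(tests), dimnames = list(NULL, tests))
  for (r in seq_len(n_repeats)) {
    d <- gen(n1, n2)
    for (tst in tests) {
      p <- if (tst == "paired_t") {
        stats::t.test(d$x, d$y, paired = TRUE)$p.value
      } else {
        suppressWarnings(stats::wilcox.test(d$x, d$y)$p.value)
      }
      hits[r, tst] <- is.finite(p) && p < alpha
    }
  }
  frac <- colMeans(hits)
  tibble::tibble(
    test = tests,
    success_fraction = unname(frac[tests]),
    accepted = unname(frac[tests] > accept_threshold),
    n_repeats = n_repeats
  )
}
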