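#' Coverage-filtered CpG methylation ratios
#'
#' Sums repeated sequencing runs of the same sample at the same CpG
#' (methylated and total counts), drops sites with total coverage below
#' `min_coverage` reads (default 4), and computes the methylation ratio
#' methylated / total. Positions are 1-based and reported exactly as input.
#'
#' @param counts Tibble with columns `chrom`, `pos`, `sample`, `group`,
#'   `methylated`, `total` (e.g. from [simulate_methylation_counts()]).
#' @param min_coverage Minimum summed total reads to keep a
#'   sample-at-a-CpG (default 4).
#' @return Tibble `chrom`, `pos`, `sample`, `group`, `methylated`,
#'   `total`, `ratio`.
#' @export
filter_and_ratio <- function(counts, min_coverage = 4) {
  counts <- tibble::as_tibble(counts)
  need <- c("chrom", "pos", "sample", "group", "methylated", "total")
  if (!all(need %in% names(counts))) {
    stop("need columns chrom, pos, sample, group, methylated, total",
         call. = FALSE)
  }
  if (any(counts$methylated > counts$total) || any(counts$methylated < 0)) {
    stop("methylated counts must lie in [0, total]", call. = FALSE)
  }
  counts |>
    dplyr::group_by(.data$chrom, .data$pos, .data$sample, .data$group) |>
    dplyr::summarise(
      methylated = sum(.data$methylated),
      total = sum(.data$total),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$total >= min_coverage) |>
    dplyr::mutate(ratio = .data$methylated / .data$total)
}

# Poisson GLM of methylated counts on group with log(total) offset; the
# group coefficient is a log rate ratio of methylation. Falls back to a
# two-sample t-test on ratios when either group has all-zero methylated
# counts (the Poisson MLE diverges there).
.compare_one_cpg <- function(d, groups) {
  g1 <- d[d$group == groups[1], ]; g2 <- d[d$group == groups[2], ]
  delta <- mean(g1$ratio) - mean(g2$ratio)
  all_zero <- sum(g1$methylated) == 0 || sum(g2$methylated) == 0
  if (all_zero) {
    p <- if (stats::sd(g1$ratio) == 0 && stats::sd(g2$ratio) == 0) {
      1 # both groups constant (e.g. all-zero vs all-zero)
    } else {
      stats::t.test(g1$ratio, g2$ratio)$p.value
    }
    return(tibble::tibble(test = "t_test", p_value = p, delta = delta,
                          rate_ratio = NA_real_))
  }
  d$group <- factor(d$group, levels = rev(groups)) # groups[1] vs reference groups[2]
  fit <- stats::glm(methylated ~ group + offset(log(total)),
                    family = stats::poisson(), data = d)
  sm <- summary(fit)$coefficients
  coef_row <- paste0("group", groups[1])
  tibble::tibble(
    test = "poisson_glm",
    p_value = sm[coef_row, "Pr(>|z|)"],
    delta = delta,
    rate_ratio = exp(sm[coef_row, "Estimate"])
  )
}

#' Group comparison of CpG methylation
#'
#' Per CpG, compares methylation between two groups using a Poisson
#' generalized linear model with log link on the methylated counts, with
#' the log of the total counts as offset (the group coefficient is then a
#' log rate ratio of methylation). When all samples in either group have
#' zero methylated counts - where the Poisson maximum-likelihood estimate
#' diverges - a Student's t-test on the per-sample ratios is used instead.
#' The ratio difference and the mild/moderate/strong class from
#' [classify_dm()] are reported alongside.
#'
#' @param counts Count tibble as for [filter_and_ratio()] (filtering and
#'   run-summing are applied first).
#' @param min_coverage Coverage filter passed on (default 4).
#' @param min_group_n Minimum samples per group after filtering (default
#'   2); CpGs below it are skipped with a reason.
#' @return Tibble: `chrom`, `pos`, `ratio_<group1>`, `ratio_<group2>`,
#'   `delta`, `rate_ratio`, `test`, `p_value`, `class`. Skipped CpGs are
#'   collected in the `skipped` attribute.
#' @export
compare_groups <- function(counts, min_coverage = 4, min_group_n = 2) {
  ratios <- filter_and_ratio(counts, min_coverage = min_coverage)
  groups <- sort(unique(ratios$group))
  if (length(groups) != 2) stop("need exactly two groups", call. = FALSE)
  skipped <- tibble::tibble(chrom = character(), pos = integer(),
                            reason = character())
  res <- ratios |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::group_map(function(d, key) {
      n_per <- table(factor(d$group, levels = groups))
      if (any(n_per < min_group_n)) {
        skipped <<- dplyr::bind_rows(skipped, tibble::tibble(
          chrom = key$chrom, pos = key$pos,
          reason = sprintf("group below %d samples after filtering", min_group_n)
        ))
        return(NULL)
      }
      cmp <- .compare_one_cpg(d, groups)
      out <- tibble::tibble(
        chrom = key$chrom, pos = key$pos,
        r1 = mean(d$ratio[d$group == groups[1]]),
        r2 = mean(d$ratio[d$group == groups[2]])
      )
      dplyr::bind_cols(out, cmp)
    }) |>
    dplyr::bind_rows()
  if (nrow(res) > 0) {
    res$class <- classify_dm(res$p_value, res$delta)
    names(res)[names(res) == "r1"] <- paste0("ratio_", groups[1])
    names(res)[names(res) == "r2"] <- paste0("ratio_", groups[2])
  }
  attr(res, "skipped") <- skipped
  res
}

#' Nonparametric clinical-group comparison of CpG methylation
#'
#' For clinical cohorts, the two-sided Wilcoxon rank-sum test on per-sample
#' methylation ratios, considering only CpGs where both groups retain at
#' least `min_group_n` samples (default 4) after coverage filtering.
#'
#' @inheritParams compare_groups
#' @param min_group_n Minimum per-group sample size (default 4).
#' @return As [compare_groups()] but with `test = "wilcoxon"` and no rate
#'   ratio.
#' @export
compare_groups_clinical <- function(counts, min_coverage = 4, min_group_n = 4) {
  ratios <- filter_and_ratio(counts, min_coverage = min_coverage)
  groups <- sort(unique(ratios$group))
  if (length(groups) != 2) stop("need exactly two groups", call. = FALSE)
  skipped <- tibble::tibble(chrom = character(), pos = integer(),
                            reason = character())
  res <- ratios |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::group_map(function(d, key) {
      n_per <- table(factor(d$group, levels = groups))
      if (any(n_per < min_group_n)) {
        skipped <<- dplyr::bind_rows(skipped, tibble::tibble(
          chrom = key$chrom, pos = key$pos,
          reason = sprintf("group below %d samples", min_group_n)
        ))
        return(NULL)
      }
      x <- d$ratio[d$group == groups[1]]; y <- d$ratio[d$group == groups[2]]
      p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
      tibble::tibble(
        chrom = key$chrom, pos = key$pos,
        r1 = mean(x), r2 = mean(y),
        test = "wilcoxon", p_value = p, delta = mean(x) - mean(y)
      )
    }) |>
    dplyr::bind_rows()
  if (nrow(res) > 0) {
    res$class <- classify_dm(res$p_value, res$delta)
    names(res)[names(res) == "r1"] <- paste0("ratio_", groups[1])
    names(res)[names(res) == "r2"] <- paste0("ratio_", groups[2])
  }
  if (nrow(skipped) > 0) {
    message(sprintf("%d CpG(s) skipped (group size below %d)",
                    nrow(skipped), min_group_n))
  }
  attr(res, "skipped") <- skipped
  res
}

#' Classify a differential-methylation call
#'
#' Differential methylation is mild, moderate or strong when p < 0.05 and
#' the absolute difference in methylation ratios is at least 0.125, 0.25 or
#' 0.5 respectively (the highest tier whose threshold is met); otherwise
#' none. The tiers are nested: every strong call also satisfies the
#' moderate and mild thresholds.
#'
#' @param p Numeric vector of p-values.
#' @param delta Numeric vector of methylation-ratio differences in
#'   `[-1, 1]`.
#' @param alpha Significance gate (default 0.05).
#' @return Factor with levels none < mild < moderate < strong.
#' @export
classify_dm <- function(p, delta, alpha = 0.05) {
  if (any(abs(delta) > 1, na.rm = TRUE)) {
    stop("ratio differences must lie in [-1, 1]", call. = FALSE)
  }
  cls <- dplyr::case_when(
    is.na(p) | is.na(delta) ~ "none",
    p >= alpha ~ "none",
    abs(delta) >= 0.5 ~ "strong",
    abs(delta) >= 0.25 ~ "moderate",
    abs(delta) >= 0.125 ~ "mild",
    .default = "none"
  )
  factor(cls, levels = c("none", "mild", "moderate", "strong"), ordered = TRUE)
}

#' Kendall correlation of CpG methylation with a clinical variable
#'
#' Per CpG, the tie-corrected Kendall tau between per-sample methylation
#' ratios and a clinical, demographic or expression variable; significant
#' at p < 0.05. CpGs with constant ratios or fewer than `min_pairs` paired
#' observations are skipped.
#'
#' @param ratios Tibble `chrom`, `pos`, `sample`, `ratio` (e.g. from
#'   [filter_and_ratio()]).
#' @param clinical Tibble `sample`, `value`.
#' @param min_pairs Minimum paired observations (default 5).
#' @param alpha Significance level (default 0.05).
#' @return Tibble: `chrom`, `pos`, `tau`, `p_value`, `n`, `significant`.
#' @export
methylation_clinical_correlation <- function(ratios, clinical, min_pairs = 5,
                                             alpha = 0.05) {
  d <- dplyr::inner_join(tibble::as_tibble(ratios),
                         tibble::as_tibble(clinical), by = "sample")
  res <- d |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::group_map(function(g, key) {
      ok <- stats::complete.cases(g$ratio, g$value)
      if (sum(ok) < min_pairs ||
          stats::sd(g$ratio[ok]) == 0 || stats::sd(g$value[ok]) == 0) {
        return(NULL)
      }
      kt <- kendall_tau(g$ratio[ok], g$value[ok])
      tibble::tibble(chrom = key$chrom, pos = key$pos,
                     tau = kt$tau, p_value = kt$p_value, n = kt$n)
    }) |>
    dplyr::bind_rows()
  if (nrow(res) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          tau = numeric(), p_value = numeric(),
                          n = integer(), significant = logical()))
  }
  dplyr::mutate(res, significant = .data$p_value < alpha)
}
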