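#' Specify a planted co-expression module
#'
#' Helper building one module specification for [simulate_study()]. Each
#' module is driven by a single latent eigen-signal with per-gene loadings
#' drawn uniformly from (0.5, 1); the signal scale is chosen so that the
#' expected pairwise within-module correlation matches `within_correlation`.
#'
#' @param size Number of genes in the module.
#' @param within_correlation Target mean absolute pairwise Pearson
#'   correlation among module genes, in (0, 1).
#' @param trait_link Which clinical trait the module eigen-signal drives:
#'   `"MAP"` (mean arterial pressure), `"BW"` (birthweight percentile) or
#'   `"none"`.
#' @param direction Case-vs-control differential expression of the module
#'   genes: `"up"`, `"down"` or `"none"`.
#' @param log2fc Magnitude of the planted case-control shift in log2 units
#'   (sign taken from `direction`).
#' @param trait_correlation Target correlation between the module activity
#'   (eigen-signal plus any case-control shift) and the linked trait.
#' @return A list of class `module_spec`.
#' @export
module_spec <- function(size, within_correlation = 0.8,
                        trait_link = c("none", "MAP", "BW"),
                        direction = c("none", "up", "down"),
                        log2fc = 1, trait_correlation = 0.8) {
  trait_link <- match.arg(trait_link)
  direction <- match.arg(direction)
  if (within_correlation <= 0 || within_correlation >= 1) {
    stop("within_correlation must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      size = as.integer(size), within_correlation = within_correlation,
      trait_link = trait_link, direction = direction,
      log2fc = log2fc, trait_correlation = trait_correlation
    ),
    class = "module_spec"
  )
}

#' Simulate a two-condition placental expression study
#'
#' Generates a log2 gene-by-sample matrix with the statistical structure the
#' downstream pipeline assumes: per-gene baselines, an additive
#' gene-independent batch offset, planted co-expression modules whose latent
#' eigen-signals optionally drive the clinical traits (MAP, birthweight
#' percentile) and carry case-vs-control shifts, and i.i.d. Gaussian noise.
#' Defaults emulate a preterm preeclampsia case-control design of 12 cases
#' and 5 gestational-age-matched controls.
#'
#' Ground truth (true module, DE status and direction per gene) is attached
#' to the returned study's `genes` table for parameter-recovery testing.
#'
#' @param n_cases,n_controls Group sizes (default 12 vs 5).
#' @param n_genes Total genes (default 500).
#' @param modules List of [module_spec()] objects; module sizes must sum to
#'   at most `n_genes`. Defaults to two trait-linked modules emulating a
#'   birthweight-linked down-regulated module and a blood-pressure-linked
#'   up-regulated module.
#' @param batch_levels Number of hybridization batches (default 2).
#' @param noise_sd Residual noise standard deviation in log2 units
#'   (default 0.2).
#' @param baseline_mean,baseline_sd Per-gene baseline distribution in log2
#'   units (default N(8, 1.5)).
#' @param batch_sd Standard deviation of the additive per-batch offset
#'   (default 0.3 log2 units).
#' @param tf_fraction Fraction of genes flagged as transcription regulators.
#' @param seed Optional integer seed; the generator is a pure function of
#'   its arguments and the seed.
#' @return An [expression_study()] with truth columns `module_truth`,
#'   `is_de_truth`, `de_direction` in `$genes`.
#' @export
simulate_study <- function(n_cases = 12, n_controls = 5, n_genes = 500,
                           modules = list(
                             module_spec(50, 0.8, trait_link = "BW",
                                         direction = "down", log2fc = 1),
                             module_spec(50, 0.8, trait_link = "MAP",
                                         direction = "up", log2fc = 1)
                           ),
                           batch_levels = 2, noise_sd = 0.2,
                           baseline_mean = 8, baseline_sd = 1.5,
                           batch_sd = 0.3, tf_fraction = 0.15,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- vapply(modules, function(m) m$size, integer(1))
  if (sum(sizes) > n_genes) stop("module sizes exceed n_genes", call. = FALSE)
  n <- n_cases + n_controls
  if (n < 3) stop("need at least 3 samples", call. = FALSE)

  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  sample_ids <- sprintf("S%02d", seq_len(n))
  group <- c(rep("case", n_cases), rep("control", n_controls))
  batch <- sprintf("B%d", rep_len(seq_len(batch_levels), n))

  baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  batch_off <- stats::rnorm(batch_levels, 0, batch_sd)[as.integer(factor(batch))]

  exprs <- matrix(baseline, n_genes, n) +
    matrix(batch_off, n_genes, n, byrow = TRUE) +
    matrix(stats::rnorm(n_genes * n, 0, noise_sd), n_genes, n)

  module_truth <- rep("none", n_genes)
  is_de <- rep(FALSE, n_genes)
  de_dir <- rep("none", n_genes)
  eigens <- list()
  at <- 0L
  for (m in seq_along(modules)) {
    sp <- modules[[m]]
    idx <- at + seq_len(sp$size)
    at <- at + sp$size
    lab <- sprintf("M%d", m)
    module_truth[idx] <- lab
    e <- stats::rnorm(n)
    # orthogonalize against earlier module eigen-signals so the planted
    # between-module independence holds exactly in-sample (at 17 samples
    # the raw correlation of two random vectors is far from negligible)
    e <- e - mean(e)
    # also orthogonalize against the group indicator: the planted DE shift
    # is the *only* group effect, so a module's fold changes do not drift
    # with the eigen-signal's chance group imbalance
    g_c <- (group == "case") - mean(group == "case")
    e <- e - sum(e * g_c) / sum(g_c^2) * g_c
    for (prev in eigens) {
      e <- e - sum(e * prev$eigen) / sum(prev$eigen^2) * prev$eigen
    }
    e <- (e - mean(e)) / stats::sd(e)
    eigens[[lab]] <- list(eigen = e, spec = sp)
    # scale so expected within-module |cor| ~ within_correlation at the
    # mean loading 0.75: ubar^2 s^2 / (ubar^2 s^2 + noise^2) = r
    r <- sp$within_correlation
    s <- sqrt(r / (1 - r)) * noise_sd / 0.75
    load <- stats::runif(sp$size, 0.5, 1)
    exprs[idx, ] <- exprs[idx, ] + outer(load * s, e)
    activity <- s * e
    if (sp$direction != "none") {
      shift <- if (sp$direction == "up") sp$log2fc else -sp$log2fc
      exprs[idx, group == "case"] <- exprs[idx, group == "case"] + shift
      is_de[idx] <- TRUE
      de_dir[idx] <- sp$direction
      # the disease shift is part of the module's activity: a linked trait
      # must co-vary with case status (hypertension defines the cases)
      activity <- activity + shift * (group == "case")
    }
    eigens[[lab]]$activity <- (activity - mean(activity)) / stats::sd(activity)
  }

  mix_trait <- function(e, rho, center, scale) {
    z <- rho * e + sqrt(1 - rho^2) * stats::rnorm(n)
    center + scale * z
  }
  map_mod <- Filter(function(x) x$spec$trait_link == "MAP", eigens)
  bw_mod <- Filter(function(x) x$spec$trait_link == "BW", eigens)
  MAP <- if (length(map_mod)) {
    mix_trait(map_mod[[1]]$activity, map_mod[[1]]$spec$trait_correlation,
              105, 15)
  } else {
    ifelse(group == "case", stats::rnorm(n, 115, 10), stats::rnorm(n, 90, 8))
  }
  BW <- if (length(bw_mod)) {
    mix_trait(bw_mod[[1]]$activity, bw_mod[[1]]$spec$trait_correlation,
              50, 25)
  } else {
    ifelse(group == "case", stats::rnorm(n, 20, 15), stats::rnorm(n, 55, 20))
  }
  BW <- pmin(pmax(BW, 0.5), 99.5)
  MAP <- pmax(MAP, 60)

  samples <- tibble::tibble(
    sample = sample_ids, group = group, batch = batch,
    maturity = "preterm",
    MAP = MAP, BW_percentile = BW,
    GA_weeks = stats::runif(n, 28, 34)
  )
  genes <- tibble::tibble(
    gene = gene_ids,
    chromosome = sample(paste0("chr", c(1:22, "X")), n_genes, replace = TRUE),
    is_tf = stats::runif(n_genes) < tf_fraction,
    is_placenta_predominant = stats::runif(n_genes) < 0.05,
    module_truth = module_truth, is_de_truth = is_de, de_direction = de_dir,
    baseline = baseline
  )
  rownames(exprs) <- gene_ids
  colnames(exprs) <- sample_ids
  expression_study(exprs, samples, genes)
}

#' Simulate a multi-tissue expression atlas
#'
#' Builds a linear-scale gene-by-tissue matrix (79 tissues by default) in
#' which exactly `n_target_specific` genes satisfy, by construction, all
#' three predominant-expression rules tested by [call_predominant()] at its
#' default thresholds: target level at least 1,000 units, at least 6 times
#' the median of the other tissues, and at least 2 times the second-highest
#' tissue. The remaining genes are constructed to fail at least one rule:
#' half are expressed below the absolute-level floor in the target tissue,
#' half are ubiquitously high so the fold rules fail.
#'
#' @param n_genes Total genes (default 500).
#' @param n_tissues Number of tissues including the target (default 79).
#' @param n_target_specific Number of constructed target-predominant genes.
#' @param specific_level Linear-scale expression of specific genes in the
#'   target tissue; must satisfy the absolute-level rule (default 3000).
#' @param background_level Scale of background expression (default 150).
#' @param target_tissue Name of the target tissue column (default
#'   `"placenta"`).
#' @param min_level Absolute-level rule the construction must honour
#'   (default 1000).
#' @param seed Optional integer seed.
#' @return A tibble (first column `gene`, one column per tissue) with
#'   attributes `target_tissue` and `truth` (tibble of `gene`,
#'   `is_target_specific`).
#' @export
simulate_atlas <- function(n_genes = 500, n_tissues = 79,
                           n_target_specific = 20,
                           specific_level = 3000, background_level = 150,
                           target_tissue = "placenta", min_level = 1000,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_target_specific > n_genes) {
    stop("n_target_specific must not exceed n_genes", call. = FALSE)
  }
  if (specific_level < min_level) {
    stop("specific_level violates the absolute-level rule by construction",
         call. = FALSE)
  }
  if (n_tissues < 2) stop("need at least 2 tissues", call. = FALSE)
  other_names <- sprintf("tissue_%02d", seq_len(n_tissues - 1))
  gene_ids <- sprintf("A%04d", seq_len(n_genes))
  mat <- matrix(0, n_genes, n_tissues,
                dimnames = list(gene_ids, c(target_tissue, other_names)))
  specific <- seq_len(n_genes) <= n_target_specific
  # other-tissue cap keeping both fold rules satisfied with margin
  cap <- 0.9 * min(specific_level / 6, specific_level / 2)
  for (g in seq_len(n_genes)) {
    if (specific[g]) {
      mat[g, 1] <- specific_level * stats::runif(1, 1, 1.5)
      mat[g, -1] <- stats::runif(n_tissues - 1, 1, cap)
    } else if (g %% 2 == 0) {
      # below the absolute floor in the target tissue
      mat[g, 1] <- stats::runif(1, 1, 0.9 * min_level)
      mat[g, -1] <- stats::runif(n_tissues - 1, 1, 4 * background_level)
    } else {
      # ubiquitous: high everywhere, fold rules fail
      mat[g, 1] <- stats::runif(1, min_level, 2 * min_level)
      mat[g, -1] <- stats::runif(n_tissues - 1, 1.5 * min_level, 3 * min_level)
    }
  }
  atlas <- tibble::as_tibble(mat, rownames = "gene")
  attr(atlas, "target_tissue") <- target_tissue
  attr(atlas, "truth") <- tibble::tibble(
    gene = gene_ids, is_target_specific = specific
  )
  atlas
}

#' Simulate a literature biomarker database
#'
#' Emulates a meta-database of maternal-blood biomarker measurements in
#' preterm preeclampsia, expressed as percent of gestational-age-matched
#' control levels and linear in gestational week. Defaults plant the
#' qualitative pattern the virtual liquid biopsy is designed to detect:
#' one marker constantly below control levels, the others starting below
#' control and rising through gestation.
#'
#' @param markers Character vector of marker ids.
#' @param slope_per_week Percent-of-control change per gestational week,
#'   recycled over markers.
#' @param intercept_percent Percent of control at week 0, recycled.
#' @param n_per_marker Measurements simulated per marker.
#' @param weeks_range Length-2 numeric range of gestational weeks sampled.
#' @param noise_sd Measurement noise in percent-of-control units.
#' @param seed Optional integer seed.
#' @return A tibble with columns `study`, `marker`, `week`,
#'   `percent_of_control`.
#' @export
simulate_biomarker_db <- function(markers = c("CSH1", "ENG", "FLT1", "LEP", "CGB3"),
                                  slope_per_week = c(0, 5, 5, 5, 5),
                                  intercept_percent = c(70, 40, 40, 40, 40),
                                  n_per_marker = 30,
                                  weeks_range = c(8, 36),
                                  noise_sd = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(weeks_range) != 2 || diff(weeks_range) <= 0) {
    stop("weeks_range must be an increasing length-2 range", call. = FALSE)
  }
  slope <- rep_len(slope_per_week, length(markers))
  icpt <- rep_len(intercept_percent, length(markers))
  purrr::map2_dfr(seq_along(markers), markers, function(i, mk) {
    wk <- stats::runif(n_per_marker, weeks_range[1], weeks_range[2])
    tibble::tibble(
      study = sprintf("S%03d", sample.int(61, n_per_marker, replace = TRUE)),
      marker = mk,
      week = wk,
      percent_of_control = pmax(
        icpt[i] + slope[i] * wk + stats::rnorm(n_per_marker, 0, noise_sd), 1
      )
    )
  })
}

#' Simulate a targeted bisulfite CpG count table
#'
#' Per-sample methylated/total read counts at CpG sites, with
#' negative-binomial sequencing depths (floored at one read) and binomial
#' methylated counts. A chosen subset of CpGs carries a planted group
#' difference in methylation ratio.
#'
#' @param n_cpgs Number of CpG sites (default 24).
#' @param samples_per_group Samples in each of the two groups (default 5).
#' @param mean_depth Mean total read count per CpG per sample (default 30).
#' @param depth_dispersion Negative-binomial size parameter (default 5).
#' @param baseline_ratio Methylation ratio of unplanted CpGs in both groups
#'   and of planted CpGs in the second group.
#' @param planted_delta Ratio increase in the first group at planted CpGs;
#'   `baseline_ratio + planted_delta` must lie in `[0, 1]`.
#' @param n_planted Number of planted CpGs (the first `n_planted` positions).
#' @param groups Length-2 character vector of group labels; the first group
#'   carries the planted shift.
#' @param chrom Chromosome name for all sites.
#' @param seed Optional integer seed.
#' @return A tibble with columns `chrom`, `pos` (1-based), `sample`,
#'   `group`, `methylated`, `total`, and a `truth` attribute flagging
#'   planted sites.
#' @export
simulate_methylation_counts <- function(n_cpgs = 24, samples_per_group = 5,
                                        mean_depth = 30, depth_dispersion = 5,
                                        baseline_ratio = 0.3,
                                        planted_delta = 0.3, n_planted = 8,
                                        groups = c("case", "control"),
                                        chrom = "chr19", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shifted <- baseline_ratio + planted_delta
  if (baseline_ratio < 0 || baseline_ratio > 1 || shifted < 0 || shifted > 1) {
    stop("baseline_ratio + planted_delta must lie in [0, 1]", call. = FALSE)
  }
  if (n_planted > n_cpgs) stop("n_planted must not exceed n_cpgs", call. = FALSE)
  pos <- sort(sample(1e6:3e6, n_cpgs))
  planted <- seq_len(n_cpgs) <= n_planted
  samples <- c(
    sprintf("%s_%02d", groups[1], seq_len(samples_per_group)),
    sprintf("%s_%02d", groups[2], seq_len(samples_per_group))
  )
  grp <- rep(groups, each = samples_per_group)
  rows <- purrr::map_dfr(seq_len(n_cpgs), function(i) {
    total <- pmax(stats::rnbinom(length(samples), mu = mean_depth,
                                 size = depth_dispersion), 1L)
    p <- ifelse(planted[i] & grp == groups[1], shifted, baseline_ratio)
    tibble::tibble(
      chrom = chrom, pos = pos[i], sample = samples, group = grp,
      methylated = stats::rbinom(length(samples), total, p),
      total = total
    )
  })
  attr(rows, "truth") <- tibble::tibble(
    chrom = chrom, pos = pos, planted = planted
  )
  rows
}
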