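#' Maternal vascular malperfusion score
#'
#' Integer count of placental histologic lesions in the maternal vascular
#' malperfusion category: the arithmetic sum of binary lesion flags.
#'
#' @param lesions Either a numeric/logical vector of 0/1 flags for one
#'   placenta, or a data frame with a `sample` column and one binary column
#'   per lesion.
#' @return For a vector, a single integer; for a data frame, a tibble
#'   `sample`, `malperfusion_score`.
#' @export
malperfusion_score <- function(lesions) {
  if (is.data.frame(lesions)) {
    lesions <- tibble::as_tibble(lesions)
    if (!"sample" %in% names(lesions)) {
      stop("lesion table needs a 'sample' column", call. = FALSE)
    }
    flags <- as.matrix(lesions[setdiff(names(lesions), "sample")])
    if (!all(flags %in% c(0, 1))) {
      stop("lesion flags must be 0/1", call. = FALSE)
    }
    return(tibble::tibble(
      sample = lesions$sample,
      malperfusion_score = as.integer(rowSums(flags))
    ))
  }
  flags <- as.numeric(lesions)
  if (!all(flags %in% c(0, 1))) stop("lesion flags must be 0/1", call. = FALSE)
  as.integer(sum(flags))
}

#' Per-gene clinical-trait association model
#'
#' Fits, for every gene, a linear model of log2 expression on the clinical
#' traits (default mean arterial pressure and birthweight percentile,
#' treated as continuous) with adjustment covariates (default batch), and
#' evaluates each trait coefficient with a moderated t-test. Q-values are
#' Benjamini-Hochberg adjusted across genes separately per trait;
#' significance uses `q <= q_threshold` (default 0.2).
#'
#' @param study An [expression_study()] whose sample table carries the
#'   traits.
#' @param traits Character vector of continuous trait columns.
#' @param adjust Character vector of adjustment covariates.
#' @param q_threshold Significance cut on the q-value.
#' @return Tibble: `gene`, `trait`, `estimate`, `t`, `p_value`, `q_value`,
#'   `significant`.
#' @export
gene_trait_model <- function(study, traits = c("MAP", "BW_percentile"),
                             adjust = "batch", q_threshold = 0.2) {
  samples <- study$samples
  for (tr in traits) {
    if (!tr %in% names(samples)) {
      stop(sprintf("trait '%s' not in sample table", tr), call. = FALSE)
    }
    if (stats::sd(samples[[tr]]) == 0) {
      stop(sprintf("trait '%s' is constant", tr), call. = FALSE)
    }
  }
  X <- .build_design(samples, stats::reformulate(c(traits, adjust)))
  fit <- limma::eBayes(limma::lmFit(study$exprs, X))
  purrr::map_dfr(traits, function(tr) {
    pp <- fit$p.value[, tr]
    tibble::tibble(
      gene = rownames(study$exprs), trait = tr,
      estimate = unname(fit$coefficients[, tr]),
      t = unname(fit$t[, tr]),
      p_value = unname(pp),
      q_value = bh_adjust(unname(pp))
    )
  }) |>
    dplyr::mutate(significant = .data$q_value <= q_threshold)
}

#' Module enrichment among trait-associated genes
#'
#' For one trait, tests each module for over-representation of genes
#' significantly associated with that trait (Fisher 2x2 of module
#' membership against trait significance over the association background).
#'
#' @param modules A `module_assignment`.
#' @param trait_associations Output of [gene_trait_model()].
#' @param trait Trait name to test.
#' @param alternative Sidedness of the Fisher test.
#' @return Tibble as from [module_enrichment()]. A warning is raised when
#'   no gene is significant for the trait.
#' @export
module_trait_enrichment <- function(modules, trait_associations, trait,
                                    alternative = "two.sided") {
  assoc <- dplyr::filter(trait_associations, .data$trait == !!trait)
  if (nrow(assoc) == 0) stop(sprintf("no associations for trait '%s'", trait),
                             call. = FALSE)
  if (!any(assoc$significant)) {
    warning(sprintf("no significant genes for trait '%s': odds ratios degenerate",
                    trait), call. = FALSE)
  }
  module_enrichment(
    modules,
    tibble::tibble(gene = assoc$gene, property = assoc$significant),
    alternative = alternative
  )
}

#' Gene expression versus histology score
#'
#' Simple per-gene linear regression of qPCR -dCt expression on the
#' maternal vascular malperfusion score, optionally adjusting for
#' gestational age; significance at p < 0.05.
#'
#' @param neg_dct Tibble `sample`, `gene`, `neg_delta_ct`.
#' @param scores Tibble `sample`, `malperfusion_score`; scores must be
#'   available for all samples.
#' @param ga Optional tibble `sample`, `GA_weeks` for gestational-age
#'   adjustment.
#' @param alpha Significance level (default 0.05).
#' @return Tibble: `gene`, `slope`, `p_value`, `significant`.
#' @export
gene_histology_assoc <- function(neg_dct, scores, ga = NULL, alpha = 0.05) {
  d <- dplyr::left_join(tibble::as_tibble(neg_dct),
                        tibble::as_tibble(scores), by = "sample")
  if (any(is.na(d$malperfusion_score))) {
    stop("malperfusion score missing for some samples", call. = FALSE)
  }
  if (stats::sd(d$malperfusion_score) == 0) {
    stop("malperfusion score is constant", call. = FALSE)
  }
  if (!is.null(ga)) d <- dplyr::left_join(d, tibble::as_tibble(ga), by = "sample")
  form <- if (is.null(ga)) {
    neg_delta_ct ~ malperfusion_score
  } else {
    neg_delta_ct ~ malperfusion_score + GA_weeks
  }
  d |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(g, key) {
      fit <- summary(stats::lm(form, data = g))
      tibble::tibble(
        slope = fit$coefficients["malperfusion_score", "Estimate"],
        p_value = fit$coefficients["malperfusion_score", "Pr(>|t|)"]
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p_value < alpha)
}
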