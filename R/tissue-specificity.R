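.atlas_parts <- function(atlas, target_tissue) {
  atlas <- tibble::as_tibble(atlas)
  if (!"gene" %in% names(atlas)) stop("atlas needs a 'gene' column", call. = FALSE)
  if (is.null(target_tissue)) {
    stop("target tissue missing: pass target_tissue= or set the attribute",
         call. = FALSE)
  }
  tissues <- setdiff(names(atlas), "gene")
  if (!target_tissue %in% tissues) {
    stop(sprintf("target tissue '%s' not found in atlas", target_tissue),
         call. = FALSE)
  }
  if (length(tissues) < 2) stop("need at least 2 tissues", call. = FALSE)
  mat <- as.matrix(atlas[tissues])
  rownames(mat) <- atlas$gene
  if (any(mat < 0)) stop("atlas values must be non-negative (linear scale)",
                         call. = FALSE)
  list(mat = mat, target = target_tissue,
       others = setdiff(tissues, target_tissue))
}

#' Call predominantly target-tissue-expressed genes
#'
#' Applies the three-rule atlas test for predominant expression in one
#' tissue: the target-tissue level must (1) reach an absolute floor
#' (default 1,000 linear fluorescence units), (2) be at least `fold_median`
#' times the median level across all other tissues (default 6), and (3) be
#' at least `fold_second` times the highest level among the other tissues
#' (default 2). Ties at a threshold pass (>= semantics).
#'
#' @param atlas Tibble of linear-scale expression: `gene` column plus one
#'   column per tissue (e.g. from [simulate_atlas()]).
#' @param target_tissue Name of the target tissue column; defaults to the
#'   atlas's `target_tissue` attribute.
#' @param min_level Absolute-level floor (rule 1).
#' @param fold_median Fold over the median of other tissues (rule 2).
#' @param fold_second Fold over the highest other tissue (rule 3).
#' @return A tibble with one row per gene: `gene`, `level`,
#'   `median_other`, `max_other`, `fold_over_median`, `fold_over_second`,
#'   and `passes` (all three rules hold).
#' @export
call_predominant <- function(atlas, target_tissue = attr(atlas, "target_tissue"),
                             min_level = 1000, fold_median = 6,
                             fold_second = 2) {
  ap <- .atlas_parts(atlas, target_tissue)
  level <- ap$mat[, ap$target]
  others <- ap$mat[, ap$others, drop = FALSE]
  med <- apply(others, 1, stats::median)
  mx <- apply(others, 1, max)
  tibble::tibble(
    gene = rownames(ap$mat),
    level = unname(level),
    median_other = unname(med),
    max_other = unname(mx),
    fold_over_median = unname(level / med),
    fold_over_second = unname(level / mx),
    passes = unname(level >= min_level &
                      level >= fold_median * med &
                      level >= fold_second * mx)
  )
}

#' Collapse probeset-level specificity calls to genes
#'
#' A gene is called predominant if any of its probesets passes. Probesets
#' absent from the map are excluded with a warning.
#'
#' @param calls Tibble from [call_predominant()] where `gene` holds probeset
#'   ids.
#' @param probe_map Tibble with columns `probeset` and `gene`.
#' @return A tibble with one row per mapped gene: `gene`, `n_probesets`,
#'   `n_passing`, `passes`.
#' @export
collapse_to_genes <- function(calls, probe_map) {
  probe_map <- tibble::as_tibble(probe_map)
  if (!all(c("probeset", "gene") %in% names(probe_map))) {
    stop("probe_map needs columns 'probeset' and 'gene'", call. = FALSE)
  }
  unmapped <- setdiff(calls$gene, probe_map$probeset)
  if (length(unmapped) > 0) {
    warning(sprintf("%d unmapped probeset(s) excluded: %s",
                    length(unmapped),
                    paste(utils::head(unmapped, 5), collapse = ", ")),
            call. = FALSE)
  }
  calls |>
    dplyr::rename(probeset = "gene") |>
    dplyr::inner_join(probe_map, by = "probeset") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_probesets = dplyr::n(),
      n_passing = sum(.data$passes),
      passes = any(.data$passes),
      .groups = "drop"
    )
}

#' Tissue enrichment score for liquid-biopsy marker selection
#'
#' Ratio of target-tissue expression to the mean expression across all other
#' tissues, the score used to rank candidate placenta-derived maternal-blood
#' markers.
#'
#' @inheritParams call_predominant
#' @param genes Optional character vector restricting the output.
#' @return A tibble with columns `gene` and `enrichment_score`. A zero mean
#'   across other tissues yields `Inf` with a warning.
#' @export
enrichment_score <- function(atlas, genes = NULL,
                             target_tissue = attr(atlas, "target_tissue")) {
  ap <- .atlas_parts(atlas, target_tissue)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(ap$mat))
    if (length(missing) > 0) {
      stop(sprintf("gene(s) not in atlas: %s",
                   paste(utils::head(missing, 5), collapse = ", ")),
           call. = FALSE)
    }
    ap$mat <- ap$mat[genes, , drop = FALSE]
  }
  mean_other <- rowMeans(ap$mat[, ap$others, drop = FALSE])
  if (any(mean_other == 0)) {
    warning("zero mean expression in other tissues: score reported as Inf",
            call. = FALSE)
  }
  tibble::tibble(
    gene = rownames(ap$mat),
    enrichment_score = unname(ap$mat[, ap$target] / mean_other)
  )
}
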