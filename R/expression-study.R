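#' Expression study container
#'
#' Bundles a log2 gene-by-sample expression matrix with the per-sample
#' clinical covariates and per-gene annotations the downstream models use.
#'
#' @param exprs Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids), log2 scale.
#' @param samples Data frame with one row per sample; must contain a `sample`
#'   column matching `colnames(exprs)`. Typical covariates: `group`, `batch`,
#'   `maturity`, `MAP` (mmHg), `BW_percentile`, `GA_weeks`.
#' @param genes Optional data frame with one row per gene (`gene` column
#'   matching `rownames(exprs)`); typical annotations: `chromosome`, `is_tf`
#'   (transcription-regulator flag), `is_placenta_predominant`.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(exprs, samples, genes = NULL) {
  exprs <- as.matrix(exprs)
  samples <- tibble::as_tibble(samples)
  if (is.null(rownames(exprs))) stop("exprs must have gene rownames", call. = FALSE)
  if (!"sample" %in% names(samples)) stop("samples needs a 'sample' column", call. = FALSE)
  if (!identical(colnames(exprs), as.character(samples$sample))) {
    stop("colnames(exprs) must equal samples$sample (same order)", call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- tibble::tibble(gene = rownames(exprs))
  } else {
    genes <- tibble::as_tibble(genes)
    if (!"gene" %in% names(genes)) stop("genes needs a 'gene' column", call. = FALSE)
    if (!identical(rownames(exprs), as.character(genes$gene))) {
      stop("rownames(exprs) must equal genes$gene (same order)", call. = FALSE)
    }
  }
  structure(
    list(exprs = exprs, samples = samples, genes = genes),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "expression_study: %d genes x %d samples (log2 scale)\n",
    nrow(x$exprs), ncol(x$exprs)
  ))
  if ("group" %in% names(x$samples)) {
    print(table(x$samples$group))
  }
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$exprs)

#' Long-format view of an expression study
#'
#' @param x An `expression_study`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample`, `log2_expr` joined to the
#'   sample covariates.
#' @export
tidy.expression_study <- function(x, ...) {
  long <- tibble::as_tibble(x$exprs, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "log2_expr")
  dplyr::left_join(long, x$samples, by = "sample")
}

#' @export
glance.expression_study <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$exprs), n_samples = ncol(x$exprs),
    n_groups = if ("group" %in% names(x$samples)) {
      length(unique(x$samples$group))
    } else NA_integer_
  )
}
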