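#' Discretize differential-expression results into UP/DN/NS states
#'
#' A gene is UP when it is significant (`q <= q_threshold` and linear fold
#' change at least `fc_threshold`) with a positive fold change, DN when
#' significant with a negative fold change, and NS (not significant)
#' otherwise.
#'
#' @param de A tibble with columns `gene`, `log2fc`, `q_value` (e.g. a
#'   `de_result`).
#' @param q_threshold,fc_threshold Significance thresholds for the state
#'   call (defaults 0.05 and 1.5).
#' @return Tibble `gene`, `state` with `state` a factor UP/DN/NS.
#' @export
discretize_states <- function(de, q_threshold = 0.05, fc_threshold = 1.5) {
  de <- tibble::as_tibble(de)
  if (!all(c("gene", "log2fc", "q_value") %in% names(de))) {
    stop("need columns gene, log2fc, q_value", call. = FALSE)
  }
  if (any(is.na(de$log2fc)) || any(is.na(de$q_value))) {
    stop("missing DE statistics for some genes", call. = FALSE)
  }
  sig <- de$q_value <= q_threshold & abs(de$log2fc) >= log2(fc_threshold)
  tibble::tibble(
    gene = de$gene,
    state = factor(
      dplyr::case_when(sig & de$log2fc > 0 ~ "UP",
                       sig & de$log2fc < 0 ~ "DN",
                       .default = "NS"),
      levels = c("UP", "DN", "NS")
    )
  )
}

# per-gene concordance score table: +1 perfect match (UP/UP, DN/DN),
# 0 neutral (NS/NS), -1 perfect mismatch (UP/DN, DN/UP), -0.5 otherwise
.match_score_table <- matrix(
  c(1, -1, -0.5,
    -1, 1, -0.5,
    -0.5, -0.5, 0),
  nrow = 3, byrow = TRUE,
  dimnames = list(c("UP", "DN", "NS"), c("UP", "DN", "NS"))
)

#' Concordance match score of two discretized expression patterns
#'
#' Each shared gene contributes +1 for a perfect match (UP/UP or DN/DN),
#' 0 for a neutral NS/NS match, -1 for a perfect mismatch (UP/DN or DN/UP)
#' and -0.5 for all other state pairs; the match score is the sum over
#' genes.
#'
#' @param a,b Tibbles `gene`, `state` over the same gene universe (e.g. from
#'   [discretize_states()]).
#' @return A `match_score_result`: list with `score` and `gene_scores`
#'   (tibble `gene`, `state_a`, `state_b`, `score`).
#' @export
match_score <- function(a, b) {
  a <- tibble::as_tibble(a); b <- tibble::as_tibble(b)
  only_a <- setdiff(a$gene, b$gene); only_b <- setdiff(b$gene, a$gene)
  if (length(only_a) > 0 || length(only_b) > 0) {
    stop(sprintf(
      "patterns cover different genes (only in a: %s; only in b: %s)",
      paste(utils::head(only_a, 5), collapse = ","),
      paste(utils::head(only_b, 5), collapse = ",")
    ), call. = FALSE)
  }
  merged <- dplyr::inner_join(
    dplyr::rename(a, state_a = "state"),
    dplyr::rename(b, state_b = "state"),
    by = "gene"
  )
  merged$score <- .match_score_table[cbind(as.character(merged$state_a),
                                           as.character(merged$state_b))]
  structure(
    list(score = sum(merged$score), gene_scores = merged),
    class = "match_score_result"
  )
}

#' @export
print.match_score_result <- function(x, ...) {
  cat(sprintf("match score = %.1f over %d genes\n",
              x$score, nrow(x$gene_scores)))
  if (!is.null(x$permutation)) {
    cat(sprintf("  permutation p = %.4g (%s null, %d arrangements)\n",
                x$permutation$p_value,
                if (x$permutation$exhaustive) "exhaustive" else "sampled",
                x$permutation$n_permutations))
  }
  invisible(x)
}

#' @export
tidy.match_score_result <- function(x, ...) x$gene_scores

#' @export
glance.match_score_result <- function(x, ...) {
  out <- tibble::tibble(score = x$score, n_genes = nrow(x$gene_scores))
  if (!is.null(x$permutation)) {
    out$p_value <- x$permutation$p_value
    out$n_permutations <- x$permutation$n_permutations
    out$exhaustive <- x$permutation$exhaustive
  }
  out
}

#' Permutation test for in vitro / in vivo pattern concordance
#'
#' Scores the concordance between the differential-expression pattern of an
#' in vitro experiment and a fixed in vivo reference pattern, and assesses
#' its significance by permuting the in vitro class labels. Each
#' permutation re-derives the full chain - two-group moderated-t
#' differential expression, discretization into UP/DN/NS, match score -
#' so the null reflects label exchange, not state shuffling. Permutations
#' are exhaustive when the number of distinct label arrangements is at most
#' `max_exhaustive`, otherwise a random sample of `n_random` arrangements
#' is used. The default alternative is one-sided for high concordance.
#'
#' @param exprs Log2 expression matrix of the in vitro experiment (genes x
#'   samples) or an [expression_study()].
#' @param labels Two-class condition labels for the in vitro samples (at
#'   least 2 per class).
#' @param reference Tibble `gene`, `state`: the in vivo pattern, covering
#'   the same genes.
#' @param q_threshold,fc_threshold Thresholds of the per-permutation
#'   discretization (defaults 0.05 and 1.5).
#' @param max_exhaustive,n_random,seed,tail Passed to
#'   [permutation_pvalue()].
#' @return A `match_score_result` with a `permutation` element
#'   (a `permutation_result`).
#' @export
match_permutation_test <- function(exprs, labels, reference,
                                   q_threshold = 0.05, fc_threshold = 1.5,
                                   max_exhaustive = 20000, n_random = 5000,
                                   seed = NULL, tail = "greater") {
  if (inherits(exprs, "expression_study")) exprs <- exprs$exprs
  exprs <- as.matrix(exprs)
  reference <- tibble::as_tibble(reference)
  if (!setequal(rownames(exprs), reference$gene)) {
    stop("reference pattern must cover exactly the expression genes",
         call. = FALSE)
  }
  tab <- table(labels)
  if (length(tab) != 2 || any(tab < 2)) {
    stop("need two in vitro classes with at least 2 samples each", call. = FALSE)
  }
  if (choose(length(labels), tab[[1]]) < 2) {
    stop("degenerate design: only one label arrangement", call. = FALSE)
  }
  ref_states <- stats::setNames(as.character(reference$state), reference$gene)
  gene_order <- rownames(exprs)
  stat <- function(values, labs) {
    de <- .fast_de_two_group(values, labs, q_threshold = q_threshold,
                             fc_threshold = fc_threshold)
    st <- discretize_states(de, q_threshold = q_threshold,
                            fc_threshold = fc_threshold)
    sum(.match_score_table[cbind(as.character(st$state),
                                 ref_states[st$gene])])
  }
  perm <- permutation_pvalue(exprs, labels, stat,
                             max_exhaustive = max_exhaustive,
                             n_random = n_random, seed = seed, tail = tail)
  de_obs <- .fast_de_two_group(exprs, labels, q_threshold = q_threshold,
                               fc_threshold = fc_threshold)
  obs <- match_score(
    discretize_states(de_obs, q_threshold, fc_threshold),
    tibble::tibble(gene = gene_order,
                   state = factor(ref_states[gene_order],
                                  levels = c("UP", "DN", "NS")))
  )
  obs$permutation <- perm
  obs
}
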