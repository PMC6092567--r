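#' Build a weighted co-expression network
#'
#' Computes the gene pairwise similarity matrix (absolute Pearson
#' correlation), soft-thresholds it by raising to the power `beta`
#' (default 10, chosen for approximate scale-free topology) to obtain the
#' adjacency, and derives the topological overlap matrix
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'                      {\min(k_i, k_j) + 1 - a_{ij}}}
#' with unit diagonal, where \eqn{k_i = \sum_{j \ne i} a_{ij}} is the
#' connectivity. `1 - TOM` is the clustering distance used by
#' [detect_modules()].
#'
#' @param x An [expression_study()] or a numeric genes-x-samples matrix.
#' @param genes Optional character vector restricting the network to a gene
#'   subset (typically the differentially expressed genes).
#' @param beta Soft-thresholding power (default 10).
#' @return A `coexpression_network`: list with `similarity`, `adjacency`,
#'   `connectivity`, `tom` and `beta`. Constant genes get zero similarity
#'   with a warning.
#' @export
build_network <- function(x, genes = NULL, beta = 10) {
  exprs <- if (inherits(x, "expression_study")) x$exprs else as.matrix(x)
  if (!is.null(genes)) exprs <- exprs[genes, , drop = FALSE]
  if (nrow(exprs) < 2) stop("need at least 2 genes", call. = FALSE)
  if (ncol(exprs) < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(exprs, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("%d constant gene(s): correlations set to 0", sum(sds == 0)),
            call. = FALSE)
  }
  s <- abs(suppressWarnings(stats::cor(t(exprs))))
  s[is.na(s)] <- 0
  diag(s) <- 1
  a <- s^beta
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a # diag(a) = 0, so entry ij sums over u != i, j only via u terms
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (shared + a) / denom
  diag(tom) <- 1
  diag(a) <- 1
  structure(
    list(similarity = s, adjacency = a, connectivity = k, tom = tom,
         beta = beta),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "coexpression_network: %d genes, beta = %g, mean connectivity = %.2f\n",
    nrow(x$tom), x$beta, mean(x$connectivity)
  ))
  invisible(x)
}

#' @export
glance.coexpression_network <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$tom), beta = x$beta,
    mean_connectivity = mean(x$connectivity),
    mean_tom = mean(x$tom[upper.tri(x$tom)])
  )
}

#' Edge-list view of a network
#'
#' @param x A `coexpression_network`.
#' @param ... Unused.
#' @return Tibble of upper-triangle pairs: `gene_a`, `gene_b`,
#'   `similarity`, `adjacency`, `tom`.
#' @export
tidy.coexpression_network <- function(x, ...) {
  ut <- upper.tri(x$tom)
  idx <- which(ut, arr.ind = TRUE)
  g <- rownames(x$tom)
  tibble::tibble(
    gene_a = g[idx[, 1]], gene_b = g[idx[, 2]],
    similarity = x$similarity[ut], adjacency = x$adjacency[ut],
    tom = x$tom[ut]
  )
}

#' Scale-free topology fit index of the degree distribution
#'
#' Slope-sign-corrected R-squared of the log-log regression of the binned
#' connectivity distribution (`-sign(slope) * R^2`), the standard index for
#' choosing the soft-thresholding power: a network with approximate
#' scale-free topology has many low-connectivity and few high-connectivity
#' genes, giving a good fit with a negative slope and hence an index near 1,
#' while an unthresholded network typically scores lower or negative.
#'
#' @param network A `coexpression_network`.
#' @param n_bins Number of equal-width connectivity bins (default 10).
#' @return Fit index in `[-1, 1]`.
#' @export
scale_free_fit <- function(network, n_bins = 10) {
  k <- network$connectivity
  if (diff(range(k)) < 1e-12) return(0)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- as.numeric(table(bin)) / length(k)
  keep <- !is.na(dk) & dk > 0 & pk > 0
  if (sum(keep) < 3) return(0)
  fit <- suppressWarnings(stats::lm(log10(pk[keep]) ~ log10(dk[keep])))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  -sign(stats::coef(fit)[[2]]) * r2
}

# cut height fraction of the maximum merge height per deep-split level;
# deeper splits cut lower, producing finer (and more) candidate branches
.deep_split_frac <- c(`0` = 0.95, `1` = 0.975, `2` = 0.99, `3` = 0.995)

# branch-tightness acceptance per deep-split level: a candidate branch is a
# module only when its mean intra-branch distance is below this fraction of
# its mean distance to genes outside the branch; deeper splits are more
# permissive
.deep_split_tightness <- c(`0` = 0.80, `1` = 0.85, `2` = 0.90, `3` = 0.95)

#' Detect co-expression modules by dynamic tree cutting
#'
#' Average-linkage hierarchical clustering on the `1 - TOM` distance,
#' followed by a dynamic hybrid-style cut: the dendrogram is cut at a
#' `deep_split`-dependent fraction of its maximum merge height; branches
#' smaller than `min_module_size`, or whose mean intra-branch distance is
#' not clearly below their mean distance to the rest of the network
#' (a `deep_split`-dependent tightness gate that leaves unstructured noise
#' unassigned), are dropped; and (optionally) a
#' PAM-like stage assigns each unassigned gene to the nearest module when
#' its average distance to that module's genes is within the module's own
#' median intra-module distance. Modules are labelled `M1, M2, ...` in
#' decreasing size order; the reserved label for unassigned genes is
#' `"unassigned"`.
#'
#' @param network A `coexpression_network` from [build_network()].
#' @param min_module_size Smallest branch kept as a module (default 30).
#' @param deep_split Integer 0-3 controlling cut depth (default 2).
#' @param pam Reassign unassigned genes to nearby modules (default `TRUE`).
#' @return A `module_assignment`: tibble `gene`, `module` with attributes
#'   `dendrogram` (the hclust object) and `params`.
#' @export
detect_modules <- function(network, min_module_size = 30, deep_split = 2,
                           pam = TRUE) {
  if (!deep_split %in% 0:3) stop("deep_split must be 0, 1, 2 or 3", call. = FALSE)
  d <- 1 - network$tom
  genes <- rownames(network$tom)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  heights <- hc$height
  if (max(heights) - min(heights) < 1e-12) {
    warning("all distances equal: single module returned", call. = FALSE)
    labels <- rep("M1", length(genes))
    return(.new_module_assignment(genes, labels, hc, min_module_size, deep_split))
  }
  cut_h <- .deep_split_frac[[as.character(deep_split)]] * max(heights)
  cl <- stats::cutree(hc, h = cut_h)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  # tightness gate: drop branches indistinguishable from the background
  tight <- .deep_split_tightness[[as.character(deep_split)]]
  keep <- Filter(function(ci) {
    idx <- which(cl == ci)
    if (length(idx) == length(genes)) return(FALSE) # no outside reference
    intra <- mean(d[idx, idx][upper.tri(diag(length(idx)))])
    inter <- mean(d[idx, -idx])
    intra <= tight * inter
  }, keep)
  labels <- rep("unassigned", length(genes))
  for (ci in keep) labels[cl == ci] <- paste0("branch", ci)

  if (pam && length(keep) > 0 && any(labels == "unassigned")) {
    mods <- unique(labels[labels != "unassigned"])
    radius <- vapply(mods, function(m) {
      dm <- d[labels == m, labels == m, drop = FALSE]
      stats::median(dm[upper.tri(dm)])
    }, numeric(1))
    for (i in which(labels == "unassigned")) {
      avg_d <- vapply(mods, function(m) mean(d[i, labels == m]), numeric(1))
      best <- which.min(avg_d)
      if (avg_d[best] <= radius[best]) labels[i] <- mods[best]
    }
  }
  .new_module_assignment(genes, labels, hc, min_module_size, deep_split)
}

# relabel modules M1, M2, ... by decreasing size (ties broken by the
# smallest member gene id, so labelling is order-stable)
.new_module_assignment <- function(genes, labels, hc, min_module_size,
                                   deep_split) {
  mods <- setdiff(unique(labels), "unassigned")
  if (length(mods) > 0) {
    size <- vapply(mods, function(m) sum(labels == m), integer(1))
    first_gene <- vapply(mods, function(m) min(genes[labels == m]), character(1))
    ord <- order(-size, first_gene)
    relabel <- stats::setNames(paste0("M", seq_along(mods)), mods[ord])
    labels[labels != "unassigned"] <- relabel[labels[labels != "unassigned"]]
  }
  res <- tibble::tibble(gene = genes, module = labels)
  structure(res,
    class = c("module_assignment", class(res)),
    dendrogram = hc,
    params = list(min_module_size = min_module_size, deep_split = deep_split)
  )
}

#' @export
glance.module_assignment <- function(x, ...) {
  tab <- table(x$module[x$module != "unassigned"])
  tibble::tibble(
    n_genes = nrow(x), n_modules = length(tab),
    n_unassigned = sum(x$module == "unassigned"),
    largest_module = if (length(tab)) max(tab) else 0L
  )
}

#' Hub transcription-regulator candidates
#'
#' Within each module, candidate hub genes are transcription regulators
#' expressed at high levels (mean log2 intensity above `intensity_min`,
#' default 9) ranked by the number of co-expression partners with absolute
#' Pearson correlation above `cor_min` (default 0.7) in the partner set.
#' Ties are broken by the summed absolute correlation over qualifying
#' partners, then by gene id.
#'
#' @param study An [expression_study()]; `study$genes` must carry the
#'   transcription-regulator flag.
#' @param modules A `module_assignment` from [detect_modules()].
#' @param intensity_min Mean log2-intensity floor (strict, default 9).
#' @param cor_min Absolute-correlation floor for counting a partner
#'   (strict, default 0.7).
#' @param restrict_to Name of the logical gene-annotation column flagging
#'   eligible candidate genes (default `"is_tf"`).
#' @param partner_set Character vector of genes among which partners are
#'   counted; default all genes in `modules`.
#' @return A tibble: `gene`, `module`, `mean_intensity`, `n_partners`,
#'   `sum_abs_r`, `rank` (within module).
#' @export
hub_candidates <- function(study, modules, intensity_min = 9, cor_min = 0.7,
                           restrict_to = "is_tf", partner_set = NULL) {
  if (is.null(partner_set)) partner_set <- modules$gene
  partner_set <- intersect(partner_set, rownames(study$exprs))
  if (length(partner_set) == 0) stop("empty partner set", call. = FALSE)
  if (!restrict_to %in% names(study$genes)) {
    stop(sprintf("gene annotation '%s' not found", restrict_to), call. = FALSE)
  }
  flagged <- study$genes$gene[isTRUE_vec(study$genes[[restrict_to]])]
  assigned <- modules[modules$module != "unassigned", ]
  cand <- intersect(intersect(flagged, assigned$gene), rownames(study$exprs))
  mean_int <- rowMeans(study$exprs[cand, , drop = FALSE])
  cand <- cand[mean_int[cand] > intensity_min]
  if (length(cand) == 0) {
    return(tibble::tibble(
      gene = character(), module = character(), mean_intensity = numeric(),
      n_partners = integer(), sum_abs_r = numeric(), rank = integer()
    ))
  }
  r <- abs(suppressWarnings(stats::cor(
    t(study$exprs[cand, , drop = FALSE]),
    t(study$exprs[partner_set, , drop = FALSE])
  )))
  r[is.na(r)] <- 0
  # a gene is not its own partner
  for (g in intersect(cand, partner_set)) r[g, g] <- 0
  qual <- r > cor_min
  res <- tibble::tibble(
    gene = cand,
    mean_intensity = unname(rowMeans(study$exprs[cand, , drop = FALSE])),
    n_partners = unname(rowSums(qual)),
    sum_abs_r = unname(rowSums(r * qual))
  ) |>
    dplyr::left_join(assigned, by = "gene") |>
    dplyr::arrange(.data$module, dplyr::desc(.data$n_partners),
                   dplyr::desc(.data$sum_abs_r), .data$gene) |>
    dplyr::group_by(.data$module) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "module", "mean_intensity", "n_partners",
                  "sum_abs_r", "rank")
  res
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Module enrichment for a binary gene property
#'
#' One Fisher 2x2 test per module: module membership against the property,
#' over the chosen background gene universe. Benjamini-Hochberg q-values
#' are added across modules when more than one is tested.
#'
#' @param modules A `module_assignment` (or tibble `gene`, `module`).
#' @param gene_property Tibble with columns `gene` and `property` (logical),
#'   covering the background universe.
#' @param background Character vector of background genes; default all
#'   genes in `gene_property`.
#' @param alternative Sidedness passed to [fisher_exact_2x2()].
#' @return Tibble: `module`, `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`,
#'   `q_value`. Empty modules are skipped with a warning.
#' @export
module_enrichment <- function(modules, gene_property, background = NULL,
                              alternative = "two.sided") {
  gene_property <- tibble::as_tibble(gene_property)
  if (!all(c("gene", "property") %in% names(gene_property))) {
    stop("gene_property needs columns 'gene' and 'property'", call. = FALSE)
  }
  if (is.null(background)) background <- gene_property$gene
  prop <- stats::setNames(gene_property$property, gene_property$gene)
  if (!all(background %in% names(prop))) {
    stop("property undefined for part of the background", call. = FALSE)
  }
  mods <- setdiff(unique(modules$module), "unassigned")
  rows <- purrr::map_dfr(mods, function(m) {
    members <- intersect(modules$gene[modules$module == m], background)
    if (length(members) == 0) {
      warning(sprintf("module %s has no genes in the background: skipped", m),
              call. = FALSE)
      return(NULL)
    }
    outside <- setdiff(background, members)
    a <- sum(prop[members]); b <- length(members) - a
    cc <- sum(prop[outside]); dd <- length(outside) - cc
    ft <- fisher_exact_2x2(a, b, cc, dd, alternative = alternative)
    tibble::tibble(
      module = m, a = a, b = b, c = cc, d = dd,
      odds_ratio = ft$odds_ratio, p_value = ft$p_value
    )
  })
  if (nrow(rows) > 1) rows$q_value <- bh_adjust(rows$p_value)
  else if (nrow(rows) == 1) rows$q_value <- rows$p_value
  rows
}
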