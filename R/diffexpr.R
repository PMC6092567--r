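#' Preprocess and filter an expression matrix
#'
#' Log2-transforms (if the input is linear), quantile-normalizes samples,
#' and removes genes that never reach the intensity floor: a gene is kept
#' only if its normalized log2 intensity exceeds `intensity_floor` (default
#' log2(50)) in at least `min_samples` samples (default 2).
#'
#' @param raw Numeric matrix, genes x samples, with rownames and colnames.
#' @param samples Data frame of per-sample covariates with a `sample`
#'   column matching `colnames(raw)`.
#' @param genes Optional per-gene annotation table (`gene` column).
#' @param log2_input Set `TRUE` when `raw` is already on the log2 scale.
#' @param intensity_floor Log2 intensity a gene must exceed (strictly).
#' @param min_samples Minimum number of samples exceeding the floor.
#' @return An [expression_study()] of the retained genes, with attribute
#'   `n_retained` and `n_input`.
#' @export
preprocess_filter <- function(raw, samples, genes = NULL, log2_input = FALSE,
                              intensity_floor = log2(50), min_samples = 2) {
  raw <- as.matrix(raw)
  if (ncol(raw) < 2) stop("need at least 2 samples", call. = FALSE)
  if (!log2_input) {
    if (any(raw < 0)) stop("linear-scale input must be non-negative", call. = FALSE)
    raw <- log2(raw + 1)
  }
  norm <- limma::normalizeQuantiles(raw)
  dimnames(norm) <- dimnames(raw)
  keep <- rowSums(norm > intensity_floor) >= min_samples
  norm <- norm[keep, , drop = FALSE]
  if (!is.null(genes)) {
    genes <- tibble::as_tibble(genes)
    genes <- genes[match(rownames(norm), genes$gene), , drop = FALSE]
  }
  study <- expression_study(norm, samples, genes)
  attr(study, "n_input") <- length(keep)
  attr(study, "n_retained") <- sum(keep)
  study
}

# design matrix from a formula over the sample table, with single-level
# factors dropped and an informative error on rank deficiency
.build_design <- function(samples, design) {
  vars <- all.vars(design)
  missing <- setdiff(vars, names(samples))
  if (length(missing) > 0) {
    stop(sprintf("covariate(s) not in sample table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df <- as.data.frame(samples[vars])
  for (v in vars) {
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
    if (is.factor(df[[v]]) && nlevels(droplevels(df[[v]])) < 2) {
      message(sprintf("dropping single-level covariate '%s' from the design", v))
      vars <- setdiff(vars, v)
    }
  }
  design <- stats::reformulate(if (length(vars)) vars else "1")
  X <- stats::model.matrix(design, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  X
}

# put the reference level first: "control" if present, else alphabetical
.group_factor <- function(g) {
  g <- as.factor(g)
  if ("control" %in% levels(g)) stats::relevel(g, ref = "control") else g
}

#' Moderated-t differential expression
#'
#' Fits a per-gene linear model over the design (default group plus batch
#' adjustment), evaluates the group coefficient with an empirical-Bayes
#' moderated t-test (residual variances shrunk toward a pooled prior
#' estimated from all genes), adjusts p-values by Benjamini-Hochberg, and
#' calls a gene differentially expressed when `q <= q_threshold` and the
#' linear-scale fold change is at least `fc_threshold` (i.e.
#' `|log2fc| >= log2(fc_threshold)`). Defaults are q <= 0.2 and fold change
#' >= 1.5. Positive `log2fc` means higher in cases ("control" is used as the
#' reference level when present).
#'
#' @param study An [expression_study()].
#' @param design Model formula over sample covariates (default
#'   `~ group + batch`).
#' @param group_var Name of the grouping covariate whose coefficient is
#'   tested (default `"group"`).
#' @param q_threshold,fc_threshold DE calling thresholds.
#' @param shrink Use empirical-Bayes variance shrinkage (`TRUE`, default);
#'   with `FALSE` the ordinary least-squares t is reported.
#' @return A tibble of class `de_result` with columns `gene`, `log2fc`,
#'   `t`, `p_value`, `q_value`, `de`, `direction`.
#' @export
de_linear_model <- function(study, design = ~ group + batch,
                            group_var = "group",
                            q_threshold = 0.2, fc_threshold = 1.5,
                            shrink = TRUE) {
  samples <- study$samples
  if (!group_var %in% names(samples)) {
    stop(sprintf("grouping covariate '%s' not in sample table", group_var),
         call. = FALSE)
  }
  samples[[group_var]] <- .group_factor(samples[[group_var]])
  X <- .build_design(samples, design)
  coef_name <- grep(paste0("^", group_var), colnames(X), value = TRUE)
  if (length(coef_name) != 1) {
    stop(sprintf("expected exactly one coefficient for '%s'", group_var),
         call. = FALSE)
  }
  fit <- limma::lmFit(study$exprs, X)
  if (shrink) {
    fit <- limma::eBayes(fit)
    tt <- fit$t[, coef_name]
    pp <- fit$p.value[, coef_name]
  } else {
    tt <- fit$coefficients[, coef_name] /
      (fit$stdev.unscaled[, coef_name] * fit$sigma)
    pp <- 2 * stats::pt(-abs(tt), df = fit$df.residual)
  }
  lfc <- fit$coefficients[, coef_name]
  qq <- bh_adjust(pp)
  de <- qq <= q_threshold & abs(lfc) >= log2(fc_threshold)
  res <- tibble::tibble(
    gene = rownames(study$exprs),
    log2fc = unname(lfc), t = unname(tt),
    p_value = unname(pp), q_value = unname(qq),
    de = unname(de),
    direction = dplyr::case_when(
      de & lfc > 0 ~ "up", de & lfc < 0 ~ "down", .default = "none"
    )
  )
  structure(res,
    class = c("de_result", class(res)),
    coef = coef_name, q_threshold = q_threshold, fc_threshold = fc_threshold
  )
}

#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x), n_de = sum(x$de),
    n_up = sum(x$direction == "up"), n_down = sum(x$direction == "down"),
    q_threshold = attr(x, "q_threshold"), fc_threshold = attr(x, "fc_threshold")
  )
}

# fast vectorised two-group moderated t on a matrix; same calling
# conventions and thresholds as de_linear_model with design ~ group.
# Used inside permutation loops where thousands of refits are needed.
.fast_de_two_group <- function(exprs, labels, q_threshold = 0.05,
                               fc_threshold = 1.5, shrink = TRUE) {
  g <- .group_factor(labels)
  lev <- levels(droplevels(g))
  stopifnot(length(lev) == 2)
  i1 <- which(g == lev[1]); i2 <- which(g == lev[2])
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(exprs[, i1, drop = FALSE])
  m2 <- rowMeans(exprs[, i2, drop = FALSE])
  lfc <- m2 - m1 # non-reference minus reference, as in de_linear_model
  rss <- rowSums((exprs[, i1, drop = FALSE] - m1)^2) +
    rowSums((exprs[, i2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  s2 <- rss / df
  se_unscaled <- sqrt(1 / n1 + 1 / n2)
  if (shrink) {
    sq <- limma::squeezeVar(s2, df = df)
    tt <- lfc / (sqrt(sq$var.post) * se_unscaled)
    df_t <- df + sq$df.prior
  } else {
    tt <- lfc / (sqrt(s2) * se_unscaled)
    df_t <- df
  }
  pp <- 2 * stats::pt(-abs(tt), df = df_t)
  qq <- stats::p.adjust(pp, method = "BH")
  de <- qq <= q_threshold & abs(lfc) >= log2(fc_threshold)
  tibble::tibble(
    gene = rownames(exprs), log2fc = unname(lfc), t = unname(tt),
    p_value = unname(pp), q_value = unname(qq), de = unname(de),
    direction = dplyr::case_when(
      de & lfc > 0 ~ "up", de & lfc < 0 ~ "down", .default = "none"
    )
  )
}

#' Reference-normalized qPCR expression (-dCt)
#'
#' Converts cycle-threshold values to log2-scale relative expression,
#' `-dCt(gene) = Ct(reference) - Ct(gene)`, and optionally removes
#' between-batch offsets using calibrator samples measured in every batch:
#' after calibration a calibrator has the same -dCt in all batches.
#'
#' @param ct Long tibble with columns `sample`, `gene`, `ct` and, when
#'   calibrating, `batch`.
#' @param reference_gene Reference gene id (default `"RPLP0"`).
#' @param calibrators Character vector of calibrator sample ids measured in
#'   each batch; `NULL` skips batch calibration.
#' @return A tibble `sample[, batch], gene, neg_delta_ct` (reference gene
#'   rows excluded). Samples lacking the reference gene are dropped with a
#'   warning.
#' @export
qpcr_delta_ct <- function(ct, reference_gene = "RPLP0", calibrators = NULL) {
  ct <- tibble::as_tibble(ct)
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(ct))) {
    stop("ct table needs columns sample, gene, ct", call. = FALSE)
  }
  has_batch <- "batch" %in% names(ct)
  keys <- if (has_batch) c("sample", "batch") else "sample"
  ref <- ct |>
    dplyr::filter(.data$gene == reference_gene) |>
    dplyr::select(dplyr::all_of(keys), ref_ct = "ct")
  if (nrow(ref) == 0) {
    stop(sprintf("reference gene '%s' absent from table", reference_gene),
         call. = FALSE)
  }
  out <- ct |>
    dplyr::filter(.data$gene != reference_gene) |>
    dplyr::left_join(ref, by = keys)
  n_drop <- length(unique(out$sample[is.na(out$ref_ct)]))
  if (n_drop > 0) {
    warning(sprintf("%d sample(s) dropped: reference gene not measured", n_drop),
            call. = FALSE)
    out <- dplyr::filter(out, !is.na(.data$ref_ct))
  }
  out <- out |>
    dplyr::mutate(neg_delta_ct = .data$ref_ct - .data$ct) |>
    dplyr::select(dplyr::all_of(keys), "gene", "neg_delta_ct")

  if (!is.null(calibrators)) {
    if (!has_batch) stop("batch column required for calibration", call. = FALSE)
    cal <- dplyr::filter(out, .data$sample %in% calibrators)
    if (nrow(cal) == 0) stop("no calibrator measurements found", call. = FALSE)
    offsets <- cal |>
      dplyr::group_by(.data$gene) |>
      dplyr::mutate(overall = mean(.data$neg_delta_ct)) |>
      dplyr::group_by(.data$gene, .data$batch) |>
      dplyr::summarise(
        offset = mean(.data$neg_delta_ct) - .data$overall[1], .groups = "drop"
      )
    out <- out |>
      dplyr::left_join(offsets, by = c("gene", "batch")) |>
      dplyr::mutate(
        neg_delta_ct = .data$neg_delta_ct -
          dplyr::coalesce(.data$offset, 0)
      ) |>
      dplyr::select(-"offset")
  }
  out
}

#' Per-gene qPCR group model with maturity interaction
#'
#' For each gene, fits a linear model of -dCt on the clinical group and the
#' maturity status of the fetus (term vs preterm) with their interaction,
#' and reports the group effect within each maturity stratum together with
#' the interaction term.
#'
#' @param neg_dct Tibble with columns `sample`, `gene`, `neg_delta_ct`, and
#'   either `group`/`maturity` columns or joinable via `sample_info`.
#' @param sample_info Optional tibble (`sample`, `group`, `maturity`) to
#'   join onto `neg_dct`.
#' @return A tidy tibble: `gene`, `term` (one of `group@<stratum>` per
#'   maturity level and `interaction`), `estimate`, `p_value`.
#' @export
qpcr_group_model <- function(neg_dct, sample_info = NULL) {
  d <- tibble::as_tibble(neg_dct)
  if (!is.null(sample_info)) {
    d <- dplyr::left_join(d, tibble::as_tibble(sample_info), by = "sample")
  }
  need <- c("gene", "neg_delta_ct", "group", "maturity")
  if (!all(need %in% names(d))) {
    stop("need columns gene, neg_delta_ct, group, maturity", call. = FALSE)
  }
  d$group <- .group_factor(d$group)
  d$maturity <- factor(d$maturity)
  if (nlevels(droplevels(d$group)) < 2 || nlevels(droplevels(d$maturity)) < 2) {
    stop("group and maturity each need at least 2 levels", call. = FALSE)
  }
  if (any(table(d$group, d$maturity) == 0)) {
    stop("empty group-by-maturity stratum", call. = FALSE)
  }
  strata <- levels(d$maturity)
  grp_coef <- paste0("group", levels(d$group)[2])
  d |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(g, key) {
      rows <- purrr::map_dfr(strata, function(s) {
        gs <- g
        gs$maturity <- stats::relevel(gs$maturity, ref = s)
        fit <- summary(stats::lm(neg_delta_ct ~ group * maturity, data = gs))
        tibble::tibble(
          term = paste0("group@", s),
          estimate = fit$coefficients[grp_coef, "Estimate"],
          p_value = fit$coefficients[grp_coef, "Pr(>|t|)"]
        )
      })
      fit <- summary(stats::lm(neg_delta_ct ~ group * maturity, data = g))
      inter <- grep(":", rownames(fit$coefficients), value = TRUE)
      dplyr::bind_rows(rows, tibble::tibble(
        term = "interaction",
        estimate = fit$coefficients[inter[1], "Estimate"],
        p_value = fit$coefficients[inter[1], "Pr(>|t|)"]
      ))
    }) |>
    dplyr::ungroup()
}
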