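.known_config_keys <- list(
  top = c("seed", "output_dir", "stages", "simulate", "de", "modules", "hubs",
          "enrichment", "clinical", "biopsy", "methylation"),
  stages = c("simulate", "de", "modules", "hubs", "enrichment", "clinical",
             "biopsy", "methylation"),
  simulate = c("study", "atlas", "biomarker", "methylation"),
  de = c("q_threshold", "fc_threshold"),
  modules = c("beta", "min_module_size", "deep_split", "pam"),
  hubs = c("intensity_min", "cor_min"),
  enrichment = c("alternative"),
  clinical = c("traits", "adjust", "q_threshold"),
  biopsy = c("cutoff_week"),
  methylation = c("min_coverage", "min_group_n")
)

.validate_config <- function(config) {
  bad <- setdiff(names(config), .known_config_keys$top)
  if (length(bad) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  for (sect in intersect(names(config), names(.known_config_keys))) {
    if (sect == "top") next
    bad <- setdiff(names(config[[sect]]), .known_config_keys[[sect]])
    if (length(bad) > 0) {
      stop(sprintf("unknown config key(s) in '%s': %s",
                   sect, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(config)
}

.stage_on <- function(config, stage) {
  isTRUE(config$stages[[stage]] %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_stage <- function(x, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the pipeline stages in dependency order - simulate,
#' differential expression, co-expression modules, hub candidates,
#' placenta-predominance enrichment, clinical-trait association, virtual
#' liquid biopsy, methylation comparison - writing one TSV per stage plus
#' a JSON report recording the seed and every stage parameter. With a fixed
#' seed the run is fully deterministic: running twice produces identical
#' outputs.
#'
#' @param config Either a list or the path of a YAML file. Recognised
#'   top-level keys: `seed`, `output_dir`, `stages` (logical toggles per
#'   stage), and per-stage parameter sections `simulate` (sub-sections
#'   `study`, `atlas`, `biomarker`, `methylation` passed to the
#'   corresponding `simulate_*()` generator), `de`, `modules`, `hubs`,
#'   `enrichment`, `clinical`, `biopsy`, `methylation`. Unknown keys are
#'   rejected before execution.
#' @return Invisibly, a list with the per-stage results and the report.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validate_config(config)
  seed <- config$seed %||% 1L
  out_dir <- config$output_dir %||% "pipeline_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  results <- list()
  files <- list()
  report <- list(seed = seed, parameters = config[setdiff(names(config),
                                                          c("output_dir"))])

  if (!.stage_on(config, "simulate")) {
    stop("stage 'simulate' is required: downstream stages need its outputs",
         call. = FALSE)
  }
  sim <- config$simulate %||% list()
  study <- do.call(simulate_study, sim$study %||% list())
  atlas <- do.call(simulate_atlas, sim$atlas %||% list())
  biomarkers <- do.call(simulate_biomarker_db, sim$biomarker %||% list())
  meth_counts <- do.call(simulate_methylation_counts, sim$methylation %||% list())
  results$study <- study
  files$expression <- .write_stage(
    tibble::as_tibble(study$exprs, rownames = "gene"), out_dir, "expression"
  )
  files$samples <- .write_stage(study$samples, out_dir, "samples")
  files$atlas <- .write_stage(atlas, out_dir, "atlas")
  files$biomarkers <- .write_stage(biomarkers, out_dir, "biomarkers")
  files$methylation_counts <- .write_stage(meth_counts, out_dir,
                                           "methylation_counts")

  if (.stage_on(config, "de")) {
    de_par <- config$de %||% list()
    de <- de_linear_model(
      study,
      q_threshold = de_par$q_threshold %||% 0.2,
      fc_threshold = de_par$fc_threshold %||% 1.5
    )
    results$de <- de
    files$de <- .write_stage(de, out_dir, "de_results")
  }

  if (.stage_on(config, "modules")) {
    if (is.null(results$de)) {
      stop("stage 'modules' needs the output of stage 'de'", call. = FALSE)
    }
    mod_par <- config$modules %||% list()
    de_genes <- results$de$gene[results$de$de]
    if (length(de_genes) < 2) {
      stop("stage 'modules': fewer than 2 DE genes", call. = FALSE)
    }
    net <- build_network(study, genes = de_genes,
                         beta = mod_par$beta %||% 10)
    mods <- detect_modules(
      net,
      min_module_size = mod_par$min_module_size %||% 30,
      deep_split = mod_par$deep_split %||% 2,
      pam = mod_par$pam %||% TRUE
    )
    results$network <- net
    results$modules <- mods
    files$modules <- .write_stage(mods, out_dir, "modules")
  }

  if (.stage_on(config, "hubs")) {
    if (is.null(results$modules)) {
      stop("stage 'hubs' needs the output of stage 'modules'", call. = FALSE)
    }
    hub_par <- config$hubs %||% list()
    hubs <- hub_candidates(
      study, results$modules,
      intensity_min = hub_par$intensity_min %||% 9,
      cor_min = hub_par$cor_min %||% 0.7
    )
    results$hubs <- hubs
    files$hubs <- .write_stage(hubs, out_dir, "hub_candidates")
  }

  if (.stage_on(config, "enrichment")) {
    if (is.null(results$de)) {
      stop("stage 'enrichment' needs the output of stage 'de'", call. = FALSE)
    }
    calls <- call_predominant(atlas)
    # enrichment of target-tissue-predominant genes among DE genes uses the
    # study's own annotation flag over the study gene universe
    ann <- study$genes
    a <- sum(ann$is_placenta_predominant & results$de$de)
    b <- sum(ann$is_placenta_predominant & !results$de$de)
    cc <- sum(!ann$is_placenta_predominant & results$de$de)
    dd <- sum(!ann$is_placenta_predominant & !results$de$de)
    enr <- fisher_exact_2x2(a, b, cc, dd,
                            alternative = (config$enrichment %||%
                                             list())$alternative %||% "two.sided")
    results$predominant_calls <- calls
    results$enrichment <- enr
    files$predominant_calls <- .write_stage(calls, out_dir, "predominant_calls")
    files$enrichment <- .write_stage(enr, out_dir, "enrichment")
  }

  if (.stage_on(config, "clinical")) {
    cl_par <- config$clinical %||% list()
    assoc <- gene_trait_model(
      study,
      traits = cl_par$traits %||% c("MAP", "BW_percentile"),
      adjust = cl_par$adjust %||% "batch",
      q_threshold = cl_par$q_threshold %||% 0.2
    )
    results$trait_associations <- assoc
    files$trait_associations <- .write_stage(assoc, out_dir,
                                             "trait_associations")
    if (!is.null(results$modules)) {
      mte <- purrr::map_dfr(
        cl_par$traits %||% c("MAP", "BW_percentile"),
        function(tr) {
          dplyr::mutate(
            suppressWarnings(
              module_trait_enrichment(results$modules, assoc, tr)
            ),
            trait = tr, .before = 1
          )
        }
      )
      results$module_trait_enrichment <- mte
      files$module_trait_enrichment <- .write_stage(mte, out_dir,
                                                    "module_trait_enrichment")
    }
  }

  if (.stage_on(config, "biopsy")) {
    bio_par <- config$biopsy %||% list()
    trend <- ga_trend(biomarkers, cutoff_week = bio_par$cutoff_week %||% 12)
    tri <- trimester_summary(biomarkers,
                             cutoff_week = bio_par$cutoff_week %||% 12)
    results$ga_trend <- trend
    results$trimester_summary <- tri
    files$ga_trend <- .write_stage(trend, out_dir, "ga_trend")
    files$trimester_summary <- .write_stage(tri, out_dir, "trimester_summary")
  }

  if (.stage_on(config, "methylation")) {
    me_par <- config$methylation %||% list()
    dm <- compare_groups(
      meth_counts,
      min_coverage = me_par$min_coverage %||% 4,
      min_group_n = me_par$min_group_n %||% 2
    )
    results$methylation <- dm
    files$methylation <- .write_stage(dm, out_dir, "methylation_dm")
  }

  report$files <- files
  report$summary <- list(
    n_genes = nrow(study$exprs),
    n_samples = ncol(study$exprs),
    n_de = if (!is.null(results$de)) sum(results$de$de) else NULL,
    n_modules = if (!is.null(results$modules)) {
      length(setdiff(unique(results$modules$module), "unassigned"))
    } else NULL,
    n_dm = if (!is.null(results$methylation)) {
      sum(results$methylation$class != "none")
    } else NULL
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  results$report <- report
  invisible(results)
}
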