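# placentr

Placental multi-omic analysis of preeclampsia phenotypes, as one tested,
tidyverse-native R pipeline.

Preeclampsia — new-onset hypertension with proteinuria in pregnancy — comes
in a severe preterm phenotype, typically accompanied by fetal growth
restriction and placental maternal-vascular-malperfusion lesions, and a
milder term phenotype. Dissecting its placental origins requires a chain of
bespoke computational steps that are usually re-implemented ad hoc for each
study. `placentr` packages that chain for researchers working on placental
transcriptomics, targeted methylation, and maternal-blood biomarkers:

* **Tissue specificity** — call predominantly placenta-expressed genes from
  a 79-tissue atlas by three rules: level ≥ 1,000 fluorescence units,
  ≥ 6× the median of the other tissues, ≥ 2× the second-highest tissue;
  plus the liquid-biopsy enrichment score (placental level / mean of the
  other tissues).
* **Differential expression** — quantile normalization, log2(50) intensity
  filter, per-gene linear models with batch adjustment and empirical-Bayes
  moderated *t*; DE at *q* ≤ 0.2 and fold change ≥ 1.5.
* **Co-expression modules** — similarity `s_ij = |cor(x_i, x_j)|`, soft
  thresholding `a_ij = s_ij^β` (β = 10, scale-free criterion), topological
  overlap `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
  average-linkage clustering on `1 − TOM` with a dynamic hybrid-style cut,
  and hub transcription-regulator ranking (mean log2 intensity > 9, partner
  count at |r| > 0.7).
* **Clinical association** — per-gene models of MAP and birthweight
  percentile, module enrichment among trait-associated genes (Fisher), the
  maternal vascular malperfusion score, and qPCR −ΔCt processing with
  calibrator-based batch adjustment and group×maturity interaction models.
* **Virtual liquid biopsy** — biomarker levels as percent of
  gestational-age-matched control, Pearson trends across gestation, and a
  12-week first-trimester split.
* **Pattern match score** — discretize DE into UP/DN/NS, score pattern
  pairs (+1 perfect match, 0 neutral, −1 mismatch, −0.5 otherwise), and
  test concordance by permuting class labels with the full DE chain
  re-derived per permutation (exhaustive when ≤ 20,000 arrangements, else
  5,000 random).
* **Methylation** — coverage-filtered CpG ratios (≥ 4 reads, runs summed),
  Poisson GLM with log(total) offset (t-test fallback for all-zero
  groups), Wilcoxon for clinical cohorts (groups ≥ 4), mild / moderate /
  strong classification at *p* < 0.05 and |Δ| ≥ 0.125 / 0.25 / 0.5, and
  Kendall tau-b clinical correlations.
* **Synthetic data** — seeded generators for every input with planted
  ground truth (modules, DE shifts, trait links, atlas positives, biomarker
  trends, methylation differences), so each stage is testable by parameter
  recovery.

## Worked example

```r
library(placentr)
library(dplyr)

# a 12-case vs 5-control study with two planted trait-linked modules
study <- simulate_study(seed = 42)

de <- de_linear_model(study)            # q <= 0.2, FC >= 1.5
glance(de)
#>   n_genes  n_de  n_up n_down q_threshold fc_threshold
#> 1     500   100    50     50         0.2          1.5

modules <- detect_modules(build_network(study, genes = de$gene[de$de]))
glance(modules)
#>   n_genes n_modules n_unassigned largest_module
#> 1     100         2            0             50

head(hub_candidates(study, modules), 3)
#>   gene  module mean_intensity n_partners sum_abs_r  rank
#> 1 G0033 M1               9.09         52      45.7     1
#> 2 G0060 M2               9.41         63      56.3     1
#> 3 G0086 M2               9.75         61      54.9     2

# enrichment of placenta-predominant genes among DE genes, from the
# published counts (38/119 predominant vs 1371/14411 other genes)
fisher_exact_2x2(38, 119, 1371, 14411)[, 1:2]
#>   odds_ratio       p_value
#> 1       3.36 0.00000000690

ga_trend(simulate_biomarker_db(seed = 42))
#>   marker     r  p_value     n first_trimester_mean late_slope_sign
#> 1 CGB3   0.973 2.23e-19    30                 82.6               1
#> 2 CSH1   0.192 3.10e- 1    30                 69.7               1
#> 3 ENG    0.969 1.24e-18    30                 96.3               1
#> 4 FLT1   0.978 1.59e-20    30                 98.1               1
#> 5 LEP    0.964 1.07e-17    30                 95.1               1
```

The 500-gene study recovers both planted 50-gene modules exactly (all 100
DE genes assigned, none spurious), the Fisher odds ratio of 3.36 rounds to
the published 3.4 at p = 6.9 × 10⁻⁹, and the rising biomarkers show strong
gestational-age trends (r ≈ 0.97) while the flat marker (CSH1) does not.

Full runs — simulation through DE, modules, hubs, enrichment, clinical
association, liquid biopsy, and methylation, with per-stage TSVs and a JSON
report — go through `run_pipeline()`, configured by a list or YAML file:

```r
run_pipeline(list(seed = 1, output_dir = "out",
                  simulate = list(study = list(n_genes = 300))))
```

The methods vignette (`vignettes/placentr-methods.Rmd`) documents the
models, their assumptions, every tunable threshold, and the design of the
synthetic generators.

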