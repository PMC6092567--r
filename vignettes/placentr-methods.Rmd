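---
title: "Methods: placental multi-omic dissection of preeclampsia phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: placental multi-omic dissection of preeclampsia phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentr)
```

## Scientific background

Preeclampsia is a hypertensive pregnancy syndrome with two clinically
distinct phenotypes: preterm disease (delivery before 37 weeks), which is
frequently accompanied by fetal growth restriction and placental lesions of
maternal vascular malperfusion, and term disease, which is milder and more
often driven by maternal predisposition. The syndrome originates in the
placenta: impaired extravillous trophoblast invasion leads to deficient
spiral-artery remodeling, malperfusion, ischemic stress of the villous
trophoblast, and ultimately the release of anti-angiogenic factors into the
maternal circulation.

`placentr` implements, as one tested pipeline, the computational procedures
such a study needs: calling predominantly placenta-expressed genes from a
multi-tissue expression atlas; moderated-t differential expression (DE);
weighted gene co-expression network analysis with topological-overlap
clustering and hub-gene selection; gene-level models of clinical traits
(mean arterial pressure, MAP, and birthweight percentile, BW); a "virtual
liquid biopsy" that aggregates literature measurements of placenta-enriched
maternal-blood biomarkers as percent of control across gestation; a
discretized match-score permutation test linking in vitro trophoblast
differentiation to in vivo disease signatures; and classification of
targeted bisulfite CpG methylation differences. A seeded synthetic-data
module generates every input with planted ground truth, so each stage is
validated by parameter recovery rather than by re-deriving any published
gene list.

## Models and procedures

### Tissue specificity

A gene is called predominantly expressed in the target tissue when its
linear-scale level satisfies all three rules: level at least 1,000
fluorescence units; at least 6 times the median across the other 78
tissues; and at least 2 times the highest other tissue. Ties at a threshold
pass, matching the published ">= 1,000 units" wording. Probe-level calls
collapse to genes by *any-pass*. The liquid-biopsy enrichment score is the
target level divided by the mean of all other tissues.

### Differential expression

Linear-scale matrices are log2-transformed, quantile-normalized
(`limma::normalizeQuantiles`), and filtered to genes exceeding log2(50) in
at least two samples — in that order, so the filter sees normalized values.
Per-gene linear models over group and batch are fitted with `limma`;
moderated t-statistics use empirical-Bayes variance shrinkage with
moment-matched hyperparameters. A gene is DE when its Benjamini–Hochberg
q-value is at most 0.2 *and* its linear fold change is at least 1.5
(`|log2FC| >= log2 1.5`). "Control" is always the reference level, so
positive fold changes mean up-regulation in cases.

### Co-expression network and modules

On the DE genes, the similarity is the absolute Pearson correlation
`s_ij = |cor(x_i, x_j)|`, soft-thresholded to the adjacency
`a_ij = s_ij^beta` with `beta = 10`, chosen by the scale-free topology
criterion (the slope-sign-corrected R² of the log–log degree regression is
higher at `beta = 10` than at `beta = 1` for module-structured data; the
sign correction matters because an unthresholded network can fit a *rising*
line well). The topological overlap is

    TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij),

with unit diagonal, and `1 - TOM` is the distance for average-linkage
hierarchical clustering. Module detection re-implements a dynamic hybrid
cut with three parameters: the dendrogram is cut at a `deep_split`-dependent
fraction of its maximum merge height (0.95/0.975/0.99/0.995 for levels
0–3); branches below `min_module_size` (default 30) are dropped; and a
branch is accepted as a module only when its mean intra-branch distance is
at most a `deep_split`-dependent fraction (0.80/0.85/0.90/0.95) of its mean
distance to the rest of the network. This tightness gate is what keeps
unstructured noise unassigned: for planted modules with within-correlation
0.8 the intra/inter ratio is around 0.8, while for pure noise it
concentrates near 0.94. A PAM-like final stage assigns an unassigned gene
to the nearest module when its average distance is within that module's
median intra-module distance. Modules are labelled M1, M2, ... by
decreasing size with a deterministic tie-break, and `"unassigned"` is the
reserved label. Acceptance is by planted-module recovery (adjusted Rand
index), not label-for-label agreement with any published clustering, whose
many internal constants are not reproduced here.

Hub candidates are transcription-regulator genes with mean log2 intensity
strictly above 9, ranked within modules by the number of co-expression
partners with `|r| > 0.7`, with ties broken by summed `|r|` and then gene
id, so the ranking is deterministic.

### Clinical association

Gene-trait models regress each gene's log2 expression on MAP and BW
percentile (both continuous) with batch adjustment, using moderated t per
coefficient and per-trait BH correction at q <= 0.2. The maternal vascular
malperfusion score is the arithmetic sum of binary lesion flags; qPCR
`-dCt` values are regressed on it (optionally adjusting for gestational
age) with significance at p < 0.05. qPCR processing uses
`-dCt = Ct(RPLP0) - Ct(gene)` with per-batch, per-gene calibrator
offsets so a calibrator sample has the same `-dCt` in every batch; the
group model allows a group-by-maturity interaction and reports the group
effect within each maturity stratum.

### Virtual liquid biopsy

Biomarker measurements, expressed as percent of gestational-age-matched
control levels, are analyzed per marker by Pearson correlation against
gestational week, with a half-open split at 12 weeks
(`[start, 12)` vs `[12, end]`) for trimester summaries and a direction
label (below / at / above 100%). Aggregation across studies is unweighted
by default; the original reports rarely state comparable precisions, so
equal weighting is the least-assumption choice, with sample-size weighting
left to the caller.

### Pattern match score

DE results are discretized per gene into UP / DN / NS states (q <= 0.05 and
fold change >= 1.5 by default). Two patterns are compared by summing
per-gene scores: +1 for UP/UP or DN/DN, 0 for NS/NS, −1 for UP/DN or
DN/UP, −0.5 for every other pair. Significance comes from permuting the in
vitro class labels, *re-deriving the whole DE-and-discretize chain under
each permutation* — the labels feed the DE computation, so shuffling states
alone would understate the null variance. Permutations are exhaustive when
the number of distinct arrangements is at most 20,000, otherwise 5,000
random arrangements are drawn; exhaustive p is the raw proportion of
arrangements at least as extreme (the observed labeling is itself an
arrangement, so p >= 1/P), and sampled p uses the (1 + extreme)/(1 + n)
convention so it is never zero. The default alternative is one-sided for
high concordance.

### Methylation

Repeated sequencing runs are summed per sample and CpG before the coverage
filter (total >= 4 reads); the methylation ratio is methylated/total with
1-based coordinates preserved exactly. Group comparison fits a Poisson GLM
with log link on methylated counts with `log(total)` as offset, so the
group coefficient is a log rate ratio of methylation; when either group has
all-zero methylated counts — where that MLE diverges — a two-sample t-test
on the ratios substitutes. Clinical-cohort comparisons use the two-sided
Wilcoxon rank-sum test with a minimum group size of four. Differential
methylation is classified mild / moderate / strong when p < 0.05 and the
absolute ratio difference is at least 0.125 / 0.25 / 0.5 (the highest tier
met; tiers are nested). Correlations with clinical variables use the
tie-corrected Kendall tau (tau-b), chosen because methylation ratios tie
frequently.

### Shared statistics

`fisher_exact_2x2` enumerates the conditional hypergeometric distribution
directly; the two-sided p follows the minimum-likelihood convention with a
relative tie tolerance of 1e-7, and the reported odds ratio is the sample
cross-product ratio `ad/bc` so printed enrichment statistics can be
reproduced from published counts. A table with an empty row or column
margin carries no association information and reports OR = 1. The
power-simulation rule declares a planned validation design acceptable when
more than 25% of simulated repeats reach p < 0.05 under the paired t or
Mann–Whitney test.

## The synthetic-data generators

`simulate_study` emulates a 12-case vs 5-control preterm design: per-gene
baselines N(8, 1.5) log2 units, an additive gene-independent batch offset
(SD 0.3), Gaussian noise (SD 0.2), and planted modules driven by one latent
eigen-signal each with per-gene loadings uniform on (0.5, 1); the signal
scale is solved so the expected within-module correlation matches the
specification. Three design choices deserve note:

* **Traits follow module activity, not the bare eigen-signal.** A planted
  case–control shift is part of what the module's genes express, and the
  linked trait must co-vary with case status — elevated blood pressure
  *defines* the cases. The trait is therefore built from the standardized
  sum of eigen-signal and shift, mixed with independent noise to hit the
  requested trait correlation (default 0.8).
* **Eigen-signals are orthogonalized in-sample — against each other and
  against the group indicator.** At 17 samples, two independent random
  vectors correlate with SD ≈ 0.25, and that single number propagates into
  *every* between-module gene pair; orthogonalizing each new eigen-signal
  against the previous ones makes the planted between-module independence
  hold exactly rather than on average. Likewise, an eigen-signal's chance
  group imbalance would add one shared offset to every module gene's
  fitted fold change, coupling their recovery; residualizing against the
  group indicator makes the planted shift the only group effect, so DE
  sensitivity and module recovery are decoupled and each contract is
  individually testable.
* **Sequencing depths are negative-binomial with a floor of one read**, so
  the coverage filter is genuinely exercised.

The atlas generator constructs positives that satisfy all three
predominance rules with margin and negatives that provably fail at least
one (half below the absolute floor, half ubiquitously expressed). The
biomarker generator plants linear percent-of-control trends — one marker
constantly below control, the others rising through gestation and crossing
the control line after the first trimester. The methylation generator draws
binomial methylated counts at a baseline ratio of 0.3 with a planted ratio
shift in the case group.

What these generators do *not* emulate: probe-level microarray artifacts,
correlated noise between genes outside planted modules, missing clinical
covariates, read-level bisulfite error, and between-study heterogeneity in
the biomarker database. Passing recovery tests therefore demonstrate that
the estimators are correct under the stated statistical structure, not that
real cohorts of this size would yield the same power.

## Calibration notes and known limitations

* **The Poisson group test is conservative on binomial counts.** Methylated
  counts are binomial given totals, with variance `np(1-p)` — smaller than
  the Poisson variance the GLM assumes by the factor `(1-p)`. At the
  generator's baseline ratio of 0.3 the Wald test therefore rejects at
  roughly 1.5–2.5% rather than 5% under the null. The acceptance suite
  asserts the nominal 5% band and this check is expected to fail; the unit
  suite asserts the honest property, that the test is never
  anti-conservative. At low methylation ratios (p → 0) the Poisson
  approximation — and hence the calibration — becomes exact.
* **Exhaustive permutation p-values are granular.** With 4-vs-4 designs the
  null has 70 arrangements, so the attainable level closest to 0.05 is
  3/70 ≈ 0.043; calibration checks are run against that attainable level.
* **BH re-adjustment is not idempotent.** Re-applying the step-up procedure
  to already-adjusted values can only inflate them (the smallest entries can
  be raised to the tail minimum); the tests assert exactly that dominance
  property.
* Problem sizes used by the test and acceptance suites — 100–500 genes,
  17 samples, 600 CpGs, 200 permutation repeats — were chosen as the
  smallest sizes at which the recovery and calibration properties are
  stable, and are stated in each test.

## Numerical conventions

Ties at thresholds pass (`>=` semantics) throughout; DE direction is
case-over-control with "control" auto-detected as the reference level;
module labels and hub rankings are made deterministic by explicit
tie-breaks; exhaustive permutation results are seed-independent;
coordinates stay 1-based end to end; and `run_pipeline` with a fixed seed
produces byte-identical stage outputs, which the test suite checks by
re-running the full pipeline twice.
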