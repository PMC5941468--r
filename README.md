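# pubmeth

Paired, sex-stratified differential DNA-methylation analysis across the
window of puberty, for Illumina 450K-style beta-value matrices.

## Who this is for

Epigenomics analysts with a paired longitudinal design — each child sampled
pre-puberty (~age 8) and post-puberty (~age 14) — who want a tested,
self-contained pipeline for:

* probe QC (sex-chromosome / multi-mapping / SNP-overlap / detection-p
  filters), PCA confounder screening and batch adjustment;
* paired differential methylation per sex with empirical-Bayes variance
  moderation, a sex-by-age interaction test, BH FDR control and DMP-set
  summaries;
* nearest-TSS gene assignment and region categories;
* a permutation test for over-representation of predicted
  estrogen-responsive genes, with an exact hypergeometric oracle;
* co-expression module detection in post-puberty expression and per-module
  enrichment;
* an unsupervised hierarchical-clustering puberty-status classifier;
* cell-composition, methylation–expression and ancestry-subset confound
  checks.

No external data are required: `simulate_cohort()` generates synthetic
cohorts with ground-truth tables that exercise every stage.

## The model in brief

Per probe, within-individual differences Δᵢ = βᵢᵖᵒˢᵗ − βᵢᵖʳᵉ are tested
with a moderated one-sample t:

    t̃ = mean(Δ) / (s̃/√n),   s̃² = (d₀s₀² + d s²)/(d₀ + d),   d = n − 1,

p-values from t on d₀+d df, where (d₀, s₀²) is a scaled inverse-χ² prior
fit across probes by method of moments on log s² (the standard array
variance-moderation device; with d₀ = 0 this is exactly the classical
paired t-test). The sex × age interaction is the two-sample moderated t on
the female vs male Δ matrices. Gene-set enrichment follows the resampling
frame in which each of 500,000 iterations draws |observed| genes from the
estrogen-responsive set and tallies overlaps with the observed DMP-gene
list ("literal" mode); a "universe" mode with an exact hypergeometric null
is also provided. See `vignettes/methods.Rmd` for assumptions, parameter
defaults and design decisions.

## Worked example

```r
library(pubmeth)

cfg   <- sim_config(n_probes = 5000, seed = 1)   # 30 F + 25 M pairs,
co    <- simulate_cohort(cfg)                    # 347/50/48 planted DMPs
delta <- paired_delta(co$beta_pre, co$beta_post, co$sheet)
sex   <- attr(delta, "sex")

res_f <- moderated_paired_test(delta[sex == "F", ], group = "female")
res_m <- moderated_paired_test(delta[sex == "M", ], group = "male")
res_c <- moderated_paired_test(delta, group = "combined")
sets  <- classify_dmps(res_f, res_m, res_c, 0.05)
sets$counts
#>     female_specific       male_specific              shared female_male_overlap
#>                 316                  38                 316                  30

s <- summarize_dmps(sets$female_specific, delta[sex == "F", ], co$annotation)
sprintf("female-specific DMPs: %d (%.1f%% hyper), median |dbeta| = %.3f",
        s$n, s$pct_hyper, s$median_abs_delta)
#> "female-specific DMPs: 316 (45.9% hyper), median |dbeta| = 0.032"

obs <- genes_near_dmps(sets$female_specific, co$annotation)
permutation_enrichment(obs, co$er_set, co$genes$gene,
                       n_perm = 10000, mode = "universe", seed = 1)
#> Gene-set enrichment (universe mode, 10000 permutations)
#>              in_set out_of_set
#> observed         51        247
#> not_observed    264       1438
#> overlap 51/298 (17.1%), set 315, universe 2000
#> exceedances r = 2678; permutation p = 0.268
#> exact hypergeometric tail p = 0.267; Fisher (right) p = 0.267
```

Reading the output: at FDR 5% the stratified female analysis recovers 316
female-specific DMPs (347 were planted), with the hyper/hypo split and the
median |Δβ| ≈ 0.03 matching the generator's effect-size regime. The
generator plants *no* estrogen-responsive enrichment, and the permutation
p ≈ 0.27 agrees with the exact hypergeometric tail — the null machinery is
calibrated. The published-count reproduction (312 genes drawn from the
3,497-gene set, 63 observed in set, 500,000 draws, exceedance count 0,
bound p < 2.0 × 10⁻⁶) is run by the acceptance script below and by
`tests/testthat/test-acceptance.R`.

An end-to-end run with tables, JSON report and log:

```r
rep <- run_pipeline(pipeline_config(seed = 1), outdir = "run1")
```

or from the shell: `inst/scripts/pubmeth run-all --seed 1 --outdir run1`
(subcommands: simulate, filter, dmp, annotate, enrich, coexpress, classify,
confounds, run-all).

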