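# cflmd — cell-free DNA methylation diagnostics for lupus

`cflmd` is an R package for building and evaluating a cfDNA-methylation
diagnostic of systemic lupus erythematosus (SLE) and lupus nephritis.
It is written for epigenomics analysts who have: several public
HM450-style methylation and expression cohorts, a small plasma WGBS
case/control cohort, and the usual annotation files — and who want a
tested, reproducible path from those inputs to a diagnostic score with
an immune-microenvironment readout.

The pipeline:

1. **Consensus screening across array cohorts.** An empirical-Bayes
   moderated t-test (variances shrunk toward a method-of-moments
   scaled-F prior) scores every probe/gene; differentially methylated
   probes must satisfy |Δmean| ≥ 0.1 with control SD < 0.2 and case
   SD < 0.3 (top 1000 per direction), and features are kept only when
   at least 3 cohorts agree in the same direction.
2. **WGBS differential methylation.** A per-CpG beta-binomial Wald test
   with two shrinkage layers — group means shrunk toward a 500 bp local
   smooth, per-site dispersions shrunk toward the chromosome median —
   calls DMPs at p < 0.01 and |Δ| > 0.2, then merges same-direction runs
   (gap ≤ 1 kb, ≥ 6 member sites, Stouffer region p < 0.05) into DMRs.
3. **Subsample augmentation.** Binomial read-thinning expands 3 + 3
   parent samples into 21 control and 60 case sub-samples (7/20
   replicates at retention 0.5).
4. **Feature integration.** Model DMRs = WGBS DMRs overlapping the probe
   loci of genes that are both consensus DEGs and DMGs; features are
   region mean methylation (pooled ratio for WGBS, probe mean for
   arrays).
5. **Diagnostic model.** A three-hidden-layer feed-forward network
   (logistic activations, cross-entropy, full-batch gradient descent)
   on a stratified 0.6666 split, evaluated by rank-based ROC AUC and by
   Spearman correlation between score and disease activity.
6. **Immune profiling.** Non-negative-least-squares methylation
   deconvolution onto a cell-type signature, ssGSEA sample scores,
   hypergeometric over-representation and pre-ranked enrichment.

A synthetic-data module simulates every input with planted ground truth
(differential probes, DMRs, mixture proportions, a severity-coupled
activity score), so the whole pipeline is testable end to end without
downloading anything.

## Worked example

Simulate a linked multi-platform study (three expression cohorts, three
array cohorts, one 3v3 WGBS cohort, shared planted genes) and run the
full pipeline:

```r
library(cflmd)

cfg <- sim_config(seed = 11, n_control = 3, n_case = 3, n_cpgs = 2000,
                  n_true_hypo = 6, n_true_hyper = 4, effect_size = 0.3,
                  depth_mean = 30)
study <- simulate_integrated_study(cfg)

res <- cflmd_pipeline(study$expr_cohorts, study$array_cohorts,
                      study$wgbs$tables, study$ann, seed = 5)
res$model_regions
#> # A tibble: 8 × 8
#>   chrom start   end n_dmps mean_delta direction region_p gene
#>   <chr> <int> <int>  <int>      <dbl> <chr>        <dbl> <chr>
#> 1 chr1  32122 32606      7     -0.335 hypo      4.61e-36 GENE002
#> 2 chr1  41530 42154      7      0.332 hyper     3.05e-46 GENE003
#> 3 chr1  49328 49572      6     -0.375 hypo      5.65e-43 GENE004
#> 4 chr1  51704 52421      8     -0.380 hypo      5.42e-63 GENE005
#> # … 4 more planted regions, 0 false ones
```

Eight of the ten planted regions survive the DEG ∩ DMG ∩ DMR screen
(each recovered region carries its planted gene; `mean_delta` is the
case-minus-control methylation difference, hypo-dominant as planted).
The trained model and its validation performance:

```r
res$model
#> <cflmd_model> 8 features -> [16, 8, 4] -> score; 3000 epochs, final loss 0.0089

head(res$scores, 3)
#> # A tibble: 3 × 4
#>   sample_id       score true_group activity
#>   <chr>           <dbl> <chr>         <dbl>
#> 1 ctrl_01_rep01 0.00285 control      0.0568
#> 2 ctrl_02_rep01 0.00282 control      0.215
#> 3 ctrl_02_rep03 0.00283 control      0.215

res$auc                 # validation AUC on 27 held-out sub-samples
#> [1] 1
res$activity_spearman   # score vs disease activity, all 81 sub-samples
#> [1] 0.881
```

Control sub-samples score near 0, cases near 1; the score's rank
correlation with the planted disease-activity covariate is 0.88.
`plot_roc(res$scores)`, `plot_volcano()`, `autoplot(res$model)` and
`plot_proportions()` draw the standard figures; `tidy()`/`glance()`
expose model internals as tibbles.

Individual stages are plain functions on tibbles and light containers:
`read_bismark_cov()` / `bb_wald_test()` / `call_dmps()` / `call_dmrs()`
for the WGBS side, `read_beta_matrix()` / `impute_missing()` /
`moderated_t_test()` / `select_dmps()` / `consensus_features()` for
arrays, `deconvolve()` / `ssgsea()` / `ora_hypergeometric()` /
`gsea_preranked()` for immune profiling.

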