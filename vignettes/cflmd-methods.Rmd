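---
title: "Methods behind the cfDNA lupus methylation diagnostic pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the cfDNA lupus methylation diagnostic pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cflmd)
```

Systemic lupus erythematosus (SLE), and lupus nephritis (LN) in
particular, leaves a methylation footprint on the cell-free DNA (cfDNA)
circulating in plasma: a global loss of methylation concentrated at gene
promoters, accompanied by interferon-driven changes in the blood and
kidney immune microenvironment. `cflmd` implements an end-to-end pipeline
that turns that footprint into a diagnostic score: consensus differential
screening across public array cohorts, whole-genome bisulfite sequencing
(WGBS) differential methylation on a small plasma cohort, cross-platform
feature integration, a small neural-network classifier, and
immune-microenvironment annotation. This vignette explains the models,
their assumptions, the tunable parameters, and what the synthetic-data
experiments do and do not establish.

## The array side: moderated t and the DMP/DEG screens

Each array cohort is a probes-by-samples matrix of methylation beta
values in [0, 1] (or genes-by-samples log expression). Missing beta
values are resolved explicitly by k-nearest-probe imputation
(`impute_missing()`, k = 10 by default); they are never silently
zero-filled.

`moderated_t_test()` computes per-feature case-vs-control t statistics
with empirical-Bayes variance shrinkage. Pooled per-feature variances
`s^2` (d residual degrees of freedom) are modelled across features as
`s0^2 F(d, d0)`; the prior scale `s0^2` and degrees of freedom `d0` are
estimated by method of moments from the mean and coefficient of variation
of the observed `s^2`. The moderated variance is
`(d0 s0^2 + d s^2) / (d0 + d)` and p-values use `d + d0` degrees of
freedom. Two limits anchor the implementation: `prior_df = 0` is exactly
the classical pooled t-test (unit tested at 1e-8 agreement), and on
homoskedastic data the estimated `d0` grows large and the test approaches
a z-test. The test suite also checks rank agreement (r > 0.99) with an
independent moderated-t implementation on shared data.

Differentially methylated probes pass three joint criteria
(`select_dmps()`): |case mean − control mean| at least `delta_min` = 0.1,
control-group SD below 0.2, case-group SD below 0.3; survivors are ranked
by |delta| and capped at 1000 per direction. The SD ceilings encode the
idea that a usable marker is consistent within each group — asymmetric
because patients are biologically more heterogeneous than controls. A
literal small-difference reading of the effect criterion
(`delta_rule = "max"`, keeping |delta| <= 0.1) is retained only for
comparability; it selects non-differential probes and is not the default.
Differentially expressed genes use p < 0.05 and a top-1000 cap per
direction, applied in that order (filter, then cap).

`consensus_features()` selects a feature only when at least
`min_datasets` (default 3) cohorts agree *in the same direction*;
features with any cross-cohort direction conflict are flagged and never
selected. The default of 3 is used for both the expression and the
methylation screens and is configurable, since reasonable readings of the
screening rules differ on whether "three" is inclusive.

## The WGBS side: beta-binomial Wald test with two shrinkage layers

WGBS gives per-CpG counts (methylated reads / total reads) for a handful
of samples per group — here 3 vs 3 by default, the realistic scale of a
plasma sequencing pilot. `bb_wald_test()` tests each site covered in both
groups with a Wald statistic built from two shrinkage layers:

1. **Mean shrinkage toward the local smooth.** The group methylation
   level at a site is the pooled group fraction shrunk toward a local
   target with 20 pseudo-reads; the target is the coverage-weighted mean
   of per-sample window-smoothed fractions (±250 bp, `window_bp = 500`).
   At typical coverage (tens of reads per group) the site data dominate,
   so region edges are not diluted; at sparse sites the local smooth
   takes over. With one deeply covered isolated site per group the
   statistic reduces exactly to the unpooled two-proportion z-test
   (tested at depth 10^4 to 1e-3).
2. **Dispersion shrinkage toward the chromosome median.** A per-site
   beta-binomial dispersion is estimated by method of moments from
   residuals around the raw pooled group fractions (raw, not smoothed —
   otherwise site-to-site baseline heterogeneity masquerades as
   dispersion), clamped to [0, 0.95], then shrunk toward the
   chromosome-wide median with weight `m/(m + n_samples)`, `m = 20`
   pseudo-observations. With 6 samples this is deliberately heavy: at
   this design size per-site dispersion is barely estimable.

The group variance is the beta-binomial variance of the pooled site
fraction. Because the mean estimator only gains precision from the
smoothing prior, the resulting test is mildly conservative: on null
simulations the empirical false-positive rate at alpha = 0.01 sits around
0.002–0.003. Sites covered in only one group are skipped, not imputed.

DMPs require p < 0.01 and |delta| > 0.2; DMRs (`call_dmrs()`) merge
consecutive same-direction DMPs with gaps at most 1 kb, require at least
6 member DMPs ("more than five", with 5 available as the inclusive
reading), and a Stouffer-combined member p-value below 0.05. Chromosomes
are processed independently and all results are invariant to input file
order.

**Subsample augmentation.** A pilot-scale design (3 + 3 parents)
cannot feed a classifier directly, so `augment_subsamples()` expands each
control 7 times and each case 20 times by binomial thinning: every
replicate keeps each read independently with probability `thin_fraction`
(default 0.5). The replicate counts reproduce the 21-control /
60-case bookkeeping; thinning halves coverage in expectation (checked
within 5%) and `thin_fraction = 1` returns exact copies. Augmentation
feeds only the classifier; DMR calling always uses the parent samples.
The stratum depth of the original sampling scheme is under-specified, so
the thinning fraction is exposed rather than hard-coded.

## Feature integration and the classifier

Model regions are screened in two steps (`screen_model_regions()`):
disease-specific genes are the intersection of consensus DEGs and DMGs;
each gene's locus is the interval spanning its annotated probes, padded
by 2 kb (a definition that needs only the array annotation, no gene
model file); WGBS DMRs overlapping at least one locus are retained.
Feature values are the coverage-weighted pooled methylation ratio of the
region in WGBS samples (`build_feature_matrix_wgbs()`), and the
unweighted mean beta of probes inside the region for array samples
(`project_features_array()`); the two agree within 0.05 when probes sit
exactly on deeply covered CpGs. Array regions with no covering probe are
dropped — from every matrix, to keep feature spaces aligned.

The classifier is a fully connected network with three hidden layers
(default sizes 16, 8, 4 — the layer count is the fixed design choice,
the widths are tunable), logistic activations, sigmoid output and
cross-entropy loss, trained by full-batch gradient descent
(`learning_rate` 0.5, `l2_penalty` 1e-4, 3000 epochs) with
Glorot-uniform initialisation under a fixed seed. Feature
standardisation parameters are learned on the training split only and
frozen into the model, so validation data never leak into the scaling.
The 0.6666 train fraction is applied per class with round-half-up
(21/60 sub-samples split into 54 training and 27 validation). Scores are
evaluated by rank-based AUC (ties count one half); score–activity
association uses Spearman correlation over all scored samples — the
diagnostic claim is held out, the severity correlation is a cohort-level
description.

## Immune profiling

`deconvolve()` estimates cell-type proportions by non-negative least
squares of each bulk profile on a marker-by-cell-type methylation
signature, followed by projection onto the probability simplex. This is
a deliberate, validated substitute for least-absolute-deviation
deconvolution machinery: correctness is established by mixture recovery
(exact at zero noise, RMSE < 0.05 at noise SD 0.02 with five cell
types), not by bit-compatibility with any particular tool. No reference
signature ships with the package; `synthetic_signature()` generates a
well-conditioned one and the CSV schema accepts any user-supplied
matrix.

`ssgsea()` scores each sample against gene sets by the integrated
difference between the weighted in-set ECDF (weights = expression
mid-rank^0.25) and the uniform out-of-set ECDF. Mid-ranks make the score
exactly zero under fully tied expression and the closed form equals the
brute-force running sum for strict orderings. Being rank-based, scores
are invariant under monotone transforms of expression.
`ora_hypergeometric()` is the standard upper-tail hypergeometric
over-representation test with BH adjustment; `gsea_preranked()` computes
the weighted Kolmogorov-Smirnov enrichment score with gene-resampling
p-values. The enrichment statistic matches an independent implementation
to 1e-8 on shared rankings.

## The synthetic-data generators

The generators are first-class, tested code: every downstream stage is
exercised against planted ground truth without any external download.

* **Array cohorts** (`simulate_array_cohort()`): per-probe baselines from
  Beta(2, 2) — intermediate methylation, where differential signal is
  detectable; planted probes shift case means by ±`effect_size`, clipped
  to [0, 1] (a warning reports when more than 10% of planted effects hit
  a boundary, which the default effect of 0.3 triggers by design);
  per-sample values from a Beta distribution with precision 30 around
  the group mean. Each simulated patient carries a severity factor
  (uniform on 1 ± `severity_spread`, default spread 0.4) scaling the
  planted shift — lupus cohorts span an activity spectrum, and without
  this the activity score would have no within-case signal to track.
* **WGBS cohorts** (`simulate_wgbs_cohort()`): CpGs laid on two synthetic
  chromosomes with geometric gaps (mean 100 bp, between CpG-island and
  genome-background spacing); coverage Poisson(30) floored at one read;
  planted DMRs are runs of 8 consecutive CpGs shifted by ±`effect_size`
  scaled by patient severity. The planted signal is hypo-dominant
  (default 120 hypo vs 80 hyper probes; 6 vs 4 regions in the linked
  study), mirroring the global hypomethylation of lupus cfDNA.
* **Activity score**: `activity_slope` (default 10) times the sample's
  mean planted-signal deviation plus N(0, 0.3) noise, truncated at zero
  — an SLEDAI-like non-negative severity scale whose coupling to the
  methylation signal is known exactly.
* **Mixtures** (`simulate_mixtures()`): signature times known simplex
  proportions plus Gaussian noise, clipped to [0, 1].
* **Linked study** (`simulate_integrated_study()`): one WGBS cohort,
  a probe annotation that places three probes of one gene inside each
  planted region (plus null genes elsewhere), and three array plus three
  expression cohorts whose planted features mirror the region directions
  — the world in which the full pipeline should recover exactly the
  planted genes.

What passing these experiments shows — and what it does not: the
generators produce unimodal, beta-distributed array values and purely
binomial read sampling. Real arrays are bimodal with probe-type effects
and batch structure; real WGBS has correlated errors from mapping and
bisulfite conversion, copy-number distortion, and cell-composition
drift; real cohorts have confounders the consensus screen can only
partly absorb. Recovery of planted signal here establishes internal
correctness of the statistics and plumbing, not field performance on
clinical plasma.

## Numerical choices and problem sizes

Recovery experiments plant the stated fixed effects
(`severity_spread = 0`): DMR recall is measured at 3v3, depth 30, effect
0.4, 8-CpG regions over 20 seeds; array recall/precision at 20v20,
effect 0.3 over 10 seeds. The end-to-end experiment keeps the severity
spectrum and runs at effect 0.3 with 2000 CpGs, 10 planted regions and
three 20v20 array/expression cohorts — sizes chosen so the full suite
exercises every stage in about a minute on a laptop core while leaving
all planted-signal margins wide. The shuffled-label negative control is
reported as a mean over 60 draws: augmented sub-samples are
pseudo-replicates of six parents, so a single-draw validation AUC is
close to bimodal and only the average is a meaningful chance level.

Degenerate inputs are handled explicitly: empty coverage files load as
empty tables with a warning; zero-variance features get p = 1 and a
`constant` flag; a region with no coverage in a sample is group-mean
imputed; Spearman on a constant vector returns NA with a warning rather
than an error; BED scores cap −log10(p) at 300.

## Known limitations

The dispersion model shares one dispersion per site across both groups;
group-specific dispersion would need more replicates than the target
design has. The Stouffer region p-value treats member sites as
independent, which smoothing violates mildly — region calls are
therefore slightly anti-conservative at the region level and should be
read together with the per-site effect gate. The network has no early
stopping or calibration; its score separates groups but saturates near 0
and 1 on easy problems, which is why severity tracking is assessed by
rank correlation. CpH contexts, strand-resolved analysis, batch
correction and cell-composition adjustment of arrays are out of scope.
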