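---
title: "Simulating cross-population transcriptome prediction and TWAS power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cross-population transcriptome prediction and TWAS power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the simulation answers

Transcriptome-wide association studies (TWAS) regress a phenotype on
*genetically predicted* gene expression. The prediction models — sparse
per-gene SNP weight vectors in the PrediXcan style — are trained in a
reference population and then applied to a target population that may
differ in allele frequencies, linkage disequilibrium (LD), and in which
variants are causal for expression at all. `twasim` simulates this whole
chain with oracle control over the genetics, so that two confounded forces
can be separated:

* **eQTL architecture sharing** — the fraction `p` of a gene's causal
  *cis*-eQTLs that are identical in position and effect between two
  populations, and
* **genetic ancestry** — allele-frequency and haplotype divergence between
  the training and testing populations, including two-way admixture in any
  proportion.

Every quantity the package reports (prediction correlations, association
power) is computed by running the actual estimation machinery — nested
cross-validation elastic net, dosage-times-weight prediction, linear-model
association tests — on simulated data whose generating truth is known.

## Population model

### Founder-mosaic haplotype panels

Real studies start from phased reference haplotypes. `twasim` instead
generates an ancestral panel from `F` founder haplotypes whose per-site
allele frequencies are drawn from a density proportional to `1/x` truncated
to `[0.02, 0.98]`, concentrating frequencies at intermediate values the way
ascertained SNP panels do. The `H` panel haplotypes are Li–Stephens-style
mosaics of the founders: at each adjacent-site interval the copying template
switches with a per-interval probability (exponentially distributed around
`switch_prob_scale`, mimicking recombination-rate heterogeneity), and each
copied allele is flipped with a small mutation probability. A small founder
count (`F = 12` by default) induces realistic long-range LD; the default
`switch_prob_scale = 0.02` gives haplotype blocks of a few dozen sites
within each 150-site gene region.

### Divergence by drift rounds

Two population panels are derived from one ancestral panel by repeated
mosaic resampling: each *drift round* replaces the panel with `H` fresh
mosaics of itself, drifting allele frequencies by roughly `1/H` per round.
Divergence between two independently derived panels accumulates
approximately linearly in the number of rounds. The default of 40 rounds was
calibrated once so that two derivations reach a mean per-site Hudson F_ST
near 0.14, the continental scale of the CEU–YRI contrast; the Hudson
estimator (with its finite-sample correction) is exposed via
`estimate_fst()` so users can re-calibrate for other scales. The window
0.10–0.20 was chosen as the plausible range for continental divergence; the
paper-scale experiments this design emulates do not report the realized
F_ST of their simulated panels, so the midpoint is our choice.

### Diploid samples and admixture

`expand_population()` draws `2n` mosaics and pairs them into diploids.
`sample_admixed()` constructs a two-way admixed population: for each
individual, each haplotype, and each gene region *independently*, ancestry
is B with probability `alpha` (else A) and the haplotype segment over that
region is a fresh mosaic of the chosen panel. Local ancestry is therefore
constant per haplotype within a gene — the high-ancestry-LD approximation
appropriate for African-American-like admixture — and is recorded per gene
and haplotype. At `alpha = 0` or `1` the admixed sample is an independent
reshuffle of one ancestral panel, not a copy of the corresponding ancestral
sample.

## eQTL architectures and expression

For each gene, `sample_architecture()` places `round(p*k)` shared causal
sites (eligible if minor-allele frequency is at least 5% in *both*
ancestral populations) carrying one common effect, plus `k - round(p*k)`
population-specific sites per population (MAF-eligible in their own
population, disjoint from every other chosen site). The admixed population
inherits the union, `2k - round(p*k)` eQTLs. Effects are i.i.d. standard
normal; their scale cancels because expression noise is matched to the
realized genetic variance.

`simulate_expression()` computes the genetic value `g = X w` from dosages
and adds i.i.d. Gaussian noise with variance `Var(g) (1 - h2) / h2`, so the
realized *cis*-heritability is on target (0.15 by default) in every
population, including the admixed one. The default admixed generator is
ancestry-agnostic: the union effect vector multiplies dosages regardless of
which ancestral panel a haplotype came from. An ancestry-aware variant
(population-specific effects act only through matching-ancestry haplotypes)
is available via `ancestry_aware = TRUE` for sensitivity analyses; the two
coincide exactly when all eQTLs are shared.

## Prediction models

`fit_gene_model()` implements nested cross-validation around
`glmnet::cv.glmnet`:

* **external loop** — leave-one-out or K-fold (default K = 10); each fold's
  held-out predictions are kept, and within-population accuracy is always
  evaluated on these out-of-sample values;
* **internal loop** — per external fold, penalty strength is selected by
  internal cross-validation minimizing mean squared error over a log-spaced
  grid (`lambda.min`); mixing parameter fixed at 0.5;
* **weight averaging** — the final model averages fold weights over *all*
  external folds, counting a site as zero in folds that did not select it.
  Averaging only over selecting folds would inflate rarely chosen sites;
  both readings are defensible, and the conservative one is the default.

Two numerical choices deviate from common defaults: the lambda grid has 30
points with `lambda.min.ratio = 0.01` (the internal-CV error was flat
beyond that on these problem sizes, at half the cost), and predictors are
standardized inside glmnet with weights reported back on the dosage scale.
The `lambda.1se` selection rule is exposed as an option; it is markedly
sparser — pure-noise genes then yield an empty model about 90% of the time
and are removed by the no-eQTL filter — but it also halves the
out-of-sample correlation of genuinely heritable genes at `h2 = 0.15`, so
the MSE-minimizing rule is the default.

Predictions in a target population are `intercept + dosage %*% weights`
over the weight sites present there; the two standard gene filters (no
nonzero-weight site; fewer than half the individuals with nonmissing
predictions) are applied by `apply_model_filters()` with a per-gene reason
log.

## Evaluation

`score_gene()` reports the squared Pearson correlation (identical to the
R-squared of the simple regression of measurement on prediction) and the
Spearman rank correlation with average-rank ties. Constant predictions have
no rank correlation; such genes are scored non-positive with `r2 = 0` and
flagged rather than dropped silently, so filter accounting stays complete.
"Positive correlation" partitions use `rho > 0` strictly. Since expression
is `g` plus independent noise with heritability `h2`, no genotype-based
predictor can exceed a correlation of `sqrt(h2)` (0.387 at the 0.15
default) with expression except by sampling noise — a useful global check
on every scored scenario.

## TWAS power

Phenotypes depend on a single causal gene: `y = G beta + e` with
`e ~ N(0, sigma2)`, `sigma2 = 0.01`, where `G` is the *true* simulated
expression in the test population — predictions enter only in the
association test. Per gene, `run_twas()` regresses `y` on predicted
expression and flags the causal gene significant below `0.05 / 98`. The
denominator stays at the transcriptome-wide family size of the full-scale
design (98 genes) even in scaled-down runs, so "power" always refers to the
same multiple-testing burden. Power is the fraction of replicates — each
redrawing the causal gene uniformly and the noise independently — in which
the causal gene is significant, with a Wilson 95% interval; rejections at
non-causal genes are tallied separately as a family-wise error diagnostic.

Because the variance scale of simulated expression depends on the sampled
architecture, effect sizes are specified through the phenotype heritability
`h2_pheno = beta^2 Var(G) / (beta^2 Var(G) + sigma2)`. The default
calibration (`beta_calibration = "mean_h2"`) solves for one fixed `beta`
per level such that the *mean* realized heritability over candidate causal
genes hits the target. This mirrors the fixed-effect-size design it
emulates: with `beta` fixed, genes with high expression variance yield
higher heritability than genes with low variance, and because power is
concave in heritability near the top of the curve, this spread lowers mean
power relative to pinning every replicate at the target exactly. The
per-replicate pinning is available as `beta_calibration = "per_gene"`; it
yields systematically higher power (about 0.08 at the 0.86 level in our
desk runs) and should be chosen deliberately.

`admixture_sweep()` holds the eQTL architecture, the ancestral samples, and
their trained models fixed while the admixed population's ancestry
proportion moves across the grid, so the admixture proportion is the only
moving part of the comparison.

## Problem sizes and reproducibility

Two presets bundle the configuration: `desk_config()` (n = 400, 20 genes of
150 sites, K-fold(10) external CV, 3 replicates) runs a full grid in
minutes on one core and is the scale used by the package's own evaluation
scripts; `paper_config()` (n = 1000, 98 genes, k in {1, 10, 20, 40}, 11
sharing levels, LOOCV, 100 replicates) mirrors the full-scale design and is
meant for cluster runs — validate it with `run_experiment(cfg, dir,
dry_run = TRUE)`. Power experiments keep n = 1000 populations even at desk
scale because power depends directly on the test-population size and the
Bonferroni threshold; prediction-correlation experiments scale down to
n = 400, which costs a few hundredths of correlation relative to n = 1000
training (0.29 versus 0.33 within-population in our runs).

All randomness flows from one master seed through `split_seeds()`, a
documented splitting rule, so every experiment is bit-reproducible;
`run_experiment()` writes byte-identical tables when rerun with the same
configuration.

Internally, site indices are 1-based and inclusive throughout (the R
convention); exported site tables carry explicit site IDs so no off-by-one
arithmetic crosses the package boundary.

## What the generator does and does not emulate

The founder-mosaic model reproduces the features that drive the study's
main effects: intermediate allele frequencies, LD decaying with distance,
continental-scale allele-frequency divergence, admixture with gene-level
local ancestry, and architectures whose sharing fraction is controllable.
Two omissions matter when reading results:

* **Cross-population LD differences.** Both derived panels are mosaics of
  one ancestral panel with the *same* per-interval switch probabilities, so
  tagging structure is nearly identical across populations even at
  F_ST ≈ 0.14. Real CEU and YRI differ in LD block structure, which
  degrades cross-population weight transfer beyond what allele-frequency
  divergence alone predicts. Consequently the simulated admixture gradient
  of power (AD-trained models tested in an ancestral population as `alpha`
  moves away from that population) is directionally correct but flatter
  than with real panels, and cross-population power levels run somewhat
  high.
* **Genome realism.** Gene regions are disjoint site windows (no
  overlapping cis-windows, no variable SNP density), alleles are biallelic
  with no genotyping error or imputation uncertainty, and expression is
  Gaussian on the normalized scale with purely additive cis effects — no
  trans effects, dominance, or count-level noise.

Passing tests therefore certify the estimation machinery and the relative
geometry of the scenarios (within- versus cross-population, sharing and
admixture trends, heritability ceilings), not the absolute transferability
of any real human predictor set.
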