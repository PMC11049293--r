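---
title: "Factorial analysis of isobaric-labelled proteomics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorial analysis of isobaric-labelled proteomics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtfactorial)
```

# The experiment this package models

`tmtfactorial` analyses a 2×2 factorial proteomics experiment in which two
genotypes (euploid and trisomic, as in the Ts65Dn mouse model of Down
syndrome) are crossed with two treatments (water and fluoxetine), with
four biological replicates per cell quantified together in one 16-channel
TMTpro run. The scientific question is *phenotypic rescue*: which proteins
are dysregulated in trisomic-water (TW) animals and restored toward the
euploid-water (EW) baseline by fluoxetine (TF)? Statistically, rescue is a
genotype-by-treatment interaction.

The pipeline runs in the order the data are produced:

1. **Reporter-ion processing** — isotope-impurity correction, iterative
   median normalization, log transform, pruning of multi-protein spectra,
   intensity weighting, weighted-median rollup to protein quantities.
2. **Protein-level modeling** — missing-value filter, per-protein two-way
   ANOVA with interaction, pairwise contrasts, π-score ranking,
   permutation differential expression with Benjamini–Hochberg control.
3. **Multivariate analysis** — NIPALS PCA, per-component design ANOVA,
   randomization-based FDR for the component–design associations.
4. **Enrichment and display** — preranked GSEA with normalized enrichment
   scores, correlation/Ward.D2 clustering of interaction proteins, plot
   data for score plots, heatmaps and boxplots.

A synthetic-data generator with known ground truth drives all calibration
and recovery tests.

# Models and their assumptions

## Impurity correction

Each isobaric label leaks a lot-specific fraction of its reporter signal
into the channels at −2/−1/+1/+2 positions. Collecting these fractions
into a purity matrix $P$ (columns = true channel, rows = observed
channel), the observed intensities per spectrum are $y = P x$, and the
correction solves $P x = y$ for the true signal $x$ — the standard linear
inverse used since i-Tracker-style algorithms. Negative solutions, which
can occur with noisy data, are clamped to zero and counted. The purity
matrix must be full rank; column sums may be below one (signal lost
outside the plex). `synthetic_impurities()` ships plausible but entirely
synthetic percentages, since vendor lot certificates are not
redistributable.

## Iterative median normalization

Sample loading and labelling efficiency shift whole channels; spectrum
ionization shifts whole rows. Both are removed in the log2 domain by
alternately subtracting per-sample and per-spectrum median offsets
(relative to the median of medians, so the overall scale is kept) until
the largest adjustment falls below `tol` (default 1e-8, cap 500
iterations). At convergence all sample medians agree and all spectrum
medians agree. The iteration is an alternating median polish; it
typically needs on the order of a hundred passes on realistic tables,
which is why the cap is set well above it. The operation is idempotent up
to the tolerance.

## Rollup and weighting

Protein quantities are weighted medians of the protein's spectrum-level
log2 values per sample. The weighted median takes the smallest value
whose cumulative weight reaches half the total, resolving ties toward the
lower value. Commercial software uses an undisclosed "adaptive intensity
weighting"; the package's default weight
$w = I_\mathrm{tot}/(I_\mathrm{tot} + c)$, with $c$ the 10th percentile
of total spectrum intensities, is a documented stand-in that
down-weights low-intensity (noisier) spectra, is monotone in total
intensity, and is pluggable via `weight_fun`.

## Per-protein factorial ANOVA

For each protein the model is
$y = \mu + \alpha_\mathrm{genotype} + \beta_\mathrm{treatment} +
(\alpha\beta) + \varepsilon$ on log2 quantities. For complete balanced
rows the three ±1 contrast columns are orthogonal, so all sum-of-squares
types coincide and the fit is computed in closed form, vectorised across
proteins. Rows with missing cells (allowed through the ≤1-missing filter)
are fitted by least squares with type-II sums of squares, provided every
cell keeps at least two observations; otherwise the protein is flagged
`inestimable` rather than imputed. Zero-variance rows get p = 1 and a
flag. BH q-values are computed across proteins separately within each
effect family (genotype, treatment, interaction) — the family choice is a
design decision, since nothing forces the three effect types into one
family.

Interaction selection uses the nominal rule p < 0.05 with *strict*
inequality.

## Contrasts from summary statistics and the π score

`group_contrast()` computes a pooled two-sample t-test directly from
group means, SEMs and sizes: $SE = \sqrt{SEM_a^2 + SEM_b^2}$, df = 2n−2
for equal n (Welch–Satterthwaite otherwise). This reproduces published
contrasts exactly when the published ± values are SEMs with n = 4: the
worked TW-vs-TF examples for AP2A1 (p = 0.001) and CLTA (p = 0.0002) in
the study this pipeline re-implements check out at their printed
precision, which is itself evidence for the SEM reading. One printed
value in that study (EXOC8, p = 0.0593) is not consistent with any
standard t-test on its printed summaries; the package implements the
standard test and leaves such discrepancies to the reader.

The π score combines effect size and significance:
$\pi = \log_2\mathrm{FC} \times (-\log_{10} p)$. Its sign follows the
fold change; it is zero iff p = 1 or FC = 0; p = 0 is rejected (callers
use add-one permutation p-values or a floor). Note that some published π
values (e.g. −222.23 for FMR1) are not reproducible from this formula
with any printed p/FC pair of the same study; the package implements the
formula as stated and makes no attempt to reverse-engineer those entries.

## Permutation differential expression

The two-group statistic is the difference of group means. With 4 vs 4
samples all $\binom{8}{4} = 70$ label splits are enumerated, giving exact
p-values on the grid k/70 with two-sided minimum 2/70; enumeration is
used whenever the split count is ≤ 20,000, otherwise 10,000 Monte-Carlo
draws with the add-one convention (so p is never zero). BH across
proteins controls the FDR.

## NIPALS PCA and the randomization FDR

Samples are observations, proteins variables; each protein is
mean-centered with no unit-variance scaling (the conventional default for
log-scale omics PCA). Components are extracted by NIPALS, which handles
missing cells by restricting each regression to observed entries;
initialization is deterministic (the residual column of maximal
variance), tolerance 1e-9, at most 500 iterations per component. On
complete data the result matches the SVD up to component sign. Seven
components are retained by default, mirroring the common
~three-quarters-of-variance working dimension of such designs; a
cumulative-variance target can be used instead by inspecting
`tidy(pc_model)`.

Each component's scores are tested against the design by the same
two-way ANOVA. The randomization FDR permutes the sample labels
(columns), re-runs PCA + ANOVA `n_rand` times, and estimates
FDR = mean null count / observed discovery count. Discoveries are
component–effect pairs with p < α (default 0.05); the null count takes
pairs with p at or below the *largest observed discovery p-value*. The
second point matters: if the null were counted at α itself, the
estimator could never fall below $(21 \times α)/n_\mathrm{obs}$ for a
7-component model — about 0.26 with a handful of discoveries — whereas
counting at the observed significance level estimates how often chance
produces associations as strong as the ones actually seen, and correctly
approaches zero for strong structure. On pure noise the estimator either
reports no discoveries or attaches a high FDR to the chance exceedances
(a single chance discovery at p ≈ 0.01 among 21 tests is reported with
FDR ≈ 0.2, exactly the multiplicity arithmetic). A cell-wise shuffle
scheme is available behind `scheme = "cells"` for users who read
"randomizing the data matrix" that way; label permutation is the default
because it preserves the protein covariance structure.

## Preranked GSEA

Proteins are ranked either by a principal component's loadings or by the
signed significance metric $-\log_{10}(p) \times \log_2\mathrm{FC}$ of a
contrast, descending, with ties broken by protein identifier so results
are reproducible. The enrichment score is the classic weighted
Kolmogorov–Smirnov running sum (weight exponent 1 by default; 0 gives
the unweighted KS): hits add $|m|^w$ normalized over the set's hits,
misses subtract $1/(N - N_\mathrm{hits})$, and ES is the maximum signed
deviation, with |max|-ties resolved to the earliest extremum along the
walk. The null is gene-label permutation (random sets of matched size),
appropriate because a loading- or statistic-based ranking has no
per-sample replicates to permute. NES divides ES by the mean |null ES|
of the same sign; p is the add-one same-sign tail fraction; BH runs
across all tested sets. Sets with fewer than 5 members in the universe
are skipped and reported.

Two practical floors follow from the permutation scheme and matter when
choosing `n_perm` and collection size: with the add-one convention the
smallest attainable p is about $2/n_\mathrm{perm}$ (only same-sign nulls
count), and BH multiplies the best p by the number of tested sets. A
planted set in a 20-set collection therefore needs ≥ 1000 permutations
to be able to reach q < 0.05 at all.

## Clustering of interaction proteins

Interaction-selected proteins are standard-scaled per protein (mean
zero, variance one, *population* divide-by-n variance — the scaled rows
then have exactly unit sum of squares over n), and clustered with
distance $d = 1 - r$ (Pearson, pairwise-complete) under Ward.D2
agglomeration (squared-dissimilarity Lance–Williams update, square-root
heights), whose merge heights are monotone. The tree is cut at its first
branch; "cut1" is oriented to the cluster whose scaled TF mean minus TW
mean is negative — proteins lower under trisomic-fluoxetine — matching
the conventional display of rescue heatmaps. Sample columns stay in
design order (samples are not clustered). Boxplot summaries use type-7
(linear-interpolation) quantiles.

# The synthetic-data generator

`simulate_experiment()` emulates the statistics of the study design, not
its chemistry or chromatography. Per protein: a uniform baseline in
[8, 14] log2 units (published log2 quantities of such data sit around
8–13); i.i.d. Gaussian residual noise in log2 (log-normal intensities),
default σ = 0.25; a configurable fraction of proteins carrying a
"rescue" interaction of 1.0 log2 unit, split evenly between
down-in-TW/restored-by-TF and up-in-TW/suppressed-by-TF patterns;
separate fractions with genotype- or treatment-only main effects of 0.5
log2 units. Defaults: 2554 proteins, 4 per cell, 5% interaction
proteins, 5% per-cell missingness. The missingness default was chosen so
that the ≤1-missing filter retains roughly 81% of proteins — the scale
of the study's 2066-of-2554 retention; missingness is
missing-completely-at-random by default with an intensity-dependent
(logistic-in-abundance) MNAR option, since real data give no mechanism.

The spectrum layer generates 1 + Poisson(3) spectra per protein with a
N(0, 0.5) per-spectrum ionization offset and N(0, 0.1) measurement noise
around the protein's per-sample log2 value, so the per-protein median
per sample recovers the matrix entry up to noise; a configurable
fraction of spectra is additionally assigned to a second protein to
exercise the pruning step. Ground truth records every planted effect,
with flags derived from the realized cell-mean pattern so they are
consistent by construction.

What the generator does *not* emulate — peptide sequences, isotope
envelopes, co-isolation interference beyond the linear impurity model,
correlated (batch-like) noise, protein-inference ambiguity beyond random
spectrum sharing — bounds what passing tests show: the pipeline is
correct and calibrated for the assumed error model, which is not proof
of robustness to every pathology of real spectra.

`simulate_gene_sets()` plants enrichment by oversampling proteins with a
chosen truth flag (default 90% of the set). For signed rankings the flag
should be direction-specific (`interaction_down_true` /
`interaction_up_true`): the two rescue directions sit at opposite ends
of a signed metric, so a set mixing both directions is *not* enriched in
rank space and deliberately cannot be recovered.

# Parameters at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| `effect_size_log2` | 1.0 | log2 | a two-fold interaction, detectable but not trivial at n = 4 |
| `sigma_log2` | 0.25 | log2 | typical between-replicate spread of TMT protein quantities |
| `missing_rate` | 0.05 | probability | ~81% retention under the ≤1-missing filter |
| `max_missing` | 1 | cells | "not quantified in more than one sample" filter rule |
| interaction α | 0.05 | — | nominal selection threshold, strict inequality |
| `n_components` | 7 | — | working dimension for the design-association scan |
| PCA `tol` | 1e-9 | score units | NIPALS convergence, deterministic init |
| normalization `tol` | 1e-8 | log2 | alternating median polish stopping rule |
| GSEA `weight_exponent` | 1 | — | classic weighted KS |
| GSEA `n_perm` | 1000 | — | p floor ≈ 2/n_perm; needed for q < 0.05 over ~20 sets |
| GSEA `min_size` | 5 | proteins | smaller sets have too little rank signal |
| DE exhaustive cap | 20,000 | splits | enumerate exactly when feasible, else 10,000 draws |

# Problem sizes used by the tests

The calibration and recovery checks run at sizes chosen to make their
statistical assertions sharp while keeping the suite quick: 2000
proteins for null calibration and parameter recovery (50 replicates),
500 proteins × 200 randomizations for the PCA FDR, 1000 proteins ×
20 sets × 1000 permutations for enrichment recovery, and 60 proteins ×
50 replicates for clustering recovery. The exhaustive enrichment-score
oracle covers every gene set in every universe of up to 10 proteins.

# Known limitations

* The intensity weighting function and the permutation count of the
  original commercial pipeline are not public; the package's choices are
  documented stand-ins and results will differ in detail.
* Quantities that depend on the deposited study data — the exact 2554 /
  2066 / 106 protein counts, the ~76% seven-component variance, named
  Reactome pathways and their NES — are documented reference points, not
  reproduced outputs; the synthetic generator reproduces their *scale*
  only.
* No empirical-Bayes variance moderation: per-protein plain ANOVA is by
  design (matching the modeled workflow), at some power cost at n = 4.
* NIPALS with missing data loses exact score orthogonality; with ≤ ~6%
  missingness (the default regime) the deviation is negligible.
* GSEA uses gene-label permutation; sample-permutation nulls, which
  preserve gene–gene correlation, are not applicable to loading-based
  rankings and are not implemented.
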