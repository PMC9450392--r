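---
title: "Models and methods behind hdomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hdomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdomics)
```

`hdomics` re-implements, as small composable functions, the bespoke
computational procedures used in peripheral-tissue multi-omics studies of
Huntington disease: TMT 10plex reporter processing, sample quality
control, imputation and covariate removal, a reproducibility-optimized
differential-abundance test, and *HTT* haplotype construction. This
vignette explains the models, the defaults and the numerical choices, and
what the synthetic-data generators do and do not emulate.

## Cohort model

Disease burden is the cumulative exposure index
DBS = (CAG − 35.5) × age, defined only for carriers of an expanded CAG
tract; 35.5 is the repeat length at which the index is zero, so DBS grows
linearly in both the expansion size and age. Staging uses two UHDRS
instruments: carriers before clinical diagnosis (diagnostic confidence
level ≤ 2) are pre-HD; diagnosed carriers in total-functional-capacity
stages 1–2 (TFC 7–13) are early-HD. A diagnosed carrier with TFC below 7
is outside these strata and is reported as `unclassified` rather than
silently forced into a group.

## TMT 10plex processing

The chain runs strictly in the order *filter → impurity correction →
sum-scaling → reference ratios → peptide collapse → protein
aggregation*; each stage returns the same row identity it received, so
the stages compose without renaming.

**Impurity correction.** Each TMT lot ships a 10×10 matrix $M$ whose
column $j$ gives the fraction of channel $j$'s true signal observed in
every channel. Correction solves $M x = y$ per PSM exactly rather than by
sequential subtraction: the inversion is well defined, and the round trip
$M \hat x \approx y$ is testable to machine precision. When channels are
missing, the system is restricted to the present channels' sub-matrix —
the cross-leakage from unobserved channels cannot be estimated from a
single PSM, and the sub-system is the least-assumption choice. Small
negative solutions (possible when noise pushes an observed value below
its leaked-in share) are clamped to zero. Matrices with a 2-norm
condition number above 1e8 are rejected with the lot named, since the
solution would amplify noise unboundedly.

**Sum-scaling.** Channel sums $S_c$ are computed over present values and
every intensity in channel $c$ is multiplied by $\mathrm{median}(S)/S_c$,
so that all channel totals equal the median total afterwards — the
equalization that "sum-scaling" is meant to achieve. A common printed
description of this procedure divides in the other direction
(factor $S_c/\mathrm{median}(S)$), which would amplify already-large
channels; we treat that as a transcription slip but expose it as
`direction = "literal"` rather than deciding silently.

**Reference ratios and identifiability.** Log2 ratios are taken to a
designated reference channel; the pooled reference is conventionally the
last channel (131), and the position is configurable because naming
conventions differ between facilities. A ratio against a missing or zero
reference is reported missing, never ±Inf. Note one identifiability
limit: sum-scaling rescales each channel by a run-level constant, so
per-feature group differences of log-ratios carry a common channel-level
offset. The offset is identical for every feature, so analyses of
differences between features — and the package's exact-recovery checks,
which median-center the per-feature effect estimates — are unaffected.

**Collapse rules.** Shared peptides (non-unique gene mapping) are removed
first, then rows with no protein ID; each peptide keeps its
maximum-row-mean PSM, ties resolved by input order so the operation is
deterministic. Protein aggregation reuses the same representative rule;
aggregation method is genuinely unspecified territory, and max-mean keeps
peptide and protein levels consistent with each other.

## Sample quality control

The control charts track two robust per-sample metrics, median and IQR,
and flag a sample when either lies more than 3 SD from the across-sample
mean of that metric. A zero-variance metric raises no flags (every sample
would be at the mean).

The expression outlier detector is deliberately a conjunction of two
weak criteria: (i) the sample's (PC1, PC2) score falls outside the 68%
probability ellipse of a bivariate normal fitted to all scores (boundary
at the χ²(2 df) quantile of the Mahalanobis distance), and (ii) its
standardized connectivity — minus the mean Euclidean distance to all
other samples, standardized to mean 0 / SD 1 — is below −2.5. On
homogeneous data roughly a third of samples fall outside a 68% ellipse,
so the ellipse alone would flag constantly; conversely the connectivity
Z is below −2.5 only for samples far from everyone. The conjunction
keeps the false-flag rate below 1% of samples while planted 10-σ shifts
are always caught. PCA uses samples as observations with centered,
unscaled features; two components are used because the ellipse is a
planar construct. Both the ellipse probability and the Z cutoff are
arguments. The detector is matrix-agnostic: per-tissue or per-batch
stratification is left to the caller.

The prevalence filter keeps a feature when at least one group of at
least one requested comparison has a nonzero count in ≥ 9 samples
(half of a 17–21-sample group); it is monotone in the threshold.
Continuous covariates (age, BMI) are factorized into 5 equal-width
intervals with the range widened by 0.1% at the edges — the convention
of base R's `cut` — because downstream count models treat them as
factors.

## Imputation and normalization

**Iterative PCA.** Missing cells start at column means; we then iterate
"fit a rank-r truncated SVD to the column-centered completed matrix,
replace the missing cells with fitted values" until the maximum relative
change of the imputed cells drops below 1e-6 (cap 1000 iterations, with
a warning on non-convergence). Observed cells are never altered. The
iteration is plain truncated SVD without ridge regularization; the
low-rank-plus-noise regime it targets is checked by test, where it beats
column-mean imputation in ≥ 95% of replicates. The rank is the one free
parameter: when not supplied, 5% of observed cells are masked and the
rank in 1…10 minimizing reconstruction RMSE on the mask is chosen.

**Quantile normalization** equalizes column distributions to the
across-column mean of sorted values (ties share averaged reference
quantiles), via `limma::normalizeQuantiles`. It requires a complete
matrix — run it after imputation — and preserves within-column rank
order and the total mean.

**Covariate removal** fits, per feature, a least-squares model with
protected terms (disease stage) plus nuisance terms (plex set, site,
gender, age, BMI) and subtracts only the fitted nuisance contribution
(`limma::removeBatchEffect` is the engine). The default is a single
joint model: joint least squares is order-invariant and removes each
nuisance effect exactly in the noiseless case, and re-applying it is a
no-op (idempotence is tested to 1e-10). A `sequential` mode removing one
covariate at a time in the listed order is provided for fidelity to
pipelines that consecutively removed batch effects; with orthogonal
designs the two coincide. Designs are checked for aliasing by QR rank
and rejected with the confounded term named — removing a nuisance factor
confounded with the protected factor would silently delete the biology.
Numeric covariates enter linearly by default, or factorized into 5
intervals via `factorize =` to mirror the count-model convention.

## The reproducibility-optimized test

For a two-group comparison the statistic family is
$d_g = |m_{1g} - m_{2g}| / (\alpha_1 + \alpha_2 s_g)$ with $s_g$ the
Welch-style standard error of the mean difference. The family spans the
plain mean difference (α = (1, 0)), the t statistic (α = (0, 1)) and
regularized compromises in between; the default α₁ grid is
{0, 0.01, 0.05, 0.1, 0.25, 0.5, 1, 2, 5} with α₂ = 1, plus the (1, 0)
member. Top-list sizes follow the ladder 10, 25, 50, 100, 250, 500, …
capped at the feature count.

Selection works by bootstrap reproducibility: B pairs of datasets are
resampled with replacement within groups; for each pair and each grid
point, features are ranked by $d$ and the fractional overlap of the two
top-k lists recorded, giving $R_k$. The same scheme on group-label
permuted data gives the null overlap $R^0_k$ and its spread, and the
grid point maximizing $Z_k = (R_k - R^0_k)/\mathrm{sd}(R^0_k)$ is
selected. Ties break toward smaller k, then smaller α₂, then smaller α₁
— preferring the shorter list and the simpler statistic. The k = p rung
always has overlap 1 in both observed and null curves, so its null sd is
0 and it is skipped with a warning; this is expected, not an error. B
defaults to 1000; the test suite and examples use B = 200, which
resolves Z well at the simulated problem sizes (1000 features, 10 vs 10
samples).

Inference is permutation-based with the selected statistic: the p-value
of feature $g$ is the add-one-smoothed fraction of pooled null
statistics ≥ $d_g$; the FDR at $d_g$ averages, over permutations, the
null exceedance count divided by the observed rank, and is then enforced
monotone (non-increasing in $d$) and capped at 1. Null simulations show
≤ 1% of features at FDR < 0.05 and Z < 2; the planted regime (10% of
features at 3σ) gives Z > 2 with power ≥ 80% — the qualitative regime
in which a comparison is considered to carry reproducible signal.
Missing values are handled by pairwise-complete means and SEs as a
safety net (proteomics matrices are imputed upstream); a feature with
fewer than two observations in a group gets a missing statistic.
Permutations can be constrained within strata, but the default is
unconstrained since nuisance covariates are removed before testing.
Everything — bootstraps, permutations, k-means restarts — is a pure
function of the supplied seed.

## HTT haplotyping

Haplotypes are the ordered alleles at 21 defining variants (20 SNPs plus
the rs149109767 indel), coded 0 = reference / 1 = alternate. Construction
tabulates distinct allele vectors among phased chromosomes; chromosomes
with any missing call are excluded and counted, since a haplotype's
identity requires all loci. Naming preserves a reserved list (hap.1 …
hap.16 in the original nomenclature) by exact vector match regardless of
panel frequency, then assigns hap.17, hap.18, … to the remaining vectors
by descending frequency, with frequency ties broken lexicographically on
the allele string so that names never depend on input order. The
reserved table is an input file — the package ships a synthetic
placeholder illustrating the schema, not the published definitions — so
the tool is generic over any variant set and reserved list.

Distances between haplotypes are binary (Jaccard-style): disagreeing
loci over the union of alternate-allele loci, with 1 coding the
alternate allele; this asymmetric choice matters (its complement would
weight shared reference alleles as similarity) and is the conventional
reading of "binary distance". The all-zero pair is at distance 0 by
convention. Dendrograms use Ward's linkage on this distance; flat labels
come from k-means (k = 3 by default, 100 seeded restarts) on the binary
vectors. Normal and mutant haplotypes can be clustered separately; which
phase carries the expansion is accepted as input metadata
(`mutant_flag`), since phase-to-expansion assignment is an upstream
question the 21-variant data cannot answer alone.

## Synthetic data: what it emulates, and what it does not

The generators exist so every stage is testable without the
access-controlled cohort data, and their defaults encode the study
conditions: groups of roughly 20/21/20 participants, carriers with the
expanded allele in 40–55 repeats, ages 30–50, two sites, TMT 10plexes
with 9 sample channels and a pooled reference in channel 10. PSM base
abundances are log2-normal (mean 20, SD 2 on the log2 scale), matching
the dynamic range of reporter intensities; group effects, per-plex
shifts and Gaussian log2 noise are additive on the log2 scale, then the
impurity matrix mixes channels and cells are thinned
missing-completely-at-random. Effect sizes are free parameters — no
published effect-size distribution exists to calibrate against — and an
intensity-dependent (left-censored) missingness mode is deliberately not
the default because MCAR keeps the recovery oracles exact. The PSM
scaffold (4 PSMs per protein, 2 peptides) is identical across plexes so
noiseless recovery is exact rather than approximate.

What passing tests therefore show: the algorithms implement their
definitions correctly, with correct error control and power at the
simulated sizes. What they do not show: robustness to
intensity-dependent missingness, heavy-tailed reporter noise,
correlated features, population structure in haplotypes, or any other
real-data pathology the generators do not model.

## Problem sizes and determinism

The shipped checks run at desk scale by design: 100 random tables for
normalization conservation, 1000 PSMs for the impurity round trip, 50
replicates of 500 × 20 matrices for the outlier detector, 50 imputation
replicates, 100 covariate-removal replicates, 1000-feature / 10-vs-10
comparisons with B = 200 for the reproducibility test, and
10000-chromosome panels for haplotype frequency recovery. Every
simulation is seeded, and the acceptance script derives all its
substreams from a single `--seed`.

Known limitations: no moderated-variance (empirical Bayes) alternative
to the reproducibility test; no multi-group statistic; quantile
normalization assumes comparable distributions across sets; the
iterative-PCA rank search assumes an approximately low-rank signal; the
haplotype tools do no phasing and no CAG sizing.
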