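---
title: "Process-level ageing signatures, disease alignment and risk-SNP antagonism: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-level ageing signatures, disease alignment and risk-SNP antagonism: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`agealign` implements a process-level analysis of transcriptomic ageing
across species and its two companion analyses: the alignment of ageing
signatures with disease expression signatures, and the classification
of genomic risk variants shared between disease categories. The
pipeline runs in five stages:

1. expression preprocessing (RPKM, removal of genes without detectable
   expression);
2. mapping of expression onto gene-set ("process") activities with a
   quantile + rank normalization cascade;
3. detection of age-regulated processes by unbalanced type-II ANOVA
   with assumption filtering, marginality-respecting backward selection,
   BH-FDR and a cross-clade conservation rule;
4. ageing-mediated disease alignment (AMDA) scores against disease
   case/control foldchange signatures, with Wilcoxon significance,
   label-swap randomization, per-process disease alignment contribution
   (DAC) scores and a classical MDS co-embedding;
5. shared risk-SNP analysis: synergistic/antagonistic classification of
   variants shared between disease categories, independent-locus
   counting, and exact binomial plus randomization bias tests.

A first-class synthetic-data module generates inputs with the
statistical structure every stage assumes, together with a serialized
ground truth, so that the full pipeline is testable without downloads.
The numbered drivers under `analysis/` run the whole workflow on a
simulated study and write their tables under `results/`.

# Process activities and normalization

The activity of a process in a sample is the **sum** of the expression
values (RPKM) of its measured genes. Processes are first filtered to
those annotated with at least `min_genes = 5` measured genes in every
species x tissue stratum; a gene counts as measured when its value is
positive in all samples of the stratum.

Normalization is a two-step cascade:

* **Quantile normalization** across all samples jointly: each sample's
  sorted activity vector is replaced by the across-sample mean of
  sorted vectors, making every sample's value distribution identical.
  Ties within a sample keep input order, which makes the step
  deterministic.
* **Rank scaling** per species x tissue stratum: within each stratum,
  each process's values are replaced by average ranks scaled to a
  minimum of 0 and a maximum of 1, i.e. `(r - min r) / (max r - min r)`.
  Without ties this equals `(rank - 1) / (n - 1)`; with ties the
  extremes are still attained, so every informative stratum spans
  exactly [0, 1]. A process that is constant within a stratum has no
  ranks to scale and maps to 0.5. Ties are common after quantile
  normalization (two samples in which a process occupies the same
  within-sample rank receive identical values), so the tie behaviour is
  part of the contract, not an edge case.

Summing and averaging gene expression give identical final matrices
whenever all sets have the same size, because a common per-process
rescaling leaves within-sample ranks — and therefore the quantile step —
untouched. With unequal set sizes the two agree only approximately (the
quantile step is not invariant under per-process rescaling); the test
suite asserts the exact case and we treat the general statement as an
approximation.

# Detecting age-regulated processes

## Model and response scale

For each process we fit a fixed-effects factorial model with factors
age group (young, old_1, old_2 by default), species and tissue,
including all interactions up to three-way, and evaluate terms with
**type-II sums of squares**: the SS of a term is its reduction in
residual SS given all terms that do not contain it, with the F built on
the full model's residual mean square. On balanced designs this
coincides with the classical SS decomposition (asserted against an
explicit oracle to 1e-9), and on unbalanced designs it reproduces
`car::Anova(type = 2)` (asserted to 1e-10). The in-package
implementation exists because the ANOVA runs once per process per
permutation replicate: all processes share one design, so QR
factorizations of every sub-model are computed once per design and
reused, which makes hundreds of backward-selection fits per study take
seconds.

The ANOVA response is the **quantile-normalized** activity, while
foldchanges are taken on the **rank-scaled** values. Running the ANOVA
on the rank scale itself is not viable: per-stratum rank scaling turns
every process's values into a uniform grid, whose residuals fail any
normality test at realistic sample sizes, which would empty the
pipeline at the assumption-filter stage. The rank scale is the right
place for effect sizes (bounded, comparable across strata); the
quantile scale is the right place for residual-based inference.

## Assumption filter

Before fitting, each process must pass two checks on the full model at
`alpha = 0.005`: Shapiro–Wilk normality of residuals, and Levene's test
(median-centered, as in `car::leveneTest`) of variance homogeneity
across design cells. The deliberately stringent threshold discards only
clear violations; processes with numerically zero residual variance are
discarded as degenerate. Failing processes take no further part in the
analysis.

## Backward selection

Model reduction removes one term per iteration: among terms not
contained in any retained higher-order term, the one with the largest
type-II p-value is removed while that p-value exceeds 0.05, with ties
broken toward higher interaction order and then term name. Inestimable
terms (no added rank, e.g. from empty cells) are dropped first with a
note. Reduction stops when nothing admissible remains above the
threshold, or when the age main effect itself is the candidate — in
that case the process is reported with the age term removed and enters
the FDR family with p = 1 (keeping the family equal to all
assumption-passing processes; this is conservative).

## Signature membership

The reported p-value per process is the age main effect's from the
final model; BH-FDR is applied across processes within the ontology. A
process joins the ageing signature when its adjusted p is at most 0.05
(configurable) **and** its direction of regulation — the sign of the
foldchange, defined as mean rank-scaled activity of the pooled old
groups minus young — agrees with the overall direction in at least one
fish and at least one mammal. Per-species directions come from the
stratified data (per-species foldchanges); the rule requires agreement
of direction, not per-species significance, which matches the
stratified analyses being reported alongside rather than gating the
joint one.

The age-label permutation null re-runs this entire cascade (assumption
filter included) with age labels shuffled within species x tissue
strata, and records the signature size per replicate; on null data its
median is 0.

## Gene-level differential expression

Ageing-induced (U) and ageing-repressed (R) gene sets are derived per
study by a two-sided Wilcoxon rank-sum test of young vs pooled old
samples per gene with BH-FDR at 0.05, split by the sign of the log2
ratio of group medians. A rank-based test was chosen as the package's
gene-level method for the same reason the disease normalization is
rank-based: it is distribution-free and invariant to monotone
transforms of the expression scale. Constant genes receive p = 1 by
convention.

## Lifespan correlations

For longitudinal designs (two samples per individual), the per-process
association with lifespan is the Pearson correlation between each
individual's activity change (later minus earlier time point, on the
normalized scale) and that individual's lifespan. A lifespan
association could in principle be carried by the activity level or by
its change; we correlate the change, which is the quantity the
longitudinal design actually measures per individual, and flag
zero-variance processes as undefined.

# Disease alignment

## Normalized disease foldchanges

Disease signatures are per-gene case-vs-control foldchanges. They are
rank-transformed over the data set (average ranks for ties) and mapped
linearly onto [-1, +1]: `norm = 2 (rank - 1)/(N - 1) - 1`. This is the
unique bounded, distribution-free normalization that reproduces the
AMDA score's theoretical range of +/-2 below; it is invariant under any
strictly monotone transform of the raw foldchanges. An all-constant
signature normalizes to zeros with a warning.

## AMDA

The ageing-mediated disease alignment score of an (ageing, disease)
pair is

> AMDA = mean(norm. foldchange over ageing-induced genes) −
> mean(norm. foldchange over ageing-repressed genes),

restricted to genes measured in the disease data set, after removing
genes appearing on both sides (logged) and any excluded gene sets (the
exclusion hook supports sensitivity analyses such as removing
senescence or proliferation genes). With normalized values in [-1, +1]
the score is bounded by [-2, +2], attained exactly when every induced
gene sits at +1 and every repressed gene at -1; positive scores mean
ageing shifts the transcriptome toward the disease signature, negative
scores away from it. Significance per pair is a two-sided Wilcoxon
rank-sum test between the two sides' normalized foldchanges, with
BH-FDR across all pairs tested together and a 0.05 threshold on the
adjusted p. Pairs with fewer than two genes on either side are flagged
rather than tested.

The swap randomization destroys the U/R split while keeping everything
else: per replicate the induced/repressed labels are reshuffled over
U + R (set sizes preserved) and the full significance analysis is
recomputed. Because the shuffle makes the two sides exchangeable, the
per-pair p-values are exactly uniform under this null; replicates
therefore produce stray significant pairs at the nominal rate of the
test, and the meaningful summaries are the observed count, the median
replicate count and the empirical exceedance probability — not a strict
zero across replicates.

## DAC

The crude disease alignment contribution of a process to a disease
category sums, over all (ageing, disease) pairs of the category, the
shift in AMDA when the process's genes are removed. Normalization
divides by the number of pairs and scales to an absolute maximum of 1 —
by default within each category, optionally globally — giving a range
of [-1, +1]: +1 marks the process whose genes most strongly pull the
ageing signature toward the category, -1 the strongest pull away.
Processes sharing no genes with U + R contribute exactly 0; removals
that would empty a side skip that pair with a log message.

## MDS

Condition profiles (gene- or process-level foldchanges) are co-embedded
by classical (Torgerson) MDS of their Euclidean distances
(`stats::cmdscale`); variance explained per axis is its eigenvalue over
the sum of positive eigenvalues. Fewer positive eigenvalues than
requested axes yields the available axes with a warning.

# Shared risk-SNP analysis

Trait strings are assigned to disease categories (cancer, CVD, NDD,
T2D) by case-insensitive substring keywords; traits matching no
category form the non-ageing background pool, and multi-category
traits join every matching set. Two risk SNPs are **shared** between
two sets when they are the same rsID, or when an LD-table entry links
them with r-squared at or above 0.8 (configurable; the threshold for
"strong linkage disequilibrium" is a parameter, not a claim). LD
entries carry an explicit allele phase map — which allele of one SNP
travels with which allele of the other — because classification is
meaningless without phase and inferring it from frequencies would be
non-deterministic.

A shared pair is **synergistic** when the same allele (after mapping
through the phase for LD pairs) is the risk allele in both sets, and
**antagonistic** when one set's risk allele is the other's alternative
allele; unmappable alleles are left unclassified. Classification is
symmetric in the pair order. Independent loci are connected components
of the graph joining shared SNPs with r-squared >= 0.5 or within 1 Mb
on the same chromosome (both thresholds configurable and stated
explicitly, since no single convention for locus independence is
universal).

Antagonism bias is tested two ways: an exact binomial upper tail
P(X >= k | n, p0) with p0 the antagonistic fraction among background
shared SNPs, and a randomization null that replaces one category by
equally sized draws (without replacement) from the non-ageing pool,
10,000 times by default, with the add-one empirical p
`(1 + #{reps >= observed}) / (n_reps + 1)` so that reported p-values
are never exactly zero.

# The synthetic-data generators

`generate_expression_study()` emulates the cross-species study design:
4 pseudo-species (two labeled as fish, two as mammals, so the
conservation rule is exercised literally) x 4 tissues x 3 age groups x
6 samples per cell; 2000 genes in 200 processes, 20 of them planted as
age-regulated (half up, half down) with a monotone trend across age
groups, consistent in all species.

Design choices, made once:

* **Counts** are negative binomial with dispersion 0.1 (a standard bulk
  RNA-seq noise model at moderate depth). Library sizes are the column
  sums of the simulated counts, so RPKM carries the real data's mild
  compositional coupling between planted trends and the remaining
  genes.
* **Gene means** are lognormal around 200 counts with sdlog 0.3, and
  gene sets hold ~30 genes (a private core of 10 plus genes borrowed
  from unregulated processes, overlapping as real ontology terms do).
  Within-set expression is deliberately homogeneous: process activity
  is meant to aggregate a set, not echo its single most-expressed gene.
  This keeps activity sums near normality, which is the regime the
  assumption-filtered ANOVA pipeline is designed for. Real expression
  spans a far wider dynamic range, and on real data the Shapiro/Levene
  filter removes a much larger share of processes — passing tests on
  this generator therefore demonstrate the pipeline's behaviour in its
  intended regime, not its yield on any particular real data set.
* **Effect calibration**: the `effect` parameter is the target
  old-minus-young shift of the mean rank-scaled activity (default 0.3).
  It is translated per process into a count-scale log-multiplier via a
  normal approximation of the two-sample rank statistic (solved with
  `uniroot`), using the process's analytic activity CV. The realized
  rank shift is mildly attenuated (of order 10-15%) by count skewness
  and the quantile step; the approximation is documented rather than
  corrected, since no downstream quantity depends on nominal-vs-realized
  effect.

`generate_disease_signature()` ties a disease to the ageing truth: per
gene, foldchange = c x (planted ageing direction) + Gaussian noise,
with c = +1 (aligned), -1 (reverted) or 0 (null) and noise sd 0.3 by
default — enough noise that alignment is statistical rather than
deterministic, while keeping planted signs recoverable.

`generate_snp_catalog()` builds 30 loci of 1-5 SNPs (within-locus
r-squared >= 0.9 with consistent phase maps; loci separated by >= 30 Mb
or chromosomes, so locus counting is unambiguous at the default
clustering thresholds). The first 12 loci each carry exactly one shared
cancer/degenerative pair — identical rsID or an LD partner — labeled
antagonistic for a planted fraction (default 0.9) of pairs. One pair
per shared locus keeps label recovery exact: additional cross-pairs
within a locus would be found by the sharing scan but were not planted.
A non-ageing pool (default 500 records, with 2% background rsID
sharing into the cancer set) feeds the background and randomization
analyses.

All generators are pure functions of their parameters and seed, and
each returns a truth object sufficient to score every downstream
result without re-reading the generated data.

# Numerical choices and degenerate inputs

* BH is used wherever FDR control is required; families are stated per
  use (processes per ontology; all AMDA pairs tested together).
* Average ranks for all tie handling; quantile-step ties resolved by
  input order.
* Rank scaling of an all-tied stratum returns 0.5; all-tied disease
  foldchanges normalize to 0 with a warning; constant genes get p = 1.
* Empirical p-values use the add-one correction.
* Every stochastic routine takes an explicit seed and is bit-stable
  under it.
* Zero/negative lengths or library sizes, alleles outside {A, C, G, T},
  risk = alternative allele, r-squared outside [0, 1] and malformed
  phase maps are input errors, not warnings.

# Problem sizes in the test suite

The suite exercises the default study conditions (20 of 200 regulated
processes, effect 0.3, n = 6 per cell) across 50 seeds for recall and
FDR, and 100-replicate permutation and swap nulls on reduced designs
(2 tissues, 100-1000 processes) chosen so the full suite completes in
minutes on one CPU; unit tests run on toy fixtures built in code.

# Known limitations

* The pipeline's yield on real data depends on how often real activity
  distributions survive the Shapiro/Levene filter; the generator's
  near-normal regime is the best case (see above).
* The AMDA/DAC formulas are this package's own construction, pinned
  down by the comparison structure (induced vs repressed genes, bounded
  normalized foldchanges) and validated against the theoretical range
  and its symmetries; other bounded normalizations would yield
  score variants on the same scale.
* The LD sharing threshold and locus clustering rule are parameters;
  results that depend on a specific GWAS catalog release or a specific
  reference LD panel are out of scope.
* Homolog mapping keeps one-to-one pairs only; many-to-many orthology
  is dropped with a logged count rather than resolved.
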