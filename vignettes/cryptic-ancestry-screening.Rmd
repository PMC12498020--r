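---
title: "Detecting cryptic ancestry on marginal principal components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cryptic ancestry on marginal principal components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptpc)
```

## The problem

Pairs of populations that absorbed the same dominant ancestry component —
early Germanic and early Slavic groups both carrying substantial Baltic
Bronze Age ancestry are the canonical case — can be indistinguishable on
the leading principal components of a genotype matrix, because PC1–2
capture the largest variance axes, which those populations share. The
differentiating signal, if present at all, lives in a *marginal*
component: a low-variance PC whose loading pattern is nearly orthogonal
to the main structure. `cryptpc` operationalizes a systematic screening
protocol for such signals: compute K = 20 components, flag population
extremes on every one of them, score every component's ability to
separate pre-declared groups, and search all C(K, 3) three-way
combinations for the best discriminating subspace. Downstream, distances
in that subspace feed gradient, clustering and MDS summaries, and a
simplified f4-based mixture model quantifies ancestry proportions.

## Data model and quality control

Genotypes are alternate-allele counts 0/1/2 with missing calls, read and
written in EIGENSTRAT (`.geno`/`.snp`/`.ind`) or PLINK `.traw` form.
Pseudo-haploid data — the common shape of low-coverage ancient DNA — is
simply a matrix whose calls are all 0/2; no special handling is needed
because every downstream computation treats calls as allele-count
estimates.

The QC cascade runs SNP filters before sample filters, in a fixed order:

| stage | default | note |
|---|---|---|
| MAF | keep MAF ≥ 0.01 | all-missing sites fail |
| Hardy–Weinberg | keep exact p > 1e-6 | probability-ordering two-sided test |
| SNP missingness | keep ≤ 0.80 | |
| LD pruning | r² > 0.25, 200-SNP windows, 50-SNP steps | pairwise-complete r² |
| sample coverage | ≥ 50,000 covered SNPs | |
| sample missingness | ≤ 0.80 | |
| sex check | warn only | metadata comparison; no X/Y data modelled |
| kinship | PI_HAT > 0.25 | method-of-moments IBD on the pruned set |

Two choices here were genuinely open. The stage *order* is fixed as above
because the kinship estimator needs an LD-pruned, QC-passing site set to
be trustworthy; kinship therefore runs last, and for each related pair
the lower-coverage member is dropped (ties break to the lexicographically
later sample id, for determinism). Second, the Hardy–Weinberg test is
computed on the pooled dataset even though population structure deflates
its p-values (Wahlund effect); with the permissive 1e-6 threshold it acts
as a genotyping-artefact screen, not a population-genetics test, and that
is the only use we endorse. LD r² uses pairwise-complete observations and
skips pairs with fewer than 20 shared calls, since ancient-DNA
missingness makes sparser estimates meaningless.

## PCA conventions

Standardization is the usual drift-variance scaling: per SNP, missing
calls are replaced by the site mean (hence contribute exactly zero after
centering), and values are scaled by `sqrt(p(1-p))` with the shrunk
frequency estimate `p = (1 + sum g) / (2 + 2n)`. Scores are the unit-norm
eigenvectors of the sample-covariance matrix — the convention of the
standard genotype-PCA tools — so absolute score magnitudes depend on the
sample set and are not comparable across datasets; all screening
statistics are computed on standardized scores for exactly that reason.
Eigenvector signs being arbitrary, every component is oriented so the
mean score of a sign-anchor population (default: alphabetically first) is
non-negative, which makes extreme-value reports reproducible.

All samples are co-fitted by default, matching a single-pass workflow.
Projection of held-out samples onto fitted axes is available behind
`project_samples()` (least-squares through the SNP weights, using each
sample's observed sites only, rescaled by the observed fraction); it is
deliberately not the default, because mixing fitted and projected samples
changes score scales in ways the screening statistics would then have to
model.

## The screening statistic

"Discrimination testing" needed a concrete definition. We use a
multi-group variance-ratio score on globally standardized scores:

> F(S) = [trace B(S) / (g − 1)] / [trace W(S) / (N − g)]

where B and W are the between- and within-group scatter matrices
restricted to the PC subset S. Traces make the score invariant to
rotations within the subset, standardization makes it invariant to
rescaling, and no tuning parameter is involved; a label-permutation null
(`permutation_null_scores()`) calibrates observed values. Populations
smaller than `min_group_n = 3` never drive selection (a singleton has no
within-group variance); they are reported separately. Extreme-value
flagging compares each population's mean to the global mean in units of
the global SD over *all* samples — not over population means — which is
robust to uneven population sizes. The exhaustive triple search evaluates
all C(20, 3) = 1,140 subsets; ties break to the lexicographically
smallest index tuple. A group whose within-variance is exactly zero gets
a variance floor of 1e-12, so point-mass groups rank above everything
without dividing by zero.

## Distances, clustering, embedding

Distances between samples are plain Euclidean distances in the selected
subspace, `d(i,j) = sqrt(sum_k (PC_ki − PC_kj)^2)` — by default the
screening-selected triple, since that is where the cryptic structure is
visible. Nearest-reference distance tables exclude a sample from its own
reference set (otherwise every reference sample would sit at zero), and
both per-sample and population-mean tables are emitted. Ward clustering
uses the squared-distance (ward.D2) update, whose objective matches
variance minimization in Euclidean space, and the metric embedding is
classical Torgerson MDS; both are delegated to the standard R
implementations and exported as Newick and TSV.

## The simplified admixture model

The target's allele-frequency vector is modelled as a convex combination
of the sources', `p_T = Σ α_s p_s`, `Σ α_s = 1`. With a pivot source S1
and pivot right population R1, the constraint is equivalent to the linear
f4 system

> f4(T, S1; R1, R_j) = Σ_{s≥2} α_s f4(S_s, S1; R1, R_j),  j = 2..r,

estimated by generalized least squares with the block-jackknife
covariance of the statistics as weight (blocks are 500 consecutive SNPs
by default; all statistics share one site mask — the intersection of
sites covered in every involved population — so one covariance describes
the whole vector). The weighting runs in two passes: a first GLS fit,
then re-weighting with the jackknife covariance of the *fitted residual*
statistic, which absorbs the noise in the source-side f4s. The fit
p-value is the chi-square tail of the weighted residual on r − k degrees
of freedom; the rank test for the number of ancestry streams uses the
same machinery on the full f4 matrix (alternating GLS for ranks ≥ 1).
Infeasible fits — any weight outside [0, 1] — are flagged and rejected in
model selection rather than truncated, which keeps the 2-to-5-source scan
(acceptance gate p > 0.05; fewest sources first, then highest p) crisp.
Confidence intervals come from a percentile block bootstrap (1,000
replicates by default) that resamples jackknife blocks with replacement
and refits under the original GLS weight.

This is a self-contained estimator of the qpAdm/qpWave type, built for
testability; it is not a port of AdmixTools, and numerical agreement with
that software on real data is not claimed. Estimates are invariant to
reordering of the right panel (an invertible linear transform of the
statistic vector, under which GLS is exact), a property the test suite
checks.

## What the simulator emulates — and what it does not

`simulate_scenario()` draws ancestral frequencies from Uniform(0.05,
0.95), drifts populations under the Balding–Nichols model (population
frequency ~ Beta with mean p and variance F·p(1−p), so F plays the role
of the Fst to the parent), mixes frequencies for admixed targets, and
samples diploid (or pseudo-haploid) calls binomially with uniform
missingness, 0.3 per call by default — a typical capture-panel rate for
ancient material. Admixture is frequency-level: no chromosomes are
painted and no recombination is modelled, which is sufficient for the
PCA- and f-statistic-level behaviour the package analyzes but means the
synthetic data carries *no LD structure*. Consequently the LD-pruning and
block-resampling machinery is exercised for correctness, not for its
statistical necessity, and passing tests say nothing about haplotype-scale
phenomena in real data. Missingness is uniform rather than
sample-correlated (real ancient samples have wildly uneven coverage), and
there is no reference bias, contamination or damage model.

One structural choice deserves emphasis: populations can drift from a
*parent* population, not only from the common ancestor. A pure star
topology makes every cross-population f4 vanish in expectation, leaving
the mixture system without information — so the built-in scenarios place
each source on its own internal branch, shared with a `_ref` population
that joins the right panel alongside two deeply drifted outgroups
(F = 0.35). The drift depths (branch 0.06, tips 0.03) give f4 signals
comfortably above jackknife noise at 20,000 SNPs without pushing
frequencies to the boundaries.

The named scenarios pin down the validation conditions: `gradient` steps
a Baltic-analogue proportion through 0, 0.25, 0.5, 0.75, 1; `three_wave`
builds three targets at Baltic fractions 0.55, 0.275 and 0.375 (midpoints
of the ranges characterizing three successive migration waves — an early
wave above 50%, a middle wave at 25–30%, a late one at 35–40%); and
`barbaricum5` mixes five balanced components at (0.218, 0.211, 0.205,
0.194, 0.172). The planted-signature scenario used to validate the
screening method shifts frequencies by δ = 0.3 at 2% of 20,000 SNPs in
one of two groups (n = 30 each) that otherwise share a 50/50 mixed
ancestry, on top of three diverged background clusters; the planted
component is identified post hoc as the PC most correlated with the true
group indicator, so "recovery" is judged against ground truth, never
against the method's own output. All randomness flows from one integer
seed through labelled substreams, so adding a stage cannot change
another stage's draws.

## Numerical choices and degenerate inputs

The Hardy–Weinberg p-value uses the probability-ordering convention with
a 1 + 1e-10 tolerance factor on the observed configuration's probability
(guarding against ties lost to floating point); it is exact against
enumeration for all tables with n ≤ 20. Monomorphic sites refuse to
standardize (the error tells the user to run QC). Jackknife covariance
matrices that turn out singular are ridge-regularized with a warning;
collinear sources are refused by name, including the case where a source
is statistically indistinguishable from the pivot source (an f4 column of
zeros). `classical_mds()` warns and truncates when the requested
dimensionality exceeds the number of positive eigenvalues. Fixed-size
SNP blocks (500) are the default because simulated data has no genetic
map; a map-based blocking can be layered on by passing matrices whose
`genetic_pos` is meaningful and choosing `block_size_snps` accordingly.

## Problem sizes used in validation

The test suite validates the full protocol at the study conditions —
20,000 SNPs, 30 samples per group, a four-population right panel, 30%
missingness, with 20 replicate seeds for the recovery claims and 100 for
the calibration claims (CI coverage, null rejection rate). Unit tests
use smaller draws (1,000–8,000 SNPs) where the property under test does
not depend on scale. `scripts/acceptance.R` re-runs the full-scale
computations from scratch and writes the resulting rates and errors as
JSON.

## Known limitations

* The screening statistic is deliberately simple; it will not detect
  group differences expressed purely in variance (not location) on any
  component.
* The admixture estimator assumes the sources in the model are the true
  proximal sources; like all qpAdm-type methods it estimates
  *proportions conditional on the model*, and the p-value gate is a
  goodness-of-fit screen, not proof of historical reality.
* Chi-square references for the fit and rank tests lean on the
  block-jackknife covariance; with few blocks (< ~20) the tests run
  anticonservative. The defaults (40 blocks at 20k SNPs) behave well in
  the calibration tests.
* PI_HAT uses the classical method-of-moments estimator with pooled
  allele frequencies; in strongly structured samples it overestimates
  relatedness across populations. Its role here is duplicate/first-degree
  screening, where that bias is harmless.
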