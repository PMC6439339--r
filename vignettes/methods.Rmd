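---
title: "Methods: population pharmacogenomics of admixed cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacogenomics of admixed cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistical methods it
implements, the assumptions behind them, and the numerical and design
choices made where the methods left room.

## The problem

Drug-response variants (pharmaSNPs) segregate at very different
frequencies across human populations, and those differences track genetic
ancestry. For populations where genotyping every patient is unaffordable,
the useful question becomes population-level: which pharmacogenomic
variants are common enough, and divergent enough between local
populations, that targeted testing for them has outsized public-health
value? The package answers that question with a chain of standard
population-genetic computations plus two purpose-built statistics: a
composite effect-allele divergence measure and a supervised ancestry
estimator. The motivating setting is two neighbouring admixed populations
with very different ancestry profiles — one mainly European with strong
Native American admixture, one mainly African — for which the package's
synthetic cohorts are calibrated.

## Allele-frequency statistics

**MAF.** Counted-allele frequency is `sum(dosage) / (2 n)` over
non-missing genotypes; MAF folds it to `min(f, 1-f)`. Variants with no
non-missing calls are flagged undefined rather than silently zeroed.

**Wright's F_ST.** Per variant, `F_ST = sigma^2 / (pbar (1 - pbar))` with
`pbar` the unweighted mean of per-population frequencies and `sigma^2`
their variance. Two conventions were genuinely open:

- *N vs N-1.* The variance divisor is not fixed by the formula's usual
  statement. We default to the population (divide-by-N) convention and
  expose `var_method = "sample"` for N-1. For two populations the choice
  scales F_ST by 2, so it matters for absolute values; every analytic case
  in the tests uses the divide-by-N convention.
- *Weighting.* Population sizes do not enter; each population counts once.
  Undefined variants (`pbar` of 0 or 1 — monomorphic everywhere) are
  excluded from set averages, not counted as zero, because such variants
  carry no differentiation signal at all.

**LD pruning.** The pruning parameters (r² threshold 0.5, window 50, step
5) follow the common genome-wide-background recipe. Published descriptions
of this recipe are often internally inconsistent about whether windows are
measured in variants or nucleotides and whether the criterion is pairwise
r² or VIF; we implement the one self-consistent reading — pairwise r² on
dosages (composite LD, no phasing assumed) over 50-*variant* windows
sliding by 5. Within a window, while any pair exceeds the threshold, the
lower-MAF member of the worst pair is removed; ties go to the later
position. This makes the output deterministic, and on small instances it
matches a brute-force greedy oracle (tested). A zero-variance variant has
r² defined as 0 against everything, so monomorphic variants never cause
removals.

**IBS distance and MDS.** `d(a,b)` is the allelic Hamming distance as a
fraction of alleles compared over pairwise-complete variants. Classical
MDS is delegated to base R's `cmdscale` (Torgerson double-centering),
with two additions: a deterministic sign convention (each axis flipped so
its first nonzero loading is positive — eigenvector signs are otherwise
arbitrary, which would break byte-identical reruns), and an explicit
policy for negative eigenvalues. Allele-sharing distance matrices are
routinely slightly non-Euclidean; eigenvalues more negative than 5% of
the leading one trigger a warning, smaller ones are clamped silently.

## Supervised ancestry estimation

Unsupervised K-cluster admixture estimation on a combined
reference-plus-study panel is the field's standard tool, but at desk scale
the reference populations fully anchor the components, so the equivalent
supervised formulation is used: component allele frequencies `f_kj` come
from a reference panel and only the per-individual fractions `q` are
estimated. Per individual we maximize the binomial log-likelihood

    L(q) = sum_j [ g_j log p_j(q) + (2 - g_j) log(1 - p_j(q)) ],
    p_j(q) = sum_k q_k f_kj

over the simplex, using the multiplicative EM update

    q_k <- (q_k / 2M') sum_j [ g_j f_kj / p_j + (2 - g_j)(1 - f_kj) / (1 - p_j) ]

with `M'` the individual's non-missing variant count. The update keeps
`q` exactly on the simplex and increases `L` at every step (asserted per
iteration in the test suite). Numerical choices: panel frequencies are
clipped to `[1e-6, 1 - 1e-6]` so the log-likelihood stays finite at fixed
or absent alleles; iteration stops when the per-individual increase drops
below `tol = 1e-6` (cap 2000 iterations); initialization is uniform
`1/K`. The likelihood is concave in `q` for fixed panel frequencies, so
the uniform start is not a gamble. Fewer than 10 variants shared with the
panel is treated as an error rather than a very noisy estimate.

The estimator assumes unlinked markers (the likelihood multiplies across
variants) and a correct, ancestrally representative panel. Both hold by
construction for the synthetic data; with real panels, LD pruning first
is the appropriate discipline, which is why the pipeline estimates
ancestry on the pruned set.

## Ancestry association

Per variant, ordinary least squares of ancestry fraction on effect-allele
dosage, with slope `beta = cov(x, y)/var(x)`, `SE` from the residual
variance with `n - 2` degrees of freedom, and a two-sided P from the t
distribution. The regression includes an intercept; the slope-only model
statement is shorthand for the slope being the quantity of interest.
Because the K ancestry fractions sum to 1, the K slopes at any variant
sum to 0 (tested to 1e-10): an allele enriched with one ancestry is
necessarily depleted from the others. Degenerate cases are flagged rather
than hidden: constant response gives `beta = 0, P = 1`; a perfect
non-constant fit (SSE below `1e-14 * Syy`, a relative guard against
cancellation) reports `SE = 0, P = 0` with a `degenerate_fit` flag;
constant genotype is undefined. Raw P-values are the default output,
matching the convention of reporting per-variant evidence; BH q-values
are available but off by default. The regression pools all individuals
across cohorts — the cohort contrast is exactly the ancestry signal being
quantified, so stratifying by cohort would remove it.

## Effect-allele divergence and the screen

Between two populations, the log-ratio `R = log2(f1/f2)` captures
relative differences (dominant at low frequencies), the difference
`delta = f1 - f2` captures absolute differences (dominant at high
frequencies), and the composite is the Euclidean distance from the origin
in the `(delta, R)` plane, `E = sqrt(R^2 + delta^2)`. Since
`|delta| <= 1` while `|R|` is unbounded, E implicitly weights relative
divergence more for rare alleles; that asymmetry is inherent to the
statistic, not a bug.

Boundary frequencies would send `R` to infinity. The handling was an open
choice; we continuity-correct only boundary values by half an allele
count, `f* = (2 n f + 0.5)/(2 n + 1)`, so population-private alleles
still rank instead of being dropped, and interior frequencies are
untouched (tested to 1e-12 against the raw formula). The correction is
switchable off, in which case infinities propagate honestly.

The screen keeps high-evidence annotations (tiers 1A/1B/2A/2B) with
`E > 0.5`, *strictly* — a record at exactly 0.5 is excluded — and ranks
by decreasing E with lexicographic rsID tie-breaks for deterministic
reports. On the package's curated 13-row table of published Colombian
pharmaSNPs of interest, 11 rows exceed 0.5; the two that do not (the
warfarin-dosage SNP rs1799853 and the clopidogrel SNP rs4244285, both
with small between-population differences) illustrate that a curated
clinical shortlist and a pure divergence screen are overlapping but not
identical criteria.

## Effect-allele orientation

Dosages carry an explicit record of which allele they count. Re-coding to
effect-allele dosage flips `d -> 2 - d` exactly when the counted allele is
the annotated non-effect allele. When the VCF's ref/alt pair does not
equal the annotation's allele pair, the variant is dropped and logged —
including when a strand flip would reconcile them. Silent strand guessing
is a known source of sign errors, and for strand-ambiguous SNPs (A/T,
C/G) it is undecidable from alleles alone; dropping is the only safe
default. Orientation is involutive (swapping the annotation alleles
complements dosages; swapping twice restores them) and idempotent, both
tested.

## The synthetic-data generator

The generator exists so every stage is testable without downloads. It
emulates:

- a reference panel under the Balding–Nichols model: ancestral frequency
  `p_j ~ Uniform(0.05, 0.95)`, per-component
  `f_kj ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`, so `F` is a single knob for
  between-component differentiation (`Var(f|p) = F p (1-p)`, verified
  against the closed form in tests). Default `F = 0.15`, a value in the
  range of continental-scale human differentiation;
- admixed individuals: `q_i ~ Dirichlet(alpha)` per cohort, genotypes
  `Binomial(2, sum_k q_ik f_kj)`. The default cohorts centre on the
  published ancestry profiles of the two motivating populations —
  7/61/32% African/European/Native American for the Antioquia-like
  cohort and 76/11/13% for the Chocó-like cohort — with concentration 50,
  which gives realistic individual scatter (s.d. around 7% per component)
  while keeping cohort means recoverable at n = 100 within 0.03;
- pharmaSNP annotations over 5% of variants, with the effect allele on
  ref or alt with equal probability so orientation handling is genuinely
  exercised;
- assay error: each non-missing genotype replaced with probability
  `epsilon` by one of the other two classes, uniformly. Default
  `epsilon = 0.023`, the order of discordance seen when validating
  allele-specific PCR against exome calls (3 discordant calls in 132).

All randomness flows from one integer seed; identical configs are
bit-identical. By construction each genotype is Hardy–Weinberg given its
own admixed frequency, and pooling the two cohorts exhibits the Wahlund
homozygote excess (tested at 2000 variants).

What it deliberately does **not** emulate: linkage disequilibrium
(variants are unlinked, so LD pruning is exercised on separately
constructed correlated fixtures, not simulator output), the elevated MAF
and F_ST of real pharmaSNP panels relative to the genome-wide background
(simulated pharmaSNPs are a random subset of variants, so both sets have
the same frequency law), ascertainment bias, genotyping-error asymmetry
between classes, phased haplotypes, and star-allele/haplotype structure.
Passing tests therefore demonstrate the correctness of the computations
and the recoverability of simulated truth — not that real cohorts would
show any particular effect size.

## Concordance scoring

Truth calls (sequencing) index the rows, test calls (assay) the columns,
with a flag to swap. Samples absent from either set or with a missing
call are dropped and counted, not scored as errors — an unscored sample
is evidence of assay failure of a different kind than a miscall, and
conflating them would understate accuracy. Per-class one-vs-rest
sensitivity, specificity and precision leave zero-denominator cases as
undefined (`NA`) rather than 0; accuracy is the trace over the scored
total, and the formatted report rounds to one decimal percent while TSVs
keep full precision.

## Problem sizes

The shipped analysis and test configurations are sized for a single CPU
core: the demo study uses 3000 variants and two cohorts of 60; ancestry
recovery is verified at 5000 variants and 50 individuals (mean absolute
error ~0.02 against simulated truth, threshold 0.05); property tests that
need aggregate statistics use 1000–2000 variants. These sizes put every
Monte-Carlo assertion at least three standard errors from its pass
boundary under the fixed seeds, which is the criterion used to choose
them.

## Known limitations

- Only biallelic SNPs; no indels, structural variants, or multiallelic
  decomposition, and no haplotype/star-allele calling — multi-SNP dosing
  algorithms (e.g. warfarin) are out of scope.
- Supervised estimation only: no unsupervised clustering, no choice of K
  by cross-validation, no local-ancestry inference.
- Wright's variance-ratio F_ST, not the Weir–Cockerham or Hudson
  estimators; values are comparable within this package, not across
  estimators.
- The ancestry estimator treats panel frequencies as known constants;
  panel sampling noise is not propagated into the fractions.
- No liftover and no strand inference: annotation alleles must match the
  VCF's strand or the variant is dropped.
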