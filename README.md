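# pharmapop

Population pharmacogenomics for admixed cohorts: quantify how the allele
frequencies of drug-response variants (pharmaSNPs) differ between
populations, tie those differences to genetic ancestry, and validate cheap
genotyping assays against sequencing calls. The package is aimed at
population-genetics and precision-public-health analysts who need to decide
*which* pharmacogenomic tests matter for *which* population — the setting
where genotyping every patient is unaffordable and population-level allele
frequency profiles must guide testing priorities.

## What it computes

For a genotype matrix of biallelic SNPs with explicit effect-allele
orientation:

- **Allele frequency structure.** Folded minor allele frequency
  `p = (minor allele count) / (2 n)`, and Wright's fixation index per
  variant, `F_ST = σ² / (p̄ (1 − p̄))`, where `p̄` and `σ²` are the mean and
  variance of per-population allele frequencies. Plus greedy windowed LD
  pruning (pairwise r² on dosages, 50-variant windows, step 5),
  identity-by-state distances `d(a,b) = Σ|g_a − g_b| / 2m`, and classical
  (Torgerson) MDS.
- **Supervised ancestry estimation.** Per individual, the admixture
  fractions `q` on the K-simplex maximizing the binomial log-likelihood
  `L(q) = Σ_j [g_j log p_j(q) + (2 − g_j) log(1 − p_j(q))]`,
  `p_j(q) = Σ_k q_k f_kj`, against a reference panel of per-component
  allele frequencies `f_kj`, via a multiplicative EM update with
  guaranteed monotone likelihood.
- **Effect-allele divergence.** Between two populations, the log-ratio
  `R = log2(f₁/f₂)`, the difference `Δ = f₁ − f₂`, and the composite
  Euclidean distance from the origin `E = √(R² + Δ²)`; pharmaSNPs of
  interest are the high-evidence annotations with `E > 0.5`.
- **Ancestry association.** Per variant, OLS of ancestry fraction on
  effect-allele dosage `x ∈ {0,1,2}`: slope β, `t = β/SE_β`, two-sided P
  from the t distribution.
- **Assay concordance.** 3×3 confusion matrices (homozygous non-effect /
  heterozygous / homozygous effect) between a truth call set and a test
  call set, with accuracy and one-vs-rest per-class metrics.
- **Synthetic cohorts.** A Balding–Nichols reference panel plus
  Dirichlet-admixed cohorts and annotation tables, so the whole pipeline
  runs and is tested without any external data.

## Worked example

The curated table shipped with the package holds 13 clinically annotated
pharmaSNPs with published effect-allele frequencies in two Colombian
populations, Antioquia (mainly European ancestry) and Chocó (mainly
African ancestry):

```r
library(pharmapop)
tab <- colombia_pharmasnps()
div <- divergence(tab$freq_antioquia, tab$freq_choco, ids = tab$rsid)
subset(div, id %in% c("rs776746", "rs4149056"))
#>          id f_pop1 f_pop2 log2_ratio delta euclidean direction
#> 1  rs776746   0.81   0.32   1.339850  0.49  1.426639      pop1
#> 4 rs4149056   0.18   0.05   1.847997  0.13  1.852564      pop1
```

rs776746 (CYP3A5\*3, tacrolimus metabolism) has effect-allele frequency
0.81 in Antioquia versus 0.32 in Chocó: Δ = 0.49, R = log2(0.81/0.32) ≈
1.34, composite E ≈ 1.43 — far above the E > 0.5 screening threshold, so
it ranks as a pharmaSNP of interest. rs4149056 (SLCO1B1\*5, simvastatin
toxicity) shows a smaller absolute difference (0.18 vs 0.05) but a larger
relative one, which the log-ratio axis captures (E ≈ 1.85). Direction
`pop1` means the effect allele is more frequent in the first population
(Antioquia).

The full simulated study — cohort simulation, structure, ancestry,
divergence screen, assay concordance — is the numbered scripts:

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_population_structure.R
Rscript analysis/03_ancestry.R
Rscript analysis/04_divergence_screen.R
Rscript analysis/05_assay_concordance.R
```

On the default configuration (3000 variants, two cohorts of 60) the
ancestry stage prints cohort means of 0.08/0.62/0.31 (AFR/EUR/NAM) for the
Antioquia-like cohort and 0.75/0.12/0.13 for the Chocó-like cohort, with a
mean absolute error versus the simulated truth of about 0.02. The same
stages are available as one call, `run_pipeline(pipeline_config(), out_dir)`,
driven by a YAML config if preferred.

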