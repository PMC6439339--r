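#!/usr/bin/env Rscript
# Simulate the study system: two admixed cohorts with distinct three-way
# ancestry profiles (an Antioquia-like cohort, mostly European with Native
# American admixture, and a Choco-like cohort, mostly African), a reference
# panel of per-component allele frequencies, and a pharmaSNP annotation
# table. All downstream scripts read the files written here.

library(pharmapop)

out <- "results/study"
cfg <- sim_config(M = 3000L, cohorts = list(
  list(name = "antioquia", n = 60L, alpha = c(0.07, 0.61, 0.32) * 50,
       role = "study"),
  list(name = "choco", n = 60L, alpha = c(0.76, 0.11, 0.13) * 50,
       role = "study")
), pharma_fraction = 0.05, seed = 17L)

st <- simulate_study(cfg)
paths <- write_study(st, out)

cat("Simulated", n_samples(st$gm), "individuals x", n_variants(st$gm),
    "variants;", nrow(st$annotations), "pharmaSNP annotations.\n")
cat("Cohort mean ancestry (AFR/EUR/NAM):\n")
for (pop in names(cfg$cohorts)) {
  q <- colMeans(st$truth[grep(paste0("^", pop), rownames(st$truth)), ])
  cat(sprintf("  %-10s %s\n", pop,
              paste(sprintf("%.2f", q), collapse = " / ")))
}
cat("Files written under", out, "\n")
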