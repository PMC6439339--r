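#!/usr/bin/env Rscript
# Effect-allele divergence between the two cohorts, the E > 0.5 screen for
# pharmaSNPs of interest, and ancestry association regressions for the
# screened SNPs. Also recomputes the divergence statistics for the curated
# table of 13 published Colombian pharmaSNPs of interest, the package's
# worked real-data example.

library(pharmapop)

gm <- read_vcf("results/study/genotypes.vcf")
manifest <- read_manifest("results/study/manifest.tsv")
ann <- read_annotation("results/study/annotations.tsv")
panel <- read_panel("results/study/panel_freq.tsv")
dir.create("results/divergence", showWarnings = FALSE, recursive = TRUE)

## simulated cohorts ---------------------------------------------------
gm_ph <- orient_to_effect_allele(gm, ann)
div <- divergence_table(gm_ph, manifest, c("antioquia", "choco"))
write.table(div, "results/divergence/divergence.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

report <- screen_of_interest(div, ann, e_threshold = 0.5)
write.table(report, "results/divergence/snps_of_interest.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(nrow(report), "of", nrow(div),
    "annotated pharmaSNPs pass the E > 0.5 screen at evidence levels 1-2.\n")

anc <- estimate_ancestry(gm, panel)
assoc <- ancestry_association(subset_gm(gm_ph, variants = report$id), anc)
write.table(assoc, "results/divergence/ancestry_association.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
top <- assoc[assoc$component == "AFR", ]
top <- top[order(top$p), ][1:min(3, nrow(top)), ]
cat("Strongest African-ancestry associations among screened SNPs:\n")
print(top, digits = 3, row.names = FALSE)

## published Colombian pharmaSNPs of interest --------------------------
tab <- colombia_pharmasnps()
pub <- divergence(tab$freq_antioquia, tab$freq_choco, ids = tab$rsid)
pub$drug_response <- tab$drug_response
write.table(pub, "results/divergence/published_snps_divergence.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nPublished pharmaSNPs of interest, ranked by composite divergence:\n")
print(pub[order(-pub$euclidean),
          c("id", "drug_response", "f_pop1", "f_pop2", "log2_ratio",
            "delta", "euclidean", "direction")],
      digits = 3, row.names = FALSE)
cat(sum(pub$euclidean > 0.5), "of", nrow(pub),
    "published rows exceed the E > 0.5 screen threshold.\n")
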