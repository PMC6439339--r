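# Small in-code fixture builders shared across test files.

# Genotype matrix from a bare dosage matrix; variant metadata synthesized.
make_gm <- function(dosage, ref = NULL, alt = NULL, counted = "alt",
                    ids = NULL, chrom = "1", pos = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%02d", seq_len(nrow(dosage)))
  }
  m <- ncol(dosage)
  if (is.null(ids)) ids <- sprintf("rs%04d", seq_len(m))
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  genotype_matrix(
    dosage,
    data.frame(id = ids, chrom = chrom, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    counted_allele = rep_len(counted, m)
  )
}

# One-row-per-variant annotation table with valid vocabulary entries.
make_ann <- function(ids, effect, non_effect,
                     evidence = "1A", category = "toxicity/ADR") {
  k <- length(ids)
  data.frame(
    id = ids, gene = paste0("G_", ids)[seq_len(k)], drug = rep_len("drugX", k),
    category = rep_len(category, k),
    evidence_level = rep_len(evidence, k),
    effect_allele = effect, non_effect_allele = non_effect,
    stringsAsFactors = FALSE
  )
}

make_manifest <- function(samples, population, role = "study") {
  data.frame(sample = samples, population = rep_len(population, length(samples)),
             role = rep_len(role, length(samples)), stringsAsFactors = FALSE)
}

# Write VCF body rows with a standard header to a temp file.
write_vcf_text <- function(rows, samples = c("S1", "S2", "S3")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows
  ), path)
  path
}

vcf_row <- function(chrom, pos, id, ref, alt, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# Small simulation config used by several files (kept deliberately light).
tiny_cfg <- function(M = 500L, n = 40L, seed = 7L, diff = 0.15, ...) {
  sim_config(M = M, cohorts = list(
    list(name = "antioquia", n = n, alpha = c(0.07, 0.61, 0.32) * 50,
         role = "study"),
    list(name = "choco", n = n, alpha = c(0.76, 0.11, 0.13) * 50,
         role = "study")
  ), diff = diff, seed = seed, ...)
}
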