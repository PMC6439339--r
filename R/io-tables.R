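#' @name pharma_annotation
#' @title PharmaSNP clinical annotation tables
#'
#' @description
#' Annotations follow the shape of curated clinical pharmacogenomics
#' knowledgebases: one row per SNP-drug association, carrying the effect
#' and non-effect alleles, the response category and an evidence tier.
#' Closed vocabularies are enforced at read time so that downstream
#' filters (evidence level, category) cannot silently miss rows through
#' spelling drift.
#'
#' Columns: `id`, `gene`, `drug`, `category` (efficacy, dosage,
#' toxicity/ADR, metabolism or other), `evidence_level` (1A, 1B, 2A, 2B,
#' 3 or 4), `effect_allele`, `non_effect_allele`.
NULL

#' Closed vocabulary of drug-response categories
#' @export
pharmapop_categories <- c("efficacy", "dosage", "toxicity/ADR", "metabolism", "other")

#' Closed vocabulary of evidence tiers, strongest first
#' @export
pharmapop_evidence_levels <- c("1A", "1B", "2A", "2B", "3", "4")

#' Evidence tiers counted as high-confidence (levels 1 and 2)
#' @export
high_evidence_levels <- c("1A", "1B", "2A", "2B")

.annotation_cols <- c("id", "gene", "drug", "category", "evidence_level",
                      "effect_allele", "non_effect_allele")

#' Read a pharmaSNP annotation TSV
#'
#' @param path TSV file with a header row naming the annotation columns
#'   (see [pharma_annotation]).
#' @return data frame of validated annotations (possibly zero rows).
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(.annotation_cols, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_annotation(ann[, .annotation_cols, drop = FALSE], context = path)
}

#' Validate an annotation table against the closed vocabularies
#'
#' @param ann data frame with the annotation columns.
#' @param context label used in error messages (e.g. a file name).
#' @return `ann`, invisibly validated (returned visibly for piping).
#' @export
validate_annotation <- function(ann, context = "annotation") {
  if (nrow(ann) == 0L) return(ann)
  nt <- c("A", "C", "G", "T")
  .row_check <- function(bad, what) {
    if (any(bad)) {
      stop(context, ": ", what, " at row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
    }
  }
  .row_check(!(ann$evidence_level %in% pharmapop_evidence_levels),
             "unknown evidence level")
  .row_check(!(ann$category %in% pharmapop_categories), "unknown category")
  .row_check(!(ann$effect_allele %in% nt) | !(ann$non_effect_allele %in% nt),
             "non-nucleotide allele")
  .row_check(ann$effect_allele == ann$non_effect_allele,
             "effect allele equals non-effect allele")
  .row_check(duplicated(ann$id), "duplicate rsID")
  ann
}

#' @rdname read_annotation
#' @param ann annotation data frame.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann[, .annotation_cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify annotated variants as SNP / indel / other from their alleles
#'
#' A row is a SNP when both alleles are single A/C/G/T nucleotides, an
#' indel when both are pure nucleotide strings of unequal length (or one
#' is `-`), and `other` otherwise (e.g. symbolic CNV alleles). Used to
#' report what share of a variant-annotation catalogue the SNP-only
#' analyses actually cover.
#'
#' @param effect_allele,non_effect_allele character vectors of alleles.
#' @return character vector in `c("snp", "indel", "other")`.
#' @export
classify_variant_type <- function(effect_allele, non_effect_allele) {
  nt1 <- grepl("^[ACGT]$", effect_allele) & grepl("^[ACGT]$", non_effect_allele)
  seqlike <- function(x) grepl("^[ACGT]+$", x) | x == "-"
  indel <- !nt1 & seqlike(effect_allele) & seqlike(non_effect_allele)
  ifelse(nt1, "snp", ifelse(indel, "indel", "other"))
}

#' Read / write a population manifest
#'
#' The manifest assigns every sample to one population and one role.
#' `role` distinguishes reference-panel individuals from the study
#' cohorts under comparison.
#'
#' @param path TSV with columns `sample`, `population`, `role`
#'   (`reference` or `study`).
#' @return data frame with those three columns.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("sample", "population", "role")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0L) {
    stop("manifest '", path, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(m$sample)) {
    stop("manifest '", path, "' assigns sample(s) more than once: ",
         paste(utils::head(unique(m$sample[duplicated(m$sample)]), 5L),
               collapse = ", "))
  }
  if (!all(m$role %in% c("reference", "study"))) {
    stop("manifest '", path, "' has role outside {reference, study}")
  }
  m[, need]
}

#' @rdname read_manifest
#' @param manifest manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest[, c("sample", "population", "role")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check a manifest covers a genotype matrix exactly once
#' @param gm a [genotype_matrix()].
#' @param manifest manifest data frame.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
check_manifest <- function(gm, manifest) {
  missing_s <- setdiff(sample_ids(gm), manifest$sample)
  if (length(missing_s) > 0L) {
    stop("sample(s) absent from manifest: ",
         paste(utils::head(missing_s, 5L), collapse = ", "))
  }
  invisible(TRUE)
}

#' Curated pharmaSNPs of interest for two Colombian populations
#'
#' A small curated table of 13 clinically annotated pharmacogenomic SNPs
#' with published effect-allele frequencies in Antioquia and Choco and the
#' published ancestry-association slopes (beta) and P-values per ancestry
#' component (African, European, Native American). Rows flagged `*` carry
#' the flag through opaquely. Ships as plain text under `inst/extdata` and
#' serves as the worked example for the divergence and screening
#' functions.
#'
#' @return data frame with columns `rsid`, `drug_response`,
#'   `freq_antioquia`, `freq_choco`, `beta_afr`, `p_afr`, `beta_eur`,
#'   `p_eur`, `beta_nam`, `p_nam`, `flagged`.
#' @export
colombia_pharmasnps <- function() {
  path <- system.file("extdata", "colombia_pharmasnps_of_interest.tsv",
                      package = "pharmapop", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
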