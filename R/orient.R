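#' Re-orient dosages to count effect-allele copies
#'
#' Pharmacogenomic analyses are stated in terms of the *effect* allele —
#' the allele that increases the drug-gene effect (efficacy, required
#' dosage, toxicity risk) — while VCFs are stated in ref/alt terms. This
#' re-codes the dosage of each annotated variant so that it counts effect
#' alleles, and drops any variant whose ref/alt pair cannot be matched to
#' the annotation's allele pair.
#'
#' Strand handling is deliberately conservative: if the allele sets
#' disagree, the variant is dropped and logged even when a strand flip
#' (A<->T, C<->G complement) would reconcile them. Silent strand guessing
#' is a classic source of sign errors in effect-allele work, and
#' strand-ambiguous SNPs (A/T, C/G) cannot be resolved from alleles alone.
#'
#' @param gm a [genotype_matrix()].
#' @param ann annotation data frame (see [read_annotation()]); only
#'   variants present in both `gm` and `ann` are returned.
#' @return A `genotype_matrix` restricted to successfully oriented
#'   variants, each with dosage counting effect-allele copies. The
#'   attribute `"dropped"` carries a data frame (`id`, `reason`) of
#'   variants excluded for unresolvable orientation; retrieve it with
#'   [dropped_variants()].
#' @export
orient_to_effect_allele <- function(gm, ann) {
  shared <- intersect(gm$variants$id, ann$id)
  if (length(shared) == 0L) stop("no variants shared between genotypes and annotation")
  gm <- subset_gm(gm, variants = shared)
  ann <- ann[match(shared, ann$id), , drop = FALSE]

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  keep <- logical(length(shared))
  flip <- logical(length(shared))
  reason <- character(length(shared))

  for (j in seq_along(shared)) {
    vcf_pair <- c(gm$variants$ref[j], gm$variants$alt[j])
    ann_pair <- c(ann$effect_allele[j], ann$non_effect_allele[j])
    if (setequal(vcf_pair, ann_pair)) {
      keep[j] <- TRUE
      flip[j] <- counted_nucleotide(gm)[j] != ann$effect_allele[j]
    } else {
      ambiguous <- vcf_pair[1] == comp[vcf_pair[2]]
      flip_match <- setequal(unname(comp[vcf_pair]), ann_pair)
      reason[j] <- if (ambiguous) {
        "unresolvable orientation: strand-ambiguous SNP with mismatched alleles"
      } else if (flip_match) {
        "unresolvable orientation: alleles match only under a strand flip"
      } else {
        "unresolvable orientation: allele mismatch"
      }
    }
  }

  dropped <- data.frame(id = shared[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  if (nrow(dropped) > 0L) {
    message("orient_to_effect_allele: dropped ", nrow(dropped),
            " variant(s) with unresolvable orientation: ",
            paste(utils::head(dropped$id, 5L), collapse = ", "))
  }
  if (!any(keep)) stop("no variant could be oriented to its effect allele")

  out <- subset_gm(gm, variants = which(keep))
  fl <- flip[keep]
  if (any(fl)) {
    out$dosage[, fl] <- 2L - out$dosage[, fl]
    out$counted_allele[fl] <- ifelse(out$counted_allele[fl] == "alt", "ref", "alt")
  }
  attr(out, "dropped") <- dropped
  out
}

#' Variants dropped during effect-allele orientation
#' @param gm result of [orient_to_effect_allele()].
#' @return data frame with columns `id`, `reason` (zero rows if none).
#' @export
dropped_variants <- function(gm) {
  d <- attr(gm, "dropped")
  if (is.null(d)) data.frame(id = character(), reason = character()) else d
}
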