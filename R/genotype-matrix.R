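#' Genotype matrix with explicit allele orientation
#'
#' The central container of the package: a samples x variants matrix of
#' dosage-coded genotypes together with the variant table and, per variant,
#' a record of *which* allele the dosage counts. Keeping the counted allele
#' explicit is what makes effect-allele re-orientation
#' ([orient_to_effect_allele()]) a safe, checkable operation instead of a
#' silent convention.
#'
#' @param dosage integer matrix, samples in rows, variants in columns;
#'   entries must be 0, 1, 2 or `NA` (missing). Row names are sample IDs;
#'   column names, if present, must equal `variants$id`.
#' @param variants data frame with columns `id` (rsID, unique), `chrom`,
#'   `pos` (1-based), `ref`, `alt` (single nucleotides, `ref != alt`).
#' @param counted_allele character vector, one of `"ref"`/`"alt"` per
#'   variant, naming the allele whose copies `dosage` counts. Default:
#'   every variant counts the alt allele.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants,
                            counted_allele = rep("alt", nrow(variants))) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)

  required <- c("id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0L) {
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (ncol(dosage) != nrow(variants)) {
    stop("dosage has ", ncol(dosage), " columns but variant table has ",
         nrow(variants), " rows")
  }
  if (length(counted_allele) != nrow(variants) ||
      !all(counted_allele %in% c("ref", "alt"))) {
    stop("counted_allele must be 'ref' or 'alt' for every variant")
  }
  if (anyDuplicated(variants$id)) {
    dup <- unique(variants$id[duplicated(variants$id)])
    stop("duplicate variant ID(s): ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  bad_nt <- !(variants$ref %in% c("A", "C", "G", "T")) |
    !(variants$alt %in% c("A", "C", "G", "T")) |
    variants$ref == variants$alt
  if (any(bad_nt)) {
    stop("non-SNP or degenerate alleles at variant(s): ",
         paste(utils::head(variants$id[bad_nt], 5L), collapse = ", "))
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) > 0L && !all(vals %in% 0:2)) {
    stop("dosage entries must be 0, 1, 2 or missing")
  }
  if (is.null(rownames(dosage))) {
    stop("dosage must carry sample IDs as row names")
  }
  colnames(dosage) <- variants$id
  rownames(variants) <- NULL

  structure(
    list(dosage = dosage, variants = variants,
         counted_allele = as.character(counted_allele)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", n_samples(x), " samples x ", n_variants(x),
      " variants\n", sep = "")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  counted allele: %d alt / %d ref; missingness %.2f%%\n",
              sum(x$counted_allele == "alt"), sum(x$counted_allele == "ref"),
              100 * miss))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`.
#' @export
n_samples <- function(gm) nrow(gm$dosage)

#' @rdname genotype_matrix
#' @export
n_variants <- function(gm) ncol(gm$dosage)

#' @rdname genotype_matrix
#' @export
sample_ids <- function(gm) rownames(gm$dosage)

#' @rdname genotype_matrix
#' @export
variant_ids <- function(gm) gm$variants$id

#' Nucleotide actually counted by the dosage, per variant
#' @param gm a `genotype_matrix`.
#' @return character vector of nucleotides, one per variant.
#' @export
counted_nucleotide <- function(gm) {
  ifelse(gm$counted_allele == "alt", gm$variants$alt, gm$variants$ref)
}

#' Subset a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @param variants variant IDs or indices to keep (in the given order).
#' @param samples sample IDs or indices to keep.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_gm <- function(gm, variants = NULL, samples = NULL) {
  vi <- seq_len(n_variants(gm))
  si <- seq_len(n_samples(gm))
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, gm$variants$id) else variants
    if (anyNA(vi)) stop("unknown variant ID(s) in subset")
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, sample_ids(gm)) else samples
    if (anyNA(si)) stop("unknown sample ID(s) in subset")
  }
  genotype_matrix(gm$dosage[si, vi, drop = FALSE],
                  gm$variants[vi, , drop = FALSE],
                  gm$counted_allele[vi])
}
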