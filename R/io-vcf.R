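#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (GT subfield only) and returns the biallelic-SNP
#' subset as a [genotype_matrix()]. Multiallelic records, indels and any
#' record whose REF/ALT are not single A/C/G/T nucleotides are silently
#' excluded, mirroring the usual restriction of pharmacogenomic SNP panels
#' to simple substitutions. Phased (`|`) and unphased (`/`) genotypes are
#' treated identically; `./.` (or `.`) becomes missing.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param allele_policy which allele the returned dosage counts: `"alt"`
#'   (default) or `"ref"`.
#' @return A `genotype_matrix`. Variant IDs come from the ID column; a
#'   missing ID (`.`) is replaced by `chrom:pos`. Duplicate IDs are an
#'   error, as downstream joins key on rsID.
#' @export
read_vcf <- function(path, allele_policy = c("alt", "ref")) {
  allele_policy <- match.arg(allele_policy)
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {              # single record drops to a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF '", path, "' contains no records")

  nt <- c("A", "C", "G", "T")
  keep <- fix$REF %in% nt & fix$ALT %in% nt
  if (!any(keep)) stop("VCF '", path, "' contains no biallelic SNPs")

  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  if (anyDuplicated(ids[keep])) {
    dup <- unique(ids[keep][duplicated(ids[keep])])
    stop("duplicate variant ID(s) in '", path, "': ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) stop("VCF '", path, "' has no sample genotypes")
  gt <- gt[keep, , drop = FALSE]

  alt_count <- .gt_to_alt_count(gt, ids[keep], path)
  dosage <- t(alt_count)               # samples x variants
  if (allele_policy == "ref") dosage <- 2L - dosage

  variants <- data.frame(
    id = ids[keep], chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep], alt = fix$ALT[keep], stringsAsFactors = FALSE
  )
  genotype_matrix(dosage, variants,
                  counted_allele = rep(allele_policy, nrow(variants)))
}

# GT strings -> alt-allele counts (variants x samples), NA for missing.
.gt_to_alt_count <- function(gt, ids, path) {
  g <- gsub("|", "/", gt, fixed = TRUE)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
            "./." = NA_integer_, "." = NA_integer_)
  out <- matrix(code[g], nrow = nrow(g), ncol = ncol(g),
                dimnames = list(ids, colnames(gt)))
  bad <- !(g %in% names(code)) & !is.na(g)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("unparseable GT '", gt[bad][1L], "' at variant ", ids[w[1L]],
         ", sample ", colnames(gt)[w[2L]], " in '", path, "'")
  }
  out[is.na(gt)] <- NA_integer_
  out
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with GT-only FORMAT. Dosages are converted back
#' to ref/alt genotype calls using the stored counted-allele orientation,
#' so `read_vcf(write_vcf(gm))` round-trips dosage, sample order and
#' variant order exactly (with the reader's allele policy).
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  alt_count <- gm$dosage
  flip <- gm$counted_allele == "ref"
  if (any(flip)) alt_count[, flip] <- 2L - alt_count[, flip]

  gt_str <- matrix(c("0/0", "0/1", "1/1")[alt_count + 1L],
                   nrow = nrow(alt_count), ncol = ncol(alt_count))
  gt_str[is.na(alt_count)] <- "./."

  v <- gm$variants
  body <- character(nrow(v))
  for (j in seq_len(nrow(v))) {
    body[j] <- paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT", gt_str[, j]), collapse = "\t")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pharmapop",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(gm)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}
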