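#' Effect-allele frequencies in two populations
#'
#' @param gm an effect-allele-oriented [genotype_matrix()] (see
#'   [orient_to_effect_allele()]).
#' @param manifest population manifest.
#' @param populations character vector of exactly two population labels,
#'   `(pop1, pop2)`; divergence statistics are signed pop1 minus/over pop2.
#' @return data frame with `id`, `f_pop1`, `f_pop2`, `n1`, `n2` (non-
#'   missing sample counts). Attribute `"populations"` records the labels.
#' @export
effect_allele_frequencies <- function(gm, manifest, populations) {
  if (length(populations) != 2L) stop("exactly two populations required")
  freqs <- allele_freq_by_pop(gm, manifest, populations)
  counts <- vapply(populations, function(p) {
    ids <- intersect(manifest$sample[manifest$population == p], sample_ids(gm))
    colSums(!is.na(gm$dosage[ids, , drop = FALSE]))
  }, numeric(n_variants(gm)))
  out <- data.frame(id = rownames(freqs),
                    f_pop1 = freqs[, 1L], f_pop2 = freqs[, 2L],
                    n1 = counts[, 1L], n2 = counts[, 2L],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "populations") <- populations
  out
}

#' Between-population effect-allele divergence statistics
#'
#' Two complementary views of a frequency difference are combined: the
#' log-ratio `R = log2(f1 / f2)` emphasizes relative differences at low
#' frequencies, the plain difference `delta = f1 - f2` emphasizes absolute
#' differences at high frequencies, and the Euclidean distance from the
#' origin `E = sqrt(R^2 + delta^2)` in the (delta, R) plane is the
#' composite divergence used for ranking.
#'
#' Boundary frequencies (0 or 1) would make the log-ratio infinite; for
#' the ratio only, such frequencies are continuity-corrected by half an
#' allele count, `f* = (2 n f + 0.5) / (2 n + 1)`, so rare,
#' population-private effect alleles still rank (set
#' `continuity_correct = FALSE` to keep infinities). The difference always
#' uses raw frequencies.
#'
#' @param f_pop1,f_pop2 effect-allele frequencies (vectors align by
#'   position).
#' @param n1,n2 per-population non-missing sample counts; required only
#'   when a frequency sits on the boundary and correction is on.
#' @param ids optional variant IDs.
#' @param continuity_correct apply the half-count correction at 0/1.
#' @return data frame with `id`, `f_pop1`, `f_pop2`, `log2_ratio`,
#'   `delta`, `euclidean`, `direction` (`"pop1"`/`"pop2"`/`"equal"`,
#'   which population has the higher effect-allele frequency).
#' @export
divergence <- function(f_pop1, f_pop2, n1 = NULL, n2 = NULL, ids = NULL,
                       continuity_correct = TRUE) {
  stopifnot(length(f_pop1) == length(f_pop2),
            all(f_pop1 >= 0 & f_pop1 <= 1, na.rm = TRUE),
            all(f_pop2 >= 0 & f_pop2 <= 1, na.rm = TRUE))
  corr <- function(f, n) {
    at_edge <- !is.na(f) & (f == 0 | f == 1)
    if (!continuity_correct || !any(at_edge)) return(f)
    if (is.null(n)) {
      stop("sample sizes needed for continuity correction of boundary frequencies")
    }
    n <- rep_len(n, length(f))
    f[at_edge] <- (2 * n[at_edge] * f[at_edge] + 0.5) / (2 * n[at_edge] + 1)
    f
  }
  f1s <- corr(f_pop1, n1)
  f2s <- corr(f_pop2, n2)
  R <- log2(f1s / f2s)
  delta <- f_pop1 - f_pop2
  E <- sqrt(R^2 + delta^2)
  direction <- ifelse(delta > 0, "pop1", ifelse(delta < 0, "pop2", "equal"))
  if (is.null(ids)) ids <- as.character(seq_along(f_pop1))
  data.frame(id = ids, f_pop1 = f_pop1, f_pop2 = f_pop2,
             log2_ratio = R, delta = delta, euclidean = E,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Divergence table straight from genotypes
#'
#' Convenience wrapper: [effect_allele_frequencies()] then [divergence()].
#'
#' @inheritParams effect_allele_frequencies
#' @param continuity_correct see [divergence()].
#' @return divergence data frame; attribute `"populations"` as above.
#' @export
divergence_table <- function(gm, manifest, populations,
                             continuity_correct = TRUE) {
  f <- effect_allele_frequencies(gm, manifest, populations)
  out <- divergence(f$f_pop1, f$f_pop2, f$n1, f$n2, ids = f$id,
                    continuity_correct = continuity_correct)
  attr(out, "populations") <- populations
  out
}

#' Ranked report of pharmaSNPs of interest
#'
#' Joins divergence records to their clinical annotations, restricts to
#' the requested evidence tiers, keeps records whose composite divergence
#' strictly exceeds `e_threshold` (a record at exactly the threshold is
#' excluded), and ranks by decreasing divergence (ties broken by rsID for
#' deterministic reports).
#'
#' @param records divergence data frame ([divergence()] /
#'   [divergence_table()]).
#' @param ann annotation data frame.
#' @param e_threshold composite-divergence cutoff (strict `>`).
#' @param levels evidence tiers to keep; default the high-confidence
#'   tiers 1A/1B/2A/2B.
#' @return data frame `id`, `gene`, `drug`, `category`, `evidence_level`,
#'   `f_pop1`, `f_pop2`, `log2_ratio`, `delta`, `euclidean`, `direction`,
#'   sorted by decreasing `euclidean`. Records with no matching annotation
#'   are excluded and listed in attribute `"unjoined"`.
#' @export
screen_of_interest <- function(records, ann, e_threshold = 0.5,
                               levels = high_evidence_levels) {
  m <- match(records$id, ann$id)
  unjoined <- records$id[is.na(m)]
  if (length(unjoined) > 0L) {
    message("screen_of_interest: ", length(unjoined),
            " record(s) without annotation excluded: ",
            paste(utils::head(unjoined, 5L), collapse = ", "))
  }
  joined <- cbind(records[!is.na(m), , drop = FALSE],
                  ann[m[!is.na(m)], c("gene", "drug", "category",
                                      "evidence_level"), drop = FALSE])
  keep <- joined$evidence_level %in% levels & joined$euclidean > e_threshold
  out <- joined[keep, c("id", "gene", "drug", "category", "evidence_level",
                        "f_pop1", "f_pop2", "log2_ratio", "delta",
                        "euclidean", "direction"), drop = FALSE]
  out <- out[order(-out$euclidean, out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unjoined") <- unjoined
  out
}
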