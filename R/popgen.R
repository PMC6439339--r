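#' Per-variant allele frequencies and folded MAF
#'
#' The counted-allele frequency is `sum(dosage) / (2 * n_nonmissing)`;
#' the minor allele frequency folds it to `min(f, 1 - f)` so MAF is
#' always at most 0.5. Missing genotypes are excluded from numerator and
#' denominator alike.
#'
#' @param gm a [genotype_matrix()].
#' @param samples optional sample IDs (or indices) to restrict to.
#' @return data frame with `id`, `freq` (counted allele), `maf`,
#'   `n_used` (non-missing samples). Variants with no non-missing
#'   genotype get `NA` frequencies and are flagged in the `defined`
#'   column.
#' @export
compute_maf <- function(gm, samples = NULL) {
  if (!is.null(samples)) gm <- subset_gm(gm, samples = samples)
  d <- gm$dosage
  n_used <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * n_used)
  f[n_used == 0L] <- NA_real_
  data.frame(id = variant_ids(gm), freq = f, maf = pmin(f, 1 - f),
             n_used = n_used, defined = n_used > 0L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Counted-allele frequency per population
#'
#' @param gm a [genotype_matrix()].
#' @param manifest population manifest (see [read_manifest()]).
#' @param populations populations to include; default all in the manifest.
#' @return variants x populations matrix of counted-allele frequencies
#'   (`NA` where a population has no non-missing genotype).
#' @export
allele_freq_by_pop <- function(gm, manifest, populations = NULL) {
  check_manifest(gm, manifest)
  if (is.null(populations)) populations <- unique(manifest$population)
  absent <- setdiff(populations, manifest$population)
  if (length(absent) > 0L) {
    stop("population(s) absent from manifest: ", paste(absent, collapse = ", "))
  }
  out <- matrix(NA_real_, n_variants(gm), length(populations),
                dimnames = list(variant_ids(gm), populations))
  for (p in populations) {
    ids <- manifest$sample[manifest$population == p]
    ids <- intersect(ids, sample_ids(gm))
    d <- gm$dosage[ids, , drop = FALSE]
    n_used <- colSums(!is.na(d))
    f <- colSums(d, na.rm = TRUE) / (2 * n_used)
    f[n_used == 0L] <- NA_real_
    out[, p] <- f
  }
  out
}

#' Wright's fixation index from per-population allele frequencies
#'
#' `F_ST = sigma^2 / (pbar (1 - pbar))` where `pbar` is the unweighted
#' mean of the per-population frequencies and `sigma^2` their variance.
#' The population (divide-by-N) variance convention is the default;
#' `var_method = "sample"` gives the N-1 convention. F_ST is undefined
#' (NA, excluded from set averages) when `pbar` is 0 or 1 — a variant
#' monomorphic in every population carries no differentiation signal.
#'
#' @param freqs numeric matrix (variants x populations) or vector (one
#'   variant) of per-population frequencies of the same allele.
#' @param var_method `"population"` (divide by N, default) or `"sample"`.
#' @return data frame with `id` (row names of `freqs` if present),
#'   `pbar`, `sigma2`, `fst`, `defined`.
#' @export
compute_fst <- function(freqs, var_method = c("population", "sample")) {
  var_method <- match.arg(var_method)
  if (is.vector(freqs)) freqs <- matrix(freqs, nrow = 1)
  if (ncol(freqs) < 2L) stop("F_ST needs frequencies from at least 2 populations")
  npop <- rowSums(!is.na(freqs))
  if (any(npop < 2L)) {
    warning(sum(npop < 2L), " variant(s) with < 2 defined populations: F_ST NA")
  }
  pbar <- rowMeans(freqs, na.rm = TRUE)
  dev2 <- (freqs - pbar)^2
  denom_n <- if (var_method == "population") npop else npop - 1L
  sigma2 <- rowSums(dev2, na.rm = TRUE) / denom_n
  fst <- sigma2 / (pbar * (1 - pbar))
  undef <- npop < 2L | pbar <= 0 | pbar >= 1
  fst[undef] <- NA_real_
  ids <- rownames(freqs)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(freqs)))
  data.frame(id = ids, pbar = unname(pbar), sigma2 = unname(sigma2),
             fst = unname(fst), defined = !undef,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean F_ST over a variant set, skipping undefined variants
#' @param fst_table result of [compute_fst()].
#' @return scalar mean of the defined F_ST values.
#' @export
mean_fst <- function(fst_table) mean(fst_table$fst, na.rm = TRUE)

#' Greedy windowed LD pruning on dosage correlation
#'
#' Slides a `window`-variant window along the (chrom, pos)-ordered
#' variants in steps of `step` variants. Within each window, pairwise
#' squared dosage correlation r2 is computed over pairwise-complete
#' samples (composite LD — no phase needed); while any pair exceeds
#' `r2_threshold`, the member with the lower MAF is removed (ties go to
#' the later position). Zero-variance variants have r2 defined as 0
#' against everything. Output is deterministic.
#'
#' @param gm a [genotype_matrix()].
#' @param r2_threshold squared-correlation threshold above which a pair is
#'   pruned.
#' @param window window size in variants.
#' @param step stride in variants.
#' @return character vector of retained variant IDs, in position order.
#' @export
ld_prune <- function(gm, r2_threshold = 0.5, window = 50L, step = 5L) {
  ord <- order(gm$variants$chrom, gm$variants$pos)
  gm <- subset_gm(gm, variants = ord)
  M <- n_variants(gm)
  if (M == 1L) return(variant_ids(gm))
  maf <- compute_maf(gm)$maf
  alive <- rep(TRUE, M)
  d <- gm$dosage

  starts <- seq(1L, M, by = step)
  for (s in starts) {
    idx <- which(alive)
    idx <- idx[idx >= s & idx < s + window]
    if (length(idx) < 2L) next
    r2 <- suppressWarnings(stats::cor(d[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))^2
    r2[!is.finite(r2)] <- 0          # zero variance / no shared samples
    diag(r2) <- 0
    while (TRUE) {
      mx <- max(r2)
      if (mx <= r2_threshold) break
      hit <- which(r2 == mx, arr.ind = TRUE)[1L, ]   # first offending pair
      a <- idx[hit[1L]]; b <- idx[hit[2L]]
      drop_v <- if (maf[a] < maf[b]) a
                else if (maf[b] < maf[a]) b
                else max(a, b)                        # tie: later position
      alive[drop_v] <- FALSE
      k <- which(idx == drop_v)
      r2[k, ] <- 0; r2[, k] <- 0
    }
    if (s + window > M) break
  }
  variant_ids(gm)[alive]
}

#' Identity-by-state distance matrix
#'
#' `d(a, b) = sum_j |g_aj - g_bj| / (2 * m_ab)` where `m_ab` counts
#' variants non-missing in both genomes — the allelic Hamming distance as
#' a fraction of compared alleles, in `[0, 1]`.
#'
#' @param gm a [genotype_matrix()] with at least 2 samples.
#' @return symmetric numeric matrix with zero diagonal, sample IDs as
#'   dimnames. A sample pair with no shared non-missing variant is an
#'   error.
#' @export
ibs_distance <- function(gm) {
  n <- n_samples(gm)
  if (n < 2L) stop("IBS distance needs at least 2 samples")
  d <- gm$dosage
  if (!anyNA(d)) {
    out <- as.matrix(stats::dist(d, method = "manhattan")) / (2 * ncol(d))
  } else {
    out <- matrix(0, n, n, dimnames = list(sample_ids(gm), sample_ids(gm)))
    for (a in seq_len(n - 1L)) {
      da <- d[a, ]
      for (b in (a + 1L):n) {
        ok <- !is.na(da) & !is.na(d[b, ])
        m <- sum(ok)
        if (m == 0L) {
          stop("no shared non-missing variants between ", sample_ids(gm)[a],
               " and ", sample_ids(gm)[b])
        }
        out[a, b] <- out[b, a] <- sum(abs(da[ok] - d[b, ok])) / (2 * m)
      }
    }
  }
  dimnames(out) <- list(sample_ids(gm), sample_ids(gm))
  out
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Metric MDS via double-centering of squared distances and
#' eigendecomposition, as implemented in base R's `cmdscale`; axes are
#' ordered by decreasing eigenvalue and scaled by the square root of the
#' eigenvalue. On top of that a deterministic sign convention is applied:
#' each axis is flipped, if needed, so its first nonzero loading is
#' positive (eigenvectors are sign-arbitrary).
#'
#' @param dm symmetric distance matrix (or `dist`).
#' @param dims number of dimensions to return.
#' @param neg_eig_tol warn when the most negative eigenvalue exceeds this
#'   fraction of the leading one in magnitude. Allele-sharing distance
#'   matrices are routinely mildly non-Euclidean; small negative
#'   eigenvalues are clamped silently, material distortion is flagged.
#' @return samples x dims coordinate matrix. If the distance matrix has a
#'   substantially negative eigenvalue (not Euclidean-embeddable), a
#'   warning is issued and the offending axes are clamped to zero.
#' @export
classical_mds <- function(dm, dims = 2L, neg_eig_tol = 0.05) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  fit <- stats::cmdscale(stats::as.dist(dm), k = min(dims, n - 1L), eig = TRUE)
  eig <- fit$eig
  if (min(eig) < -neg_eig_tol * max(eig, 1e-12)) {
    warning("distance matrix not Euclidean-embeddable: negative eigenvalue ",
            signif(min(eig), 3), "; clamping")
  }
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < dims) {
    pad <- matrix(0, n, dims - if (is.null(pts)) 0L else ncol(pts))
    pts <- cbind(pts, pad)
  }
  pts <- pts[, seq_len(dims), drop = FALSE]
  for (ax in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, ax]) > 1e-12)
    if (length(nz) > 0L && pts[nz[1L], ax] < 0) pts[, ax] <- -pts[, ax]
  }
  rownames(pts) <- rownames(dm)
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  pts
}

#' Combined allele-frequency table: per-population frequencies, MAF, F_ST
#'
#' One row per variant: counted-allele frequency in every population of
#' the manifest, the pooled folded MAF, the cross-population mean and
#' variance, and Wright's F_ST.
#'
#' @inheritParams allele_freq_by_pop
#' @param var_method forwarded to [compute_fst()].
#' @return data frame.
#' @export
allele_frequency_table <- function(gm, manifest, populations = NULL,
                                   var_method = "population") {
  freqs <- allele_freq_by_pop(gm, manifest, populations)
  fst <- compute_fst(freqs, var_method = var_method)
  pooled <- compute_maf(gm, samples = intersect(manifest$sample, sample_ids(gm)))
  out <- data.frame(id = rownames(freqs), as.data.frame(freqs),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$maf <- pooled$maf[match(out$id, pooled$id)]
  out$pbar <- fst$pbar
  out$sigma2 <- fst$sigma2
  out$fst <- fst$fst
  rownames(out) <- NULL
  out
}
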