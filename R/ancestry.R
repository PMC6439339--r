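#' Supervised ancestry estimation against a reference panel
#'
#' Per individual, maximizes the binomial admixture log-likelihood
#' `L(q) = sum_j [ g_j log p_j(q) + (2 - g_j) log(1 - p_j(q)) ]` with
#' `p_j(q) = sum_k q_k f_kj`, over the probability simplex, where `f_kj`
#' are known per-component allele frequencies from the reference panel.
#' Optimization uses the multiplicative EM update
#' `q_k <- (q_k / 2M') sum_j [ g_j f_kj / p_j + (2 - g_j)(1 - f_kj) /
#' (1 - p_j) ]` (`M'` = non-missing variants for that individual),
#' initialized uniform; the update preserves the simplex exactly and the
#' likelihood is non-decreasing at every step. This is the supervised
#' counterpart of K-cluster admixture estimation: with labelled reference
#' panels the component allele frequencies are fixed rather than jointly
#' estimated.
#'
#' @param gm a [genotype_matrix()]; dosages must count the same allele the
#'   panel frequencies describe (the alt allele for simulated panels).
#' @param panel matrix of per-component allele frequencies (variants x
#'   components, row names = variant IDs), e.g. `simulate_reference_panel()$freq`
#'   or [read_panel()]. Frequencies are clipped to `[1e-6, 1 - 1e-6]` to
#'   keep the log-likelihood finite.
#' @param tol convergence threshold on the per-individual log-likelihood
#'   increase.
#' @param max_iter iteration cap.
#' @param trace if `TRUE`, attach the iterations x individuals matrix of
#'   log-likelihoods as attribute `"trace"` (used to verify monotonicity).
#' @return object of class `ancestry_fractions`: list with `Q`
#'   (individuals x components, rows summing to 1), `loglik`,
#'   `iterations`, `converged`.
#' @export
estimate_ancestry <- function(gm, panel, tol = 1e-6, max_iter = 2000L,
                              trace = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  panel <- as.matrix(panel)
  shared <- intersect(variant_ids(gm), rownames(panel))
  if (length(shared) < 10L) {
    stop("only ", length(shared), " variants shared with the panel; need >= 10")
  }
  gm <- subset_gm(gm, variants = shared)
  Fm <- panel[shared, , drop = FALSE]
  Fm <- pmin(pmax(Fm, 1e-6), 1 - 1e-6)
  K <- ncol(Fm)
  n <- n_samples(gm)

  G <- gm$dosage
  W <- !is.na(G)
  Mprime <- rowSums(W)
  if (any(Mprime == 0L)) {
    stop("individual(s) with no genotypes shared with the panel: ",
         paste(utils::head(sample_ids(gm)[Mprime == 0L], 5L), collapse = ", "))
  }
  Gz <- G; Gz[!W] <- 0L
  G2z <- 2L - G; G2z[!W] <- 0L
  storage.mode(Gz) <- "double"; storage.mode(G2z) <- "double"

  Q <- matrix(1 / K, n, K, dimnames = list(sample_ids(gm), colnames(Fm)))
  if (K == 1L) {
    ll <- .admix_loglik(Q, Fm, Gz, G2z)
    return(structure(list(Q = Q, loglik = ll,
                          iterations = rep(0L, n),
                          converged = rep(TRUE, n)),
                     class = "ancestry_fractions"))
  }

  ll <- .admix_loglik(Q, Fm, Gz, G2z)
  if (any(!is.finite(ll))) {
    stop("non-finite log-likelihood at initialization; check panel frequencies")
  }
  done <- rep(FALSE, n)
  iters <- rep(NA_integer_, n)
  tr <- if (trace) list(ll) else NULL

  for (it in seq_len(max_iter)) {
    P <- Q %*% t(Fm)
    A <- (Gz / P) %*% Fm
    B <- (G2z / (1 - P)) %*% (1 - Fm)
    Qn <- Q * (A + B) / (2 * Mprime)
    Qn <- Qn / rowSums(Qn)            # guard float drift; exact fixed point sums to 1
    act <- !done
    Q[act, ] <- Qn[act, ]
    ll_new <- .admix_loglik(Q, Fm, Gz, G2z)
    if (any(!is.finite(ll_new))) {
      j <- which(!is.finite(ll_new))[1L]
      stop("non-finite log-likelihood for individual ", sample_ids(gm)[j])
    }
    if (trace) tr[[it + 1L]] <- ll_new
    newly <- act & (ll_new - ll < tol)
    iters[newly] <- it
    done <- done | newly
    ll <- ll_new
    if (all(done)) break
  }
  iters[is.na(iters)] <- max_iter

  out <- structure(list(Q = Q, loglik = ll, iterations = iters,
                        converged = done),
                   class = "ancestry_fractions")
  if (trace) attr(out, "trace") <- do.call(rbind, tr)
  out
}

.admix_loglik <- function(Q, Fm, Gz, G2z) {
  P <- Q %*% t(Fm)
  rowSums(Gz * log(P) + G2z * log1p(-P))
}

#' @export
print.ancestry_fractions <- function(x, ...) {
  cat("ancestry_fractions: ", nrow(x$Q), " individuals x ", ncol(x$Q),
      " components (", paste(colnames(x$Q), collapse = ", "), ")\n", sep = "")
  cat(sprintf("  mean fractions: %s\n",
              paste(sprintf("%s=%.3f", colnames(x$Q), colMeans(x$Q)),
                    collapse = " ")))
  invisible(x)
}

#' Ancestry-genotype association regression
#'
#' For each variant, ordinary least squares of an individual ancestry
#' fraction `y` on the effect-allele dosage `x in {0, 1, 2}`:
#' `beta = cov(x, y) / var(x)`, `SE = sqrt(SSE / (n - 2) / Sxx)`, and a
#' two-sided P-value from the t distribution with `n - 2` degrees of
#' freedom, `t = beta / SE`. `beta > 0` means the effect allele is
#' enriched with that ancestry component.
#'
#' Degenerate cases: a constant response gives `beta = 0, P = 1`
#' (flag `constant_y`); a perfect non-constant fit (SSE = 0) gives
#' `SE = 0, P = 0` with flag `degenerate_fit`; a constant genotype is
#' undefined (flag `constant_x`, NA estimates). Raw P-values are reported;
#' Benjamini-Hochberg q-values are available via `adjust = TRUE` but off
#' by default.
#'
#' @param gm an effect-allele-oriented [genotype_matrix()].
#' @param fractions an `ancestry_fractions` object ([estimate_ancestry()])
#'   or a numeric matrix of per-individual fractions (rows named by
#'   sample).
#' @param component component name(s) to regress; default all.
#' @param adjust add a Benjamini-Hochberg `q` column (per component).
#' @return data frame with `id`, `component`, `beta`, `se`, `t`, `p`,
#'   `n`, `flag`.
#' @export
ancestry_association <- function(gm, fractions, component = NULL,
                                 adjust = FALSE) {
  Q <- if (inherits(fractions, "ancestry_fractions")) fractions$Q else as.matrix(fractions)
  common <- intersect(sample_ids(gm), rownames(Q))
  if (length(common) < 3L) stop("need >= 3 samples with both genotype and ancestry")
  gm <- subset_gm(gm, samples = common)
  Q <- Q[common, , drop = FALSE]
  if (is.null(component)) component <- colnames(Q)
  missing_c <- setdiff(component, colnames(Q))
  if (length(missing_c) > 0L) stop("unknown component(s): ",
                                   paste(missing_c, collapse = ", "))

  res <- list()
  for (comp in component) {
    y_all <- Q[, comp]
    rows <- lapply(seq_len(n_variants(gm)), function(j) {
      x <- gm$dosage[, j]
      ok <- !is.na(x)
      .ols_one(variant_ids(gm)[j], comp, x[ok], y_all[ok])
    })
    res[[comp]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  if (adjust) {
    out$q <- stats::ave(out$p, out$component,
                        FUN = function(p) stats::p.adjust(p, "BH"))
  }
  out
}

.ols_one <- function(id, comp, x, y) {
  n <- length(x)
  base <- data.frame(id = id, component = comp, beta = NA_real_,
                     se = NA_real_, t = NA_real_, p = NA_real_,
                     n = n, flag = "", stringsAsFactors = FALSE)
  if (n < 3L) stop("variant ", id, ": fewer than 3 samples with genotypes")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) { base$flag <- "constant_x"; return(base) }
  syy <- sum((y - mean(y))^2)
  if (syy == 0) {
    base$beta <- 0; base$se <- 0; base$t <- 0; base$p <- 1
    base$flag <- "constant_y"
    return(base)
  }
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  sse <- syy - beta^2 * sxx
  # guard tiny negative from cancellation
  sse <- max(sse, 0)
  base$beta <- beta
  if (sse < 1e-14 * syy) {
    base$se <- 0; base$t <- Inf * sign(beta); base$p <- 0
    base$flag <- "degenerate_fit"
    return(base)
  }
  se <- sqrt(sse / (n - 2) / sxx)
  base$se <- se
  base$t <- beta / se
  base$p <- 2 * stats::pt(-abs(base$t), df = n - 2)
  base
}
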