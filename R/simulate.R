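#' Simulation configuration for synthetic admixed cohorts
#'
#' Defines the generative model used throughout the package's tests and
#' demos: ancestral allele frequencies per variant are drawn from
#' `Uniform(base_freq[1], base_freq[2])`, per-component frequencies follow
#' the Balding-Nichols model with differentiation `diff` (F), individual
#' ancestry vectors are Dirichlet within each cohort, and genotypes are
#' Binomial(2, p) at the individual's admixed frequency (Hardy-Weinberg by
#' construction; pooling cohorts produces the Wahlund homozygote excess).
#'
#' Default cohorts emulate two admixed populations with distinct three-way
#' ancestry profiles over components (African, European, Native American):
#' an Antioquia-like cohort centred on 7/61/32 percent and a Choco-like
#' cohort centred on 76/11/13 percent, with Dirichlet concentration 50 so
#' individual ancestry varies realistically around the cohort mean while
#' remaining recoverable.
#'
#' @param K number of ancestral components.
#' @param M number of variants.
#' @param components component names, length `K`; the canonical order is
#'   African, European, Native American.
#' @param cohorts list of cohorts, each `list(name=, n=, alpha=, role=)`
#'   with `alpha` a strictly positive Dirichlet parameter vector of
#'   length `K` and `role` one of `"study"`/`"reference"`.
#' @param diff Balding-Nichols differentiation F, scalar or length `K`,
#'   each in `[0, 1)`.
#' @param base_freq range (low, high) of the ancestral mean frequency.
#' @param pharma_fraction share of variants emitted with a pharmaSNP
#'   annotation.
#' @param discordance_rate probability that a re-called genotype differs
#'   from truth in [inject_discordance()].
#' @param seed integer seed from which all randomness flows; identical
#'   configs give bit-identical output.
#' @return validated config, class `sim_config`.
#' @export
sim_config <- function(K = 3L, M = 5000L,
                       components = c("AFR", "EUR", "NAM"),
                       cohorts = list(
                         list(name = "antioquia", n = 100L,
                              alpha = c(0.07, 0.61, 0.32) * 50, role = "study"),
                         list(name = "choco", n = 100L,
                              alpha = c(0.76, 0.11, 0.13) * 50, role = "study")
                       ),
                       diff = 0.15,
                       base_freq = c(0.05, 0.95),
                       pharma_fraction = 0.05,
                       discordance_rate = 0.023,
                       seed = 1L) {
  K <- as.integer(K); M <- as.integer(M)
  stopifnot(K >= 1L, M >= 1L, length(components) == K)
  diff <- rep_len(diff, K)
  if (any(diff < 0) || any(diff >= 1)) {
    stop("diff (Balding-Nichols F) must lie in [0, 1); F = 1 is degenerate")
  }
  stopifnot(length(base_freq) == 2L, base_freq[1] > 0, base_freq[2] < 1,
            base_freq[1] <= base_freq[2])
  if (pharma_fraction < 0 || pharma_fraction > 1) stop("pharma_fraction outside [0, 1]")
  if (discordance_rate < 0 || discordance_rate > 1) stop("discordance_rate outside [0, 1]")
  for (co in cohorts) {
    if (!all(c("name", "n", "alpha") %in% names(co))) {
      stop("each cohort needs fields name, n, alpha")
    }
    if (length(co$alpha) != K || any(co$alpha <= 0)) {
      stop("cohort '", co$name, "': alpha must be length K and strictly positive")
    }
    if (co$n < 1L) stop("cohort '", co$name, "': n must be >= 1")
  }
  names(cohorts) <- vapply(cohorts, `[[`, "", "name")
  if (anyDuplicated(names(cohorts))) stop("cohort names must be unique")
  structure(list(K = K, M = M, components = components, cohorts = cohorts,
                 diff = diff, base_freq = base_freq,
                 pharma_fraction = pharma_fraction,
                 discordance_rate = discordance_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Dirichlet draws via normalized gammas (no installed package provides this).
.rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  x <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

#' Simulate a reference panel of ancestral allele frequencies
#'
#' For each variant j an ancestral mean frequency p_j is drawn from the
#' configured base law; each component k then gets
#' `f_kj ~ Beta(p_j (1-F_k)/F_k, (1-p_j)(1-F_k)/F_k)` (Balding-Nichols),
#' so that `Var(f_kj | p_j) = F_k p_j (1-p_j)`. `F = 0` returns the
#' ancestral frequency exactly.
#'
#' @param cfg a [sim_config()].
#' @return list with `freq` (M x K matrix of counted/alt-allele
#'   frequencies, columns named by component), `variants` (variant table
#'   as in [genotype_matrix()]) and `ancestral` (the p_j vector).
#' @export
simulate_reference_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  M <- cfg$M; K <- cfg$K
  p <- stats::runif(M, cfg$base_freq[1], cfg$base_freq[2])
  freq <- matrix(NA_real_, M, K, dimnames = list(NULL, cfg$components))
  for (k in seq_len(K)) {
    Fk <- cfg$diff[k]
    freq[, k] <- if (Fk == 0) p else {
      stats::rbeta(M, p * (1 - Fk) / Fk, (1 - p) * (1 - Fk) / Fk)
    }
  }
  # unlinked variants laid out on one synthetic chromosome, 1 kb apart
  nts <- c("A", "C", "G", "T")
  ref <- sample(nts, M, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1L), "")
  variants <- data.frame(
    id = sprintf("rs%07d", seq_len(M)), chrom = "1",
    pos = seq_len(M) * 1000L, ref = ref, alt = unname(alt),
    stringsAsFactors = FALSE
  )
  rownames(freq) <- variants$id
  list(freq = freq, variants = variants, ancestral = p)
}

#' Simulate admixed cohorts from a reference panel
#'
#' Each individual i in cohort c draws an ancestry vector
#' `q_i ~ Dirichlet(alpha_c)`; at variant j the individual's allele
#' frequency is `p_ij = sum_k q_ik f_kj` and the genotype is
#' `g_ij ~ Binomial(2, p_ij)`. The true ancestry vectors are returned for
#' parameter-recovery tests.
#'
#' @param cfg a [sim_config()].
#' @param panel result of [simulate_reference_panel()] with matching
#'   dimensions.
#' @return list with `gm` (a [genotype_matrix()], alt-allele counted),
#'   `manifest` (sample/population/role data frame) and `truth` (n x K
#'   matrix of true ancestry fractions, rows named by sample).
#' @export
simulate_cohort <- function(cfg, panel) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(panel$freq) != cfg$M || ncol(panel$freq) != cfg$K) {
    stop("panel dimensions do not match config")
  }
  set.seed(cfg$seed + 1L)
  dos <- list(); truth <- list(); man <- list()
  for (co in cfg$cohorts) {
    q <- .rdirichlet(co$n, co$alpha)
    ids <- sprintf("%s_%03d", co$name, seq_len(co$n))
    rownames(q) <- ids
    pij <- q %*% t(panel$freq)                       # n x M
    g <- matrix(stats::rbinom(length(pij), 2L, pij),
                nrow = co$n, dimnames = list(ids, NULL))
    dos[[co$name]] <- g
    truth[[co$name]] <- q
    role <- if (is.null(co$role)) "study" else co$role
    man[[co$name]] <- data.frame(sample = ids, population = co$name,
                                 role = role, stringsAsFactors = FALSE)
  }
  dosage <- do.call(rbind, dos)
  truth <- do.call(rbind, truth)
  colnames(truth) <- cfg$components
  gm <- genotype_matrix(dosage, panel$variants)
  list(gm = gm, manifest = do.call(rbind, c(man, make.row.names = FALSE)),
       truth = truth)
}

#' Simulate a pharmaSNP annotation table over panel variants
#'
#' Marks a configured fraction of the panel's variants as pharmaSNPs,
#' assigning genes/drugs from a small synthetic vocabulary, categories and
#' evidence tiers at random, and the effect allele as ref or alt with
#' equal probability (so orientation handling is genuinely exercised).
#'
#' @param cfg a [sim_config()].
#' @param panel result of [simulate_reference_panel()].
#' @return annotation data frame (see [read_annotation()]).
#' @export
simulate_annotations <- function(cfg, panel) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n_pharma <- max(1L, round(cfg$pharma_fraction * cfg$M))
  idx <- sort(sample.int(cfg$M, n_pharma))
  v <- panel$variants[idx, , drop = FALSE]
  effect_is_alt <- stats::runif(n_pharma) < 0.5
  genes <- sprintf("GENE%02d", sample.int(40L, n_pharma, replace = TRUE))
  drugs <- sample(c("drugA", "drugB", "drugC", "drugD", "drugE"),
                  n_pharma, replace = TRUE)
  data.frame(
    id = v$id, gene = genes, drug = drugs,
    category = sample(pharmapop_categories, n_pharma, replace = TRUE),
    evidence_level = sample(pharmapop_evidence_levels, n_pharma,
                            replace = TRUE),
    effect_allele = ifelse(effect_is_alt, v$alt, v$ref),
    non_effect_allele = ifelse(effect_is_alt, v$ref, v$alt),
    stringsAsFactors = FALSE
  )
}

#' Corrupt a call set with a fixed per-genotype discordance rate
#'
#' Each non-missing genotype is independently replaced, with probability
#' `rate`, by one of the two other genotype classes (chosen uniformly).
#' Produces truth/re-call pairs for concordance scoring.
#'
#' @param gm a [genotype_matrix()].
#' @param rate discordance probability in `[0, 1]`.
#' @param seed integer seed.
#' @return A `genotype_matrix`; attribute `"n_changed"` holds the number
#'   of altered cells.
#' @export
inject_discordance <- function(gm, rate, seed) {
  stopifnot(inherits(gm, "genotype_matrix"), rate >= 0, rate <= 1)
  set.seed(as.integer(seed))
  d <- gm$dosage
  idx <- which(!is.na(d))
  hit <- idx[stats::runif(length(idx)) < rate]
  if (length(hit) > 0L) {
    # uniform choice between the two classes other than the current one
    shift <- sample(1:2, length(hit), replace = TRUE)
    d[hit] <- (d[hit] + shift) %% 3L
  }
  out <- genotype_matrix(d, gm$variants, gm$counted_allele)
  attr(out, "n_changed") <- length(hit)
  out
}

#' Simulate a complete study bundle
#'
#' Convenience wrapper running [simulate_reference_panel()],
#' [simulate_cohort()] and [simulate_annotations()] off one config.
#'
#' @param cfg a [sim_config()].
#' @return list with `panel`, `gm`, `manifest`, `truth`, `annotations`.
#' @export
simulate_study <- function(cfg) {
  panel <- simulate_reference_panel(cfg)
  cohort <- simulate_cohort(cfg, panel)
  ann <- simulate_annotations(cfg, panel)
  list(panel = panel, gm = cohort$gm, manifest = cohort$manifest,
       truth = cohort$truth, annotations = ann)
}

#' Write a simulated study to disk as plain-text files
#'
#' Emits `genotypes.vcf`, `manifest.tsv`, `annotations.tsv`,
#' `ancestry_truth.tsv` and `panel_freq.tsv` under `dir`.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    manifest = file.path(dir, "manifest.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "ancestry_truth.tsv"),
    panel = file.path(dir, "panel_freq.tsv")
  )
  write_vcf(study$gm, paths["vcf"])
  write_manifest(study$manifest, paths["manifest"])
  write_annotation(study$annotations, paths["annotations"])
  truth <- data.frame(sample = rownames(study$truth), study$truth,
                      check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  panel <- data.frame(id = rownames(study$panel$freq), study$panel$freq,
                      check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(panel, paths["panel"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read a reference panel frequency table written by [write_study()]
#' @param path TSV with column `id` then one column per component.
#' @return matrix of frequencies with variant-ID row names.
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}
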