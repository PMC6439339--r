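#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' list. With no input paths the pipeline simulates its own study
#' ([simulate_study()]); alternatively supply `vcf`, `manifest`,
#' `annotations` and `panel` paths to run on existing files.
#'
#' @param seed master seed; every stochastic stage derives from it.
#' @param sim a [sim_config()] for the simulated-input mode (its seed is
#'   overridden by `seed`). Ignored when `inputs` are given.
#' @param inputs optional named list of paths: `vcf`, `manifest`,
#'   `annotations`, `panel`, and optionally `truth`.
#' @param populations the two study populations to compare; default the
#'   two cohorts of the simulation config.
#' @param r2_threshold,window,step LD-pruning tunables ([ld_prune()]).
#' @param tol,max_iter ancestry EM tunables ([estimate_ancestry()]).
#' @param e_threshold,evidence_levels screening tunables
#'   ([screen_of_interest()]).
#' @param discordance_rate genotype corruption rate for the concordance
#'   demonstration stage.
#' @param stages character vector of stages to run, a subset of the
#'   default order.
#' @return validated list, class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 17L,
                            sim = sim_config(M = 3000L, cohorts = list(
                              list(name = "antioquia", n = 60L,
                                   alpha = c(0.07, 0.61, 0.32) * 50,
                                   role = "study"),
                              list(name = "choco", n = 60L,
                                   alpha = c(0.76, 0.11, 0.13) * 50,
                                   role = "study")
                            ), seed = seed),
                            inputs = NULL,
                            populations = NULL,
                            r2_threshold = 0.5, window = 50L, step = 5L,
                            tol = 1e-6, max_iter = 2000L,
                            e_threshold = 0.5,
                            evidence_levels = high_evidence_levels,
                            discordance_rate = NULL,
                            stages = c("simulate", "read", "orient", "prune",
                                       "frequencies", "distance", "ancestry",
                                       "divergence", "association",
                                       "concordance")) {
  if (!is.null(inputs)) {
    need <- c("vcf", "manifest", "annotations", "panel")
    missing_in <- setdiff(need, names(inputs))
    if (length(missing_in) > 0L) {
      stop("inputs must name paths for: ", paste(missing_in, collapse = ", "))
    }
    for (p in unlist(inputs)) {
      if (!file.exists(p)) stop("input file does not exist: ", p)
    }
    stages <- setdiff(stages, "simulate")
  } else {
    sim$seed <- as.integer(seed)
  }
  stopifnot(r2_threshold > 0, window >= 2L, step >= 1L, tol > 0,
            e_threshold >= 0)
  if (is.null(discordance_rate)) {
    discordance_rate <- if (is.null(inputs)) sim$discordance_rate else 0.023
  }
  if (is.null(populations) && is.null(inputs)) {
    studies <- vapply(sim$cohorts,
                      function(co) is.null(co$role) || co$role == "study",
                      logical(1))
    populations <- names(sim$cohorts)[studies][1:2]
  }
  if (length(populations) != 2L || anyNA(populations)) {
    stop("config needs exactly two study populations to compare")
  }
  structure(list(seed = as.integer(seed), sim = sim, inputs = inputs,
                 populations = populations, r2_threshold = r2_threshold,
                 window = as.integer(window), step = as.integer(step),
                 tol = tol, max_iter = as.integer(max_iter),
                 e_threshold = e_threshold,
                 evidence_levels = evidence_levels,
                 discordance_rate = discordance_rate, stages = stages),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the arguments of [pipeline_config()];
#' `sim` sub-keys mirror [sim_config()] (cohorts as a list of
#' name/n/alpha/role mappings).
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("seed", "populations", "r2_threshold", "window", "step",
              "tol", "max_iter", "e_threshold", "evidence_levels",
              "discordance_rate", "stages", "inputs")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$sim)) {
    s <- y$sim
    if (!is.null(s$cohorts)) {
      s$cohorts <- lapply(s$cohorts, function(co) {
        # YAML 1.1 reads a bare `n:` key as boolean FALSE; map it back
        bad_n <- names(co) %in% c("FALSE", "no")
        if (!("n" %in% names(co)) && any(bad_n)) names(co)[bad_n][1] <- "n"
        co$alpha <- as.numeric(co$alpha); co
      })
    }
    args$sim <- do.call(sim_config, s)
  }
  do.call(pipeline_config, args)
}

#' Run the full population-pharmacogenomics pipeline
#'
#' Sequences the stages — simulate (optional), read/orient, LD-prune,
#' per-population frequencies and F_ST, IBS distance and MDS, supervised
#' ancestry, divergence screening, ancestry association, and assay
#' concordance — writing every table as TSV under `out_dir` together
#' with a run manifest (stage, parameters, record counts, input file
#' hashes). Outputs are a pure function of (config, inputs): a rerun with
#' the same config is byte-identical.
#'
#' @param config a `pipeline_config` (or path to a YAML config).
#' @param out_dir output directory, created if needed.
#' @return named list of the in-memory stage results, invisibly; files on
#'   disk are the primary product.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(stage, ...) {
    line <- paste0("[", stage, "] ", paste0(..., collapse = ""))
    message(line)
    log_lines <<- c(log_lines, line)
  }
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  run <- function(stage) stage %in% config$stages
  res <- list(config = config)

  # --- simulate -------------------------------------------------------
  if (run("simulate")) {
    study <- simulate_study(config$sim)
    in_dir <- file.path(out_dir, "inputs")
    paths <- write_study(study, in_dir)
    note("simulate", "M=", config$sim$M, " cohorts=",
         paste(names(config$sim$cohorts), collapse = "+"),
         " seed=", config$sim$seed)
    config$inputs <- as.list(paths)
    res$truth <- study$truth
  }
  ins <- config$inputs
  if (is.null(ins)) stop("no inputs: either run the simulate stage or supply paths")
  hashes <- tools::md5sum(unlist(ins))
  note("inputs", paste(basename(names(hashes)), unname(hashes),
                       sep = ":", collapse = " "))

  # --- read -----------------------------------------------------------
  gm <- read_vcf(ins$vcf)
  manifest <- read_manifest(ins$manifest)
  ann <- read_annotation(ins$annotations)
  panel <- read_panel(ins$panel)
  check_manifest(gm, manifest)
  note("read", n_samples(gm), " samples, ", n_variants(gm), " variants, ",
       nrow(ann), " annotations")
  res$gm <- gm; res$manifest <- manifest; res$annotations <- ann

  # --- orient ---------------------------------------------------------
  if (run("orient")) {
    gm_eff <- suppressMessages(orient_to_effect_allele(gm, ann))
    note("orient", n_variants(gm_eff), " pharma variants oriented, ",
         nrow(dropped_variants(gm_eff)), " dropped")
    res$gm_effect <- gm_eff
  }

  # --- prune ----------------------------------------------------------
  keep <- variant_ids(gm)
  if (run("prune")) {
    keep <- ld_prune(gm, config$r2_threshold, config$window, config$step)
    note("prune", length(keep), " of ", n_variants(gm),
         " variants retained (r2>", config$r2_threshold, ")")
    tsv(data.frame(id = keep), "pruned_variants.tsv")
  }
  gm_bg <- subset_gm(gm, variants = keep)

  # --- frequencies / F_ST --------------------------------------------
  if (run("frequencies")) {
    aft_bg <- allele_frequency_table(gm_bg, manifest)
    tsv(aft_bg, "freq_fst_background.tsv")
    if (!is.null(res$gm_effect)) {
      aft_ph <- allele_frequency_table(res$gm_effect, manifest)
      tsv(aft_ph, "freq_fst_pharma.tsv")
      note("frequencies", "mean MAF background=",
           signif(mean(aft_bg$maf, na.rm = TRUE), 4), " pharma=",
           signif(mean(aft_ph$maf, na.rm = TRUE), 4),
           "; mean F_ST background=",
           signif(mean(aft_bg$fst, na.rm = TRUE), 4), " pharma=",
           signif(mean(aft_ph$fst, na.rm = TRUE), 4))
      res$freq_pharma <- aft_ph
    }
    res$freq_background <- aft_bg
  }

  # --- distance / MDS -------------------------------------------------
  if (run("distance")) {
    dm <- ibs_distance(gm_bg)
    coords <- classical_mds(dm, dims = 2L)
    tsv(data.frame(sample = rownames(dm), round(dm, 10), check.names = FALSE),
        "ibs_distance.tsv")
    tsv(data.frame(sample = rownames(coords), round(coords, 10),
                   population = manifest$population[
                     match(rownames(coords), manifest$sample)],
                   check.names = FALSE),
        "mds_coordinates.tsv")
    note("distance", "IBS over ", n_variants(gm_bg), " variants; 2-D MDS")
    res$mds <- coords
  }

  # --- ancestry -------------------------------------------------------
  if (run("ancestry")) {
    anc <- estimate_ancestry(gm_bg, panel, tol = config$tol,
                             max_iter = config$max_iter)
    qdf <- data.frame(sample = rownames(anc$Q), round(anc$Q, 8),
                      population = manifest$population[
                        match(rownames(anc$Q), manifest$sample)],
                      check.names = FALSE, stringsAsFactors = FALSE)
    tsv(qdf, "ancestry_fractions.tsv")
    means <- stats::aggregate(anc$Q, by = list(population = qdf$population),
                              FUN = mean)
    tsv(data.frame(means[1], round(means[-1], 6), check.names = FALSE),
        "ancestry_cohort_means.tsv")
    note("ancestry", "estimated for ", nrow(anc$Q), " individuals; ",
         sum(anc$converged), " converged")
    if (!is.null(res$truth)) {
      mae <- mean(abs(anc$Q[rownames(res$truth), ] - res$truth))
      note("ancestry", "mean abs error vs simulated truth = ", signif(mae, 4))
    }
    res$ancestry <- anc
  }

  # --- divergence screen ---------------------------------------------
  if (run("divergence") && !is.null(res$gm_effect)) {
    div <- divergence_table(res$gm_effect, manifest, config$populations)
    tsv(cbind(div[1], round(div[2:6], 8), div[7]), "divergence.tsv")
    report <- suppressMessages(
      screen_of_interest(div, ann, config$e_threshold, config$evidence_levels))
    tsv(cbind(report[1:5], round(report[6:10], 8), report[11]),
        "snps_of_interest.tsv")
    note("divergence", nrow(report), " of ", nrow(div),
         " pharma variants pass E>", config$e_threshold,
         " at levels ", paste(config$evidence_levels, collapse = "/"))
    res$divergence <- div; res$report <- report
  }

  # --- association ----------------------------------------------------
  if (run("association") && !is.null(res$gm_effect) && !is.null(res$ancestry)) {
    assoc <- ancestry_association(res$gm_effect, res$ancestry)
    tsv(cbind(assoc[1:2], beta = round(assoc$beta, 8),
              se = round(assoc$se, 8), t = round(assoc$t, 6),
              p = signif(assoc$p, 6), assoc[c("n", "flag")]),
        "ancestry_association.tsv")
    note("association", nrow(assoc), " variant x component regressions")
    res$association <- assoc
  }

  # --- concordance ----------------------------------------------------
  if (run("concordance") && !is.null(res$gm_effect)) {
    recalled <- inject_discordance(res$gm_effect, config$discordance_rate,
                                   seed = config$seed + 1000L)
    v1 <- variant_ids(res$gm_effect)[1L]
    truth_calls <- res$gm_effect$dosage[, v1]
    test_calls <- recalled$dosage[, v1]
    cm <- build_confusion(truth_calls, test_calls)
    met <- assay_metrics(cm)
    tsv(data.frame(truth = rep(genotype_classes, each = 3L),
                   test = rep(genotype_classes, 3L),
                   count = as.vector(t(cm$counts))),
        "concordance_confusion.tsv")
    tsv(cbind(met[1], round(met[-1], 8),
              accuracy = round(cm$accuracy, 8)),
        "concordance_metrics.tsv")
    note("concordance", "variant ", v1, ": accuracy ",
         format_percent(cm$accuracy), " over ", cm$n, " samples (",
         attr(recalled, "n_changed"), " cells corrupted at rate ",
         config$discordance_rate, ")")
    res$concordance <- cm
  }

  writeLines(log_lines, file.path(out_dir, "run_manifest.txt"))
  invisible(res)
}
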