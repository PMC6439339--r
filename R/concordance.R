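#' Genotype class vocabulary for assay scoring
#'
#' Calls are scored on three classes, matching how allele-specific PCR
#' products are read: homozygous non-effect, heterozygous, homozygous
#' effect. Effect-allele dosages 0/1/2 map onto the classes in that order.
#' @export
genotype_classes <- c("hom_non_effect", "het", "hom_effect")

#' Coerce calls to the three-class genotype factor
#'
#' @param x named vector: integer dosages in \{0, 1, 2\} or character
#'   class labels from [genotype_classes]; `NA` = missing call.
#' @param context label used in error messages.
#' @return factor with levels [genotype_classes], names preserved.
#' @export
as_genotype_class <- function(x, context = "calls") {
  nm <- names(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% 0:2)
    if (any(bad)) {
      stop(context, ": dosage outside {0, 1, 2} for sample(s) ",
           paste(utils::head(nm[bad], 5L), collapse = ", "))
    }
    out <- factor(genotype_classes[x + 1L], levels = genotype_classes)
  } else {
    x <- as.character(x)
    bad <- !is.na(x) & !(x %in% genotype_classes)
    if (any(bad)) {
      stop(context, ": unknown genotype class '", x[bad][1L],
           "' for sample ", nm[which(bad)[1L]])
    }
    out <- factor(x, levels = genotype_classes)
  }
  names(out) <- nm
  out
}

#' Cross-tabulate two genotype call sets
#'
#' Builds the 3x3 confusion matrix between a truth call set (rows; e.g.
#' sequencing-derived calls) and a test call set (columns; e.g. an
#' allele-specific PCR assay). Samples present in only one set, or with a
#' missing call in either, are dropped and counted — they are not scored
#' as errors.
#'
#' @param truth_calls,test_calls named vectors of calls (see
#'   [as_genotype_class()]); names are sample IDs.
#' @param swap_axes set `TRUE` to make the test set the truth axis.
#' @return object of class `confusion_matrix`: list with `counts` (3x3
#'   integer matrix, rows = truth), `n`, `accuracy` (trace / n),
#'   `n_dropped`.
#' @export
build_confusion <- function(truth_calls, test_calls, swap_axes = FALSE) {
  if (swap_axes) {
    tmp <- truth_calls; truth_calls <- test_calls; test_calls <- tmp
  }
  if (is.null(names(truth_calls)) || is.null(names(test_calls))) {
    stop("call sets must be named by sample ID")
  }
  truth <- as_genotype_class(truth_calls, "truth calls")
  test <- as_genotype_class(test_calls, "test calls")
  common <- intersect(names(truth), names(test))
  truth <- truth[common]; test <- test[common]
  ok <- !is.na(truth) & !is.na(test)
  n_dropped <- (length(unique(c(names(truth_calls), names(test_calls)))) -
                  length(common)) + sum(!ok)
  counts <- table(truth = truth[ok], test = test[ok])
  counts <- matrix(as.integer(counts), 3L, 3L,
                   dimnames = list(truth = genotype_classes,
                                   test = genotype_classes))
  n <- sum(counts)
  if (n == 0L) stop("no scorable sample pairs")
  structure(list(counts = counts, n = n,
                 accuracy = sum(diag(counts)) / n,
                 n_dropped = n_dropped),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix (rows = truth, cols = test), n =", x$n, "\n")
  print(x$counts)
  cat("accuracy:", format_percent(x$accuracy), "\n")
  if (x$n_dropped > 0L) cat("dropped (missing/unmatched):", x$n_dropped, "\n")
  invisible(x)
}

#' Per-class assay performance metrics
#'
#' Standard one-vs-rest metrics per genotype class c:
#' sensitivity `cm[c,c] / row_c`, specificity
#' `(n - row_c - col_c + cm[c,c]) / (n - row_c)`, precision
#' `cm[c,c] / col_c`. A metric with a zero denominator is reported as
#' `NA` (undefined), never as 0.
#'
#' @param cm a `confusion_matrix`.
#' @return data frame with one row per class: `class`, `sensitivity`,
#'   `specificity`, `precision`, plus attribute `"accuracy"`.
#' @export
assay_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- cm$counts; n <- cm$n
  rs <- rowSums(counts); cs <- colSums(counts); dg <- diag(counts)
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(
    class = genotype_classes,
    sensitivity = safe_div(dg, rs),
    specificity = safe_div(n - rs - cs + dg, n - rs),
    precision = safe_div(dg, cs),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "accuracy") <- cm$accuracy
  out
}

#' Format a proportion as a percentage with one decimal
#' @param x proportion in `[0, 1]`.
#' @param digits decimal places.
#' @return character, e.g. `"97.7%"`.
#' @export
format_percent <- function(x, digits = 1L) {
  paste0(formatC(100 * x, format = "f", digits = digits), "%")
}
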