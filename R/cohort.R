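#' Align the three omic layers and the response labels into a cohort
#'
#' Restricts all layers to the samples present in every layer *and* labeled,
#' imposes one common sample ordering, and reports the class balance. Samples
#' missing any molecular layer or the response record are dropped, as the
#' modelling downstream needs complete multi-omics profiles.
#'
#' @param expression,cnv,methylation complete `omics_matrix` objects.
#' @param labels a `response_labels` tibble (see [response_labels()]).
#' @param min_minority_fraction warn when the minority class falls below this
#'   fraction of the cohort (default 0.30); serious imbalance degrades most
#'   classifiers but is not a hard error.
#' @return a `drug_cohort` list with elements `expression`, `cnv`,
#'   `methylation`, `labels`.
#' @export
align_cohort <- function(expression, cnv, methylation, labels,
                         min_minority_fraction = 0.30) {
  stopifnot(inherits(expression, "omics_matrix"), inherits(cnv, "omics_matrix"),
            inherits(methylation, "omics_matrix"))
  if (anyNA(expression) || anyNA(cnv) || anyNA(methylation)) {
    abort("omic layers must be complete (no missing values) before alignment.")
  }
  samples <- Reduce(intersect, list(colnames(expression), colnames(cnv),
                                    colnames(methylation), labels$sample_id))
  if (!length(samples)) abort("no sample is present in all three layers with a label.")
  labels <- labels[match(samples, labels$sample_id), , drop = FALSE]
  counts <- table(labels$response)
  if (any(counts == 0L)) {
    abort("a response class is empty after alignment; cohort unusable.")
  }
  minority <- min(counts) / sum(counts)
  inform(sprintf("align_cohort: %d samples (%d responders / %d non-responders; minority %.2f).",
                 length(samples), counts[["responder"]], counts[["non_responder"]],
                 minority))
  if (minority < min_minority_fraction) {
    warn(sprintf("align_cohort: class imbalance (minority fraction %.2f < %.2f).",
                 minority, min_minority_fraction))
  }
  out <- list(
    expression = restore_omics(unclass(expression)[, samples, drop = FALSE], expression),
    cnv = restore_omics(unclass(cnv)[, samples, drop = FALSE], cnv),
    methylation = restore_omics(unclass(methylation)[, samples, drop = FALSE], methylation),
    labels = labels
  )
  structure(out, class = "drug_cohort")
}

#' @export
print.drug_cohort <- function(x, ...) {
  counts <- table(x$labels$response)
  cat(sprintf(paste0("<drug_cohort> %d samples (%d responders / %d non-responders)\n",
                     "  expression: %d genes; cnv: %d genes; methylation: %d genes\n"),
              nrow(x$labels), counts[["responder"]], counts[["non_responder"]],
              nrow(x$expression), nrow(x$cnv), nrow(x$methylation)))
  invisible(x)
}

#' @rdname align_cohort
#' @param cohort a `drug_cohort`.
#' @export
cohort_samples <- function(cohort) cohort$labels$sample_id

#' Genes observed in all three omic layers of a cohort
#' @param cohort a `drug_cohort`.
#' @return character vector of gene ids.
#' @export
cohort_gene_universe <- function(cohort) {
  Reduce(intersect, list(rownames(cohort$expression), rownames(cohort$cnv),
                         rownames(cohort$methylation)))
}

# restrict a cohort to a sample subset, preserving the given order
subset_cohort <- function(cohort, samples) {
  stopifnot(all(samples %in% cohort_samples(cohort)))
  out <- list(
    expression = restore_omics(unclass(cohort$expression)[, samples, drop = FALSE],
                               cohort$expression),
    cnv = restore_omics(unclass(cohort$cnv)[, samples, drop = FALSE], cohort$cnv),
    methylation = restore_omics(unclass(cohort$methylation)[, samples, drop = FALSE],
                                cohort$methylation),
    labels = cohort$labels[match(samples, cohort$labels$sample_id), , drop = FALSE]
  )
  structure(out, class = "drug_cohort")
}
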