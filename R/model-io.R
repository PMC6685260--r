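#' Save or load a fitted signature model as a directory
#'
#' The model directory holds `signature.tsv` (the selected subpathways, or
#' the signature genes for the pathway-free baseline), `betas.tsv` (the
#' frozen per-gene regression slopes and p-values), `auc_trace.tsv`,
#' `provenance.json` (seeds, parameters, selection summary) and
#' `classifier.rds` (the trained forest).
#'
#' @param model a `signature_model`.
#' @param dir directory path (created if absent).
#' @return `dir` invisibly for the writer; a `signature_model` for the
#'   reader.
#' @export
save_signature_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (model$mode == "gene_without_pathway") {
    readr::write_tsv(tibble::tibble(gene_id = model$signature_genes),
                     file.path(dir, "signature.tsv"), progress = FALSE)
  } else {
    write_subpathways(model$subpathways, file.path(dir, "signature.tsv"))
  }
  readr::write_tsv(model$scores, file.path(dir, "betas.tsv"), progress = FALSE)
  readr::write_tsv(model$auc_trace, file.path(dir, "auc_trace.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(mode = model$mode, best_auc = model$best_auc,
         repeat_index = model$repeat_index,
         signature_genes = model$signature_genes,
         provenance = model$provenance),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  saveRDS(model$classifier, file.path(dir, "classifier.rds"))
  invisible(dir)
}

#' @rdname save_signature_model
#' @export
load_signature_model <- function(dir) {
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  mode <- prov$mode
  subp <- if (mode == "gene_without_pathway") {
    subpathway_row("none", character(0), NA_real_)[0, ]
  } else {
    read_subpathways(file.path(dir, "signature.tsv"))
  }
  scores <- readr::read_tsv(file.path(dir, "betas.tsv"),
                            col_types = readr::cols(gene_id = readr::col_character(),
                                                    .default = readr::col_double()),
                            progress = FALSE)
  trace <- readr::read_tsv(file.path(dir, "auc_trace.tsv"),
                           col_types = readr::cols(), progress = FALSE)
  structure(list(mode = mode, subpathways = subp,
                 signature_genes = as.character(prov$signature_genes),
                 scores = scores,
                 classifier = readRDS(file.path(dir, "classifier.rds")),
                 best_auc = prov$best_auc, repeat_index = prov$repeat_index,
                 auc_trace = trace, provenance = prov$provenance),
            class = "signature_model")
}

#' Read or write a response-label TSV
#'
#' Columns `sample_id` and `label` (values `responder` / `non_responder`),
#' plus an optional `raw` column.
#'
#' @param labels a `response_labels` tibble.
#' @param path file path.
#' @return `path` invisibly for the writer; a `response_labels` tibble for
#'   the reader.
#' @export
write_response_labels <- function(labels, path) {
  out <- tibble::tibble(sample_id = labels$sample_id,
                        label = as.character(labels$response))
  if ("raw" %in% names(labels)) out$raw <- labels$raw
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_response_labels
#' @export
read_response_labels <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), label = readr::col_character(),
    .default = readr::col_guess()), progress = FALSE)
  response_labels(tab$sample_id, tab$label,
                  raw = if ("raw" %in% names(tab)) tab$raw else NULL)
}
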