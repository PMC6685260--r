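#' Tidy a fitted signature model
#'
#' `tidy()` returns one row per selected subpathway (pathway id, member
#' genes, search score, permutation p-value, size); for the pathway-free
#' baseline it returns one row per signature gene with its expression slope.
#' `glance()` returns a one-row model summary. `autoplot()` draws the
#' held-out AUC trace across repeats, marking the selected repeat.
#'
#' @param x a `signature_model` from [select_signature()].
#' @param ... unused.
#' @return a tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @export
tidy.signature_model <- function(x, ...) {
  if (x$mode == "gene_without_pathway") {
    beta <- setNames(x$scores$beta_expression, x$scores$gene_id)
    return(tibble::tibble(gene_id = x$signature_genes,
                          beta_expression = unname(beta[x$signature_genes])))
  }
  out <- x$subpathways
  out$subpathway_id <- make.unique(out$pathway_id, sep = ".")
  dplyr::select(out, "subpathway_id", "pathway_id", "genes", "score",
                "size", "p_value")
}

#' @rdname tidy.signature_model
#' @export
glance.signature_model <- function(x, ...) {
  tibble::tibble(mode = x$mode,
                 best_auc = x$best_auc,
                 repeat_index = x$repeat_index,
                 n_repeats = nrow(x$auc_trace),
                 n_subpathways = nrow(x$subpathways),
                 n_signature_genes = length(x$signature_genes),
                 mean_auc = mean(x$auc_trace$test_auc),
                 n_empty_repeats = sum(x$auc_trace$empty),
                 base_seed = x$provenance$base_seed)
}

#' @rdname tidy.signature_model
#' @param object a `signature_model`.
#' @export
autoplot.signature_model <- function(object, ...) {
  trace <- object$auc_trace
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$repeat_index, y = .data$test_auc)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$empty)) +
    ggplot2::geom_point(data = trace[object$repeat_index, ],
                        colour = "red", size = 3, shape = 1, stroke = 1.2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "grey80"),
                                 name = "empty signature") +
    ggplot2::labs(x = "repeat", y = "held-out AUC",
                  title = sprintf("Signature selection trace (%s)", object$mode),
                  subtitle = sprintf("selected repeat %d, AUC %.3f",
                                     object$repeat_index, object$best_auc)) +
    ggplot2::theme_minimal()
}

#' Plot per-gene combined scores
#'
#' Histogram of the combined multi-omics gene scores, optionally highlighting
#' a gene set (e.g. an embedded truth set or a signature).
#'
#' @param scores tibble from [score_genes()].
#' @param highlight optional character vector of gene ids.
#' @return a ggplot.
#' @export
plot_gene_scores <- function(scores, highlight = NULL) {
  scores$highlighted <- scores$gene_id %in% (highlight %||% character())
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "white") +
    ggplot2::labs(x = "combined score  -sum(ln p)", y = "genes") +
    ggplot2::theme_minimal()
  if (any(scores$highlighted)) {
    p <- p + ggplot2::geom_rug(data = scores[scores$highlighted, ],
                               colour = "red")
  }
  p
}
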