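#' Per-sample subpathway activity at one omic layer
#'
#' For sample p, let `Y_i = X_i * beta_i` over the N genes of the layer, with
#' `beta_i` the univariate logistic slope of gene i at that layer. The
#' activity of a subpathway with n member genes present in the layer is
#'
#' `Z_sp = (mean(Y, subpathway) - mean(Y, all genes)) * sqrt(n) / sigma_p`
#'
#' where `sigma_p` is the population standard deviation of the `Y_i` in that
#' sample. The statistic contrasts the coefficient-weighted subpathway values
#' against the sample-wide background and is invariant to positive rescaling
#' of the omic matrix. Member genes absent from the layer are dropped from n;
#' `sigma_p = 0` or `n = 0` yields 0 with a warning.
#'
#' @param matrix an `omics_matrix` for the layer.
#' @param betas named numeric vector of per-gene slopes covering the layer's
#'   genes.
#' @param genes subpathway member genes (character vector), or a one-row
#'   subpathway tibble.
#' @param sample a sample id present in `matrix`.
#' @return scalar activity.
#' @export
subpathway_activity <- function(matrix, betas, genes, sample) {
  if (!sample %in% colnames(matrix)) abort(sprintf("unknown sample '%s'.", sample))
  if (is.data.frame(genes)) genes <- genes$genes[[1L]]
  acts <- activity_layer(matrix, betas, list(genes))
  unname(acts[1L, sample])
}

# vectorised Z_sp over all samples for a list of gene sets, one omic layer
activity_layer <- function(matrix, betas, gene_sets) {
  mat <- unclass(matrix)
  all_genes <- rownames(mat)
  b <- betas[all_genes]
  if (anyNA(b)) {
    abort(paste0("gene(s) without a coefficient: ",
                 paste(head(all_genes[is.na(b)], 5L), collapse = ", ")))
  }
  Y <- mat * as.vector(b)
  mu_all <- colMeans(Y)
  sigma_p <- sqrt(colMeans(Y^2) - mu_all^2)
  sigma_p <- pmax(sigma_p, 0)  # guard tiny negative from rounding
  out <- matrix(0, nrow = length(gene_sets), ncol = ncol(mat),
                dimnames = list(NULL, colnames(mat)))
  for (i in seq_along(gene_sets)) {
    members <- intersect(gene_sets[[i]], all_genes)
    n <- length(members)
    dropped <- setdiff(gene_sets[[i]], all_genes)
    if (length(dropped)) {
      inform(sprintf("activity: %d subpathway gene(s) absent from the %s layer dropped.",
                     length(dropped), omic_kind(matrix)))
    }
    if (n == 0L) {
      warn("activity: subpathway has no genes in this layer; activity set to 0.")
      next
    }
    mu_sub <- colMeans(Y[members, , drop = FALSE])
    zero_sd <- sigma_p == 0
    if (any(zero_sd)) {
      warn(sprintf("activity: sigma_p = 0 in %d sample(s); activity set to 0 there.",
                   sum(zero_sd)))
    }
    vals <- (mu_sub - mu_all) * sqrt(n) / ifelse(zero_sd, Inf, sigma_p)
    out[i, ] <- vals
  }
  out
}

#' Build the integrated subpathway activity matrix
#'
#' Computes the per-sample activity of every subpathway at each requested
#' omic layer (using that layer's regression slopes from the gene score
#' table) and stacks the per-layer matrices row-wise. Row names are
#' `subpathway_id:omic`, where subpathway ids are `pathway_id` made unique.
#' Deterministic: no randomness is involved.
#'
#' @param cohort a `drug_cohort`.
#' @param scores gene score tibble from [score_genes()] (provides the betas).
#' @param subpathways subpathway tibble (e.g. from [find_subpathways()]).
#' @param omics layers to include (default all three).
#' @return numeric matrix, `length(omics) * nrow(subpathways)` rows by
#'   samples.
#' @export
build_activity_matrices <- function(cohort, scores, subpathways,
                                    omics = c("expression", "cnv", "methylation")) {
  if (!nrow(subpathways)) abort("no subpathways supplied.")
  ids <- make.unique(subpathways$pathway_id, sep = ".")
  gene_sets <- subpathways$genes
  any_present <- vapply(gene_sets, function(gs) {
    any(vapply(omics, function(om) any(gs %in% rownames(cohort[[om]])), logical(1L)))
  }, logical(1L))
  if (any(!any_present)) {
    abort(paste0("subpathway(s) with no genes in any layer: ",
                 paste(ids[!any_present], collapse = ", ")))
  }
  blocks <- lapply(omics, function(om) {
    betas <- setNames(scores[[paste0("beta_", om)]], scores$gene_id)
    layer <- cohort[[om]]
    # N spans the genes detected in this layer that carry a fitted slope
    scored <- intersect(rownames(layer), scores$gene_id)
    if (!length(scored)) abort(sprintf("no scored gene in the %s layer.", om))
    layer <- restore_omics(unclass(layer)[scored, , drop = FALSE], layer)
    block <- activity_layer(layer, betas, gene_sets)
    rownames(block) <- paste(ids, om, sep = ":")
    block
  })
  do.call(rbind, blocks)
}
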