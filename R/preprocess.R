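#' Remove genes with too many zero expression values
#'
#' Drops genes whose expression is zero in strictly more than
#' `zero_fraction` of samples (default 20%), keeping the survivors in their
#' original order. Idempotent on its own output.
#'
#' @param x an expression `omics_matrix`.
#' @param zero_fraction maximum tolerated fraction of zero values per gene.
#' @return the filtered `omics_matrix`.
#' @export
filter_expression <- function(x, zero_fraction = 0.20) {
  stopifnot(inherits(x, "omics_matrix"))
  if (omic_kind(x) != "expression") {
    abort("filter_expression() applies to the expression layer only.")
  }
  frac_zero <- rowMeans(x == 0, na.rm = TRUE)
  keep <- frac_zero <= zero_fraction
  if (!any(keep)) abort("all genes removed by the zero-fraction filter; layer unusable.")
  restore_omics(unclass(x)[keep, , drop = FALSE], x)
}

#' K-nearest-neighbour imputation over matrix rows
#'
#' Fills missing cells of a numeric matrix by averaging the `k` nearest rows
#' (Euclidean distance over the columns observed in both rows, normalised by
#' the number of shared columns) that carry a value in the missing cell's
#' column. Falls back to the column mean when no neighbour is usable.
#'
#' @param mat numeric matrix, possibly with `NA`s.
#' @param k number of neighbours (default 10).
#' @return the matrix with all `NA`s filled.
#' @export
impute_knn <- function(mat, k = 10L) {
  if (!anyNA(mat)) return(mat)
  obs <- !is.na(mat)
  col_means <- colMeans(mat, na.rm = TRUE)
  out <- mat
  need <- which(rowSums(!obs) > 0L)
  for (i in need) {
    # mean squared difference over shared observed columns
    shared <- obs & rep(obs[i, ], each = nrow(mat))
    diffs <- sweep(mat, 2L, mat[i, ], "-")
    diffs[!shared] <- NA_real_
    d2 <- rowMeans(diffs^2, na.rm = TRUE)
    d2[i] <- Inf
    d2[rowSums(shared) == 0L] <- Inf
    for (j in which(!obs[i, ])) {
      cand <- which(obs[, j] & is.finite(d2))
      if (!length(cand)) {
        out[i, j] <- col_means[j]
        next
      }
      nn <- cand[order(d2[cand])][seq_len(min(k, length(cand)))]
      out[i, j] <- mean(mat[nn, j])
    }
  }
  out
}

#' Preprocess CpG-level methylation into a gene-level matrix
#'
#' Applies the standard methylation cleaning chain: CpG sites whose beta
#' values are missing in strictly more than `na_fraction` of samples are
#' dropped, the remaining missing betas are imputed by k-nearest-neighbour
#' over CpG profiles, and genes with several surviving CpGs get the arithmetic
#' mean beta per sample. CpGs without a gene assignment, and genes whose CpGs
#' were all dropped, are omitted (with a message).
#'
#' @param cpg_matrix numeric CpG x sample matrix (betas in \[0,1\] or `NA`),
#'   or a methylation `omics_matrix` whose rows are CpG ids.
#' @param cpg_to_gene named character vector mapping CpG id to gene id, or a
#'   two-column data frame (`cpg_id`, `gene_id`).
#' @param na_fraction maximum tolerated missing fraction per CpG.
#' @param k_impute neighbours for [impute_knn()].
#' @return a complete gene-level methylation `omics_matrix`.
#' @export
preprocess_methylation <- function(cpg_matrix, cpg_to_gene,
                                   na_fraction = 0.20, k_impute = 10L) {
  mat <- unclass(cpg_matrix)
  if (is.data.frame(cpg_to_gene)) {
    map <- setNames(as.character(cpg_to_gene[[2L]]), as.character(cpg_to_gene[[1L]]))
  } else {
    map <- cpg_to_gene
  }
  keep <- rowMeans(is.na(mat)) <= na_fraction
  if (!any(keep)) abort("no CpG site survives the missing-fraction filter.")
  dropped <- sum(!keep)
  if (dropped) inform(sprintf("preprocess_methylation: dropped %d CpG site(s) with > %.0f%% missing betas.",
                              dropped, 100 * na_fraction))
  mat <- mat[keep, , drop = FALSE]
  mat <- impute_knn(mat, k = k_impute)
  genes <- unname(map[rownames(mat)])
  unmapped <- is.na(genes)
  if (any(unmapped)) {
    inform(sprintf("preprocess_methylation: %d CpG site(s) without a gene mapping omitted.",
                   sum(unmapped)))
    mat <- mat[!unmapped, , drop = FALSE]
    genes <- genes[!unmapped]
  }
  if (!nrow(mat)) abort("no mapped CpG site survives preprocessing.")
  lost <- setdiff(unique(unname(map)), unique(genes))
  if (length(lost)) {
    inform(sprintf("preprocess_methylation: %d gene(s) lost all CpG sites.", length(lost)))
  }
  collapsed <- rowsum(mat, group = genes, reorder = FALSE) /
    as.vector(table(factor(genes, levels = unique(genes))))
  # clamp tiny numeric overshoot from imputation averaging
  collapsed[collapsed < 0] <- 0
  collapsed[collapsed > 1] <- 1
  omics_matrix(collapsed, "methylation", allow_na = FALSE)
}

#' Average repeated profiles of the same patient
#'
#' Samples profiled more than once are collapsed to a single column by the
#' per-gene arithmetic mean, yielding one column per patient (in order of
#' first appearance).
#'
#' @param x an `omics_matrix`.
#' @param sample_to_patient named character vector mapping every sample id in
#'   `x` to a patient id.
#' @return an `omics_matrix` with one column per patient.
#' @export
collapse_replicates <- function(x, sample_to_patient) {
  stopifnot(inherits(x, "omics_matrix"))
  missing_map <- setdiff(colnames(x), names(sample_to_patient))
  if (length(missing_map)) {
    abort(paste0("sample(s) without a patient mapping: ",
                 paste(missing_map, collapse = ", ")))
  }
  patients <- unname(sample_to_patient[colnames(x)])
  f <- factor(patients, levels = unique(patients))
  collapsed <- t(rowsum(t(unclass(x)), group = f, reorder = FALSE)) /
    rep(as.vector(table(f)), each = nrow(x))
  colnames(collapsed) <- levels(f)
  restore_omics(collapsed, x)
}
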