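#' Construct a single-omic gene-by-sample matrix
#'
#' An `omics_matrix` is a numeric genes x samples matrix tagged with the omic
#' layer it carries (`"expression"`, `"cnv"` or `"methylation"`). Row names are
#' gene identifiers (opaque strings), column names are sample identifiers; both
#' must be unique. Missing values (`NA`) are allowed on input so that the
#' preprocessing filters can act on them; downstream modelling requires a
#' complete matrix.
#'
#' @param values numeric matrix with gene row names and sample column names.
#' @param omic_kind one of `"expression"`, `"cnv"`, `"methylation"`.
#' @param allow_na keep `NA` entries (`TRUE`, the default for raw input)?
#'   Modelling code constructs matrices with `allow_na = FALSE`.
#'
#' @return a matrix of class `omics_matrix` with attribute `omic_kind`.
#' @export
#' @examples
#' m <- matrix(rnorm(6), 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' omics_matrix(m, "cnv")
omics_matrix <- function(values, omic_kind = c("expression", "cnv", "methylation"),
                         allow_na = TRUE) {
  omic_kind <- match.arg(omic_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    abort("`values` must carry gene row names and sample column names.")
  }
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene id(s): ",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  if (anyDuplicated(samples)) {
    abort(paste0("duplicate sample id(s): ",
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  if (!allow_na && anyNA(values)) {
    abort("missing values are not allowed in this omics matrix.")
  }
  if (omic_kind == "methylation") {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1)) {
      abort("methylation beta values must lie in [0, 1].")
    }
  }
  structure(values, omic_kind = omic_kind,
            class = c("omics_matrix", class(values)))
}

#' @rdname omics_matrix
#' @param x an `omics_matrix`.
#' @export
omic_kind <- function(x) {
  attr(x, "omic_kind") %||% abort("not an omics_matrix")
}

#' @export
as.matrix.omics_matrix <- function(x, ...) {
  y <- unclass(x)
  attr(y, "omic_kind") <- NULL
  y
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix: %s> %d genes x %d samples", omic_kind(x),
              nrow(x), ncol(x)))
  if (anyNA(x)) cat(sprintf(" (%d missing)", sum(is.na(x))))
  cat("\n")
  print(head(unclass(x)[, seq_len(min(5L, ncol(x))), drop = FALSE], 5L))
  invisible(x)
}

# rebuild the class/attr after matrix subsetting (base `[` drops them)
restore_omics <- function(values, template) {
  omics_matrix(values, omic_kind(template), allow_na = TRUE)
}

#' Read a single-omic TSV into an `omics_matrix`
#'
#' Expects a tab-separated file whose first column (`gene_id`) holds gene
#' identifiers and whose remaining header fields are sample identifiers. Empty
#' cells and the literal string `NA` are recorded as missing, not zero. A
#' non-numeric body cell is a parse error naming the offending gene and sample.
#'
#' @param path file path.
#' @inheritParams omics_matrix
#' @return an `omics_matrix` with missing markers preserved and the file's
#'   row/column order.
#' @export
read_omics_matrix <- function(path, omic_kind = c("expression", "cnv", "methylation")) {
  omic_kind <- match.arg(omic_kind)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  if (ncol(raw) < 2L) abort(sprintf("'%s': need a gene_id column plus >= 1 sample.", path))
  genes <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  body[body == ""] <- NA_character_
  body[body == "NA"] <- NA_character_
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("'%s': non-numeric value '%s' at gene '%s', sample '%s'.",
                  path, body[bad[1L, , drop = FALSE]], genes[bad[1L, 1L]],
                  colnames(body)[bad[1L, 2L]]))
  }
  dimnames(num) <- list(genes, colnames(body))
  omics_matrix(num, omic_kind)
}

#' Write an `omics_matrix` to TSV
#'
#' Inverse of [read_omics_matrix()]: the first column is `gene_id`, missing
#' entries are written as `NA`. Round-trips are value-exact.
#'
#' @param x an `omics_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path) {
  df <- tibble::as_tibble(unclass(x), rownames = "gene_id")
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}
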