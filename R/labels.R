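#' Response label table
#'
#' Binary drug-response labels are kept as a tibble with columns `sample_id`,
#' `response` (factor with levels `non_responder`, `responder`) and optionally
#' `raw` carrying the original category (RECIST class or GI50 value).
#'
#' @param sample_id character vector of sample identifiers (unique).
#' @param response character/factor vector of `"responder"` / `"non_responder"`.
#' @param raw optional vector of raw categories or values.
#' @return a `response_labels` tibble.
#' @export
response_labels <- function(sample_id, response, raw = NULL) {
  if (anyDuplicated(sample_id)) abort("duplicate sample ids in labels.")
  response <- factor(as.character(response), levels = c("non_responder", "responder"))
  if (anyNA(response)) abort("labels must be 'responder' or 'non_responder'.")
  out <- tibble::tibble(sample_id = as.character(sample_id), response = response)
  if (!is.null(raw)) out$raw <- raw
  class(out) <- c("response_labels", class(out))
  out
}

#' Label clinical samples from RECIST categories
#'
#' Complete response (CR) and partial response (PR) become responders; stable
#' disease (SD) and progressive disease (PD) become non-responders. Samples
#' with any other category are dropped with a warning.
#'
#' @param raw named character vector (names = sample ids, values = RECIST
#'   category), or a two-column data frame (`sample_id`, `category`).
#' @return a `response_labels` tibble.
#' @export
#' @examples
#' label_recist(c(s1 = "CR", s2 = "PD"))
label_recist <- function(raw) {
  if (is.data.frame(raw)) raw <- setNames(as.character(raw[[2L]]), as.character(raw[[1L]]))
  cat_up <- toupper(trimws(raw))
  known <- cat_up %in% c("CR", "PR", "SD", "PD")
  if (any(!known)) {
    warn(sprintf("label_recist: dropped %d sample(s) with unrecognised category (%s).",
                 sum(!known), paste(unique(raw[!known]), collapse = ", ")))
  }
  if (!any(known)) abort("no sample carries a recognised RECIST category.")
  resp <- ifelse(cat_up[known] %in% c("CR", "PR"), "responder", "non_responder")
  response_labels(names(raw)[known], resp, raw = unname(raw[known]))
}

#' Label cell lines from processed GI50 drug sensitivities
#'
#' Processed GI50 is \eqn{-\log_{10}} of the concentration inhibiting 50% of
#' growth; higher values mean greater sensitivity. A drug whose GI50 is
#' missing in strictly more than `drug_na_fraction` of the cell lines is
#' excluded outright (error). Otherwise, with `n` non-missing values and
#' `k` set either to `ceiling(top_fraction * n)` (quantile mode, default
#' top/bottom 25%) or to the explicit `top_k` (validation-style top/bottom-k
#' labeling), the `k` highest values become responders and the `k` lowest
#' non-responders; the rest stay unlabeled. Ties at a boundary are broken by
#' stable input order.
#'
#' @param gi50 named numeric vector of processed GI50 values (may contain `NA`).
#' @param top_fraction fraction labeled at each extreme (default 0.25).
#' @param drug_na_fraction maximum tolerated missing fraction for the drug.
#' @param top_k optional explicit count per extreme, overriding `top_fraction`.
#' @return a `response_labels` tibble covering only the labeled cell lines.
#' @export
#' @examples
#' label_gi50(setNames(1:8, paste0("c", 1:8)))
label_gi50 <- function(gi50, top_fraction = 0.25, drug_na_fraction = 0.20,
                       top_k = NULL) {
  if (is.null(names(gi50))) abort("`gi50` must be named by cell-line id.")
  na_frac <- mean(is.na(gi50))
  if (na_frac > drug_na_fraction) {
    abort(sprintf("drug excluded: GI50 missing in %.0f%% of cell lines (> %.0f%%).",
                  100 * na_frac, 100 * drug_na_fraction))
  }
  vals <- gi50[!is.na(gi50)]
  n <- length(vals)
  if (n < 4L) abort("need at least 4 non-missing GI50 values.")
  k <- if (is.null(top_k)) ceiling(top_fraction * n) else as.integer(top_k)
  if (2L * k > n) abort("top and bottom sets overlap: too few cell lines for this labeling.")
  ord_hi <- order(vals, decreasing = TRUE)  # stable: ties keep input order
  ord_lo <- order(vals, decreasing = FALSE)
  hi <- names(vals)[ord_hi[seq_len(k)]]
  lo <- names(vals)[ord_lo[seq_len(k)]]
  ids <- c(hi, lo)
  response_labels(ids,
                  rep(c("responder", "non_responder"), each = k),
                  raw = unname(vals[ids]))
}
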