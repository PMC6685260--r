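#' Simulated-annealing schedule parameters
#'
#' @param initial_temperature starting temperature (> 0).
#' @param cooling_rate geometric cooling factor in (0, 1) applied per
#'   iteration.
#' @param iterations moves attempted per restart.
#' @param restarts independent restarts; the best subgraph over all restarts
#'   is returned.
#' @return an `sa_params` list.
#' @export
sa_params <- function(initial_temperature = 1.0, cooling_rate = 0.995,
                      iterations = 5000L, restarts = 3L) {
  stopifnot(initial_temperature > 0,
            cooling_rate > 0, cooling_rate < 1,
            iterations >= 1, restarts >= 1)
  structure(list(initial_temperature = initial_temperature,
                 cooling_rate = cooling_rate,
                 iterations = as.integer(iterations),
                 restarts = as.integer(restarts)),
            class = "sa_params")
}

#' Size-normalised subnetwork score
#'
#' `s(S) = sum(z_g, g in S) / sqrt(|S|)` — the standard active-module
#' objective, which keeps scores comparable across subset sizes when z is
#' standardized over the gene background.
#'
#' @param genes non-empty character vector of member genes.
#' @param z named numeric vector of standardized gene scores.
#' @return scalar score.
#' @export
subnetwork_score <- function(genes, z) {
  if (!length(genes)) abort("empty gene set has no subnetwork score.")
  zi <- z[genes]
  if (anyNA(zi)) {
    abort(paste0("gene(s) without a z-score: ",
                 paste(head(genes[is.na(zi)], 5L), collapse = ", ")))
  }
  sum(zi) / sqrt(length(genes))
}

# one-row subpathway tibble; genes stored as a list-column (sorted)
subpathway_row <- function(pathway_id, genes, score, p_value = NA_real_) {
  n <- length(genes)
  tibble::tibble(pathway_id = pathway_id,
                 genes = list(sort(genes)),
                 score = score,
                 size = n,
                 p_value = p_value)
}

#' Search one pathway for its highest-scoring connected subnetwork
#'
#' Runs simulated annealing over connected induced subgraphs of `graph`,
#' maximising [subnetwork_score()]. Proposals add a node adjacent to the
#' current subgraph or remove a member whose removal preserves connectivity;
#' a worsening move is accepted with probability `exp(delta / T)` under
#' geometric cooling. Reproducible under `set.seed()`.
#'
#' @param graph a [pathway_graph()] (igraph); every node needs a z-score.
#' @param z named numeric vector of standardized gene scores.
#' @param params an [sa_params()] schedule.
#' @return a one-row subpathway tibble (`pathway_id`, `genes` list-column,
#'   `score`, `size`, `p_value = NA`).
#' @export
sa_search <- function(graph, z, params = sa_params()) {
  nodes <- igraph::V(graph)$name
  if (!length(nodes)) abort("empty pathway graph.")
  zi <- z[nodes]
  if (anyNA(zi)) {
    abort(paste0("node(s) without a z-score: ",
                 paste(head(nodes[is.na(zi)], 5L), collapse = ", ")))
  }
  adj <- lapply(igraph::adjacent_vertices(graph, igraph::V(graph)),
                function(v) as.integer(v) - 1L)
  res <- sa_search_cpp(adj, unname(zi), params$iterations,
                       params$initial_temperature, params$cooling_rate,
                       params$restarts)
  subpathway_row(pathway_id(graph), nodes[res$members + 1L], res$score)
}

#' Exhaustive search over all connected subsets (test oracle)
#'
#' Enumerates every connected induced subgraph of a small pathway (at most 16
#' nodes) by bitmask and returns the maximum-score subset. Ties are broken
#' toward the smaller subset, then lexicographically on the sorted gene
#' names. Serves as the independent optimum oracle for [sa_search()].
#'
#' @inheritParams sa_search
#' @return a one-row subpathway tibble.
#' @export
exhaustive_search <- function(graph, z) {
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  if (n == 0L) abort("empty pathway graph.")
  if (n > 16L) abort("exhaustive_search is limited to graphs with <= 16 nodes.")
  zi <- unname(z[nodes])
  if (anyNA(zi)) abort("every node needs a z-score.")
  # adjacency bitmasks
  adj_mask <- integer(n)
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(el)) {
    for (e in seq_len(nrow(el))) {
      a <- el[e, 1L]; b <- el[e, 2L]
      adj_mask[a] <- bitwOr(adj_mask[a], bitwShiftL(1L, b - 1L))
      adj_mask[b] <- bitwOr(adj_mask[b], bitwShiftL(1L, a - 1L))
    }
  }
  bit_of <- bitwShiftL(1L, seq_len(n) - 1L)
  best <- NULL
  for (mask in seq_len(bitwShiftL(1L, n) - 1L)) {
    bits <- which(bitwAnd(mask, bit_of) != 0L)
    # flood fill from the lowest member
    reach <- bit_of[bits[1L]]
    repeat {
      grown <- reach
      for (v in bits) {
        if (bitwAnd(reach, bit_of[v]) != 0L) {
          grown <- bitwOr(grown, bitwAnd(adj_mask[v], mask))
        }
      }
      if (grown == reach) break
      reach <- grown
    }
    if (reach != mask) next
    score <- sum(zi[bits]) / sqrt(length(bits))
    cand_genes <- sort(nodes[bits])
    if (is.null(best) || score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 &&
         (length(bits) < best$size ||
          (length(bits) == best$size &&
           paste(cand_genes, collapse = "\r") < paste(best$genes[[1L]], collapse = "\r"))))) {
      best <- subpathway_row(pathway_id(graph), nodes[bits], score)
    }
  }
  best
}

#' Permutation significance of a searched subpathway
#'
#' Builds a per-pathway null by repeatedly shuffling the combined gene scores
#' over the whole universe, re-standardizing, and re-running the annealing
#' search on the same graph, so that pathway size and topology are controlled.
#' The empirical p-value uses the plus-one estimator
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`. Reproducible under
#' `set.seed()`.
#'
#' @param observed a one-row subpathway tibble from [sa_search()].
#' @param graph the pathway graph that was searched.
#' @param scores gene score tibble from [score_genes()].
#' @param universe gene background over which scores are shuffled.
#' @param n_perm number of permutations (default 100).
#' @param params the [sa_params()] used for the observed search.
#' @return `observed` with `p_value` filled in; the null scores are attached
#'   as attribute `"null_scores"`.
#' @export
estimate_significance <- function(observed, graph, scores,
                                  universe = scores$gene_id, n_perm = 100L,
                                  params = sa_params()) {
  stopifnot(n_perm >= 1L)
  z_universe <- unname(standardize_scores(scores, universe))
  nodes <- igraph::V(graph)$name
  adj <- lapply(igraph::adjacent_vertices(graph, igraph::V(graph)),
                function(v) as.integer(v) - 1L)
  null_scores <- vapply(seq_len(n_perm), function(i) {
    zp <- sample(z_universe, length(nodes))
    sa_search_cpp(adj, zp, params$iterations, params$initial_temperature,
                  params$cooling_rate, params$restarts)$score
  }, numeric(1L))
  p <- (1 + sum(null_scores >= observed$score)) / (1 + n_perm)
  out <- observed
  out$p_value <- p
  attr(out, "null_scores") <- null_scores
  out
}

#' Filter searched subpathways to signature candidates
#'
#' Keeps subpathways significant at `alpha` (strict inequality) whose member
#' sets contain at least `min_size` connected genes, preserving input order.
#'
#' @param subpathways subpathway tibble (rows from [estimate_significance()]).
#' @param alpha significance cutoff (default 0.05, strict).
#' @param min_size minimum member count (default 3).
#' @return the filtered subpathway tibble.
#' @export
filter_candidates <- function(subpathways, alpha = 0.05, min_size = 3L) {
  if (!nrow(subpathways)) return(subpathways)
  dplyr::filter(subpathways, .data$p_value < alpha, .data$size >= min_size)
}

#' Locate candidate subpathways across a pathway collection
#'
#' The full search stage: for each pathway, restrict to genes with a score,
#' run [sa_search()], assess significance by permutation, and apply
#' [filter_candidates()]. Pathways with no scored gene are skipped.
#'
#' @param scores gene score tibble from [score_genes()].
#' @param pathways named list of pathway graphs.
#' @param universe background gene set (default: all scored genes).
#' @param alpha,min_size candidate filter, see [filter_candidates()].
#' @param n_perm permutations per pathway.
#' @param params an [sa_params()] schedule.
#' @param keep_all return all searched subpathways (with p-values) instead of
#'   only the filtered candidates.
#' @return subpathway tibble (one row per pathway searched, filtered unless
#'   `keep_all`).
#' @export
find_subpathways <- function(scores, pathways, universe = scores$gene_id,
                             alpha = 0.05, min_size = 3L, n_perm = 100L,
                             params = sa_params(), keep_all = FALSE) {
  z <- standardize_scores(scores, universe)
  rows <- purrr::map(pathways, function(g) {
    keep <- intersect(igraph::V(g)$name, universe)
    if (!length(keep)) return(NULL)
    sub_g <- igraph::induced_subgraph(g, keep)
    obs <- sa_search(sub_g, z, params)
    estimate_significance(obs, sub_g, scores, universe = universe,
                          n_perm = n_perm, params = params)
  })
  all_rows <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1L))])
  if (keep_all) all_rows else filter_candidates(all_rows, alpha, min_size)
}

#' Read/write subpathway tables
#'
#' TSV with columns `pathway_id`, `genes` (semicolon-joined), `score`,
#' `size`, `p_value`.
#'
#' @param subpathways subpathway tibble.
#' @param path file path.
#' @return `path` invisibly for the writer; a subpathway tibble for the
#'   reader.
#' @export
write_subpathways <- function(subpathways, path) {
  flat <- dplyr::mutate(subpathways,
                        genes = vapply(.data$genes, paste, character(1L),
                                       collapse = ";"))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_subpathways
#' @export
read_subpathways <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    pathway_id = readr::col_character(), genes = readr::col_character(),
    score = readr::col_double(), size = readr::col_integer(),
    p_value = readr::col_double()), progress = FALSE)
  tab$genes <- strsplit(tab$genes, ";", fixed = TRUE)
  tab
}
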