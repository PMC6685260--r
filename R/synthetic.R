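#' Specification of a synthetic multi-omics drug-response study
#'
#' Defines the pathway collection and cohort a synthetic benchmark draws:
#' `n_pathways` connected gene graphs with sizes uniform in
#' `pathway_size_range` and edge count `edge_density * choose(n, 2)` (at
#' least a spanning tree), a cohort of responders and non-responders with
#' per-gene background noise, and optionally one or more *embedded* signals —
#' connected gene subsets whose responder-group means are shifted by
#' `d_omic` standard deviations at each omic layer. Defaults reflect a
#' desk-scale study: 20 pathways of 8-15 genes, 60 responders + 60
#' non-responders, unit noise, and a single 6-gene embedded subpathway with
#' per-omic effect 1.0.
#'
#' @param n_pathways number of pathways.
#' @param pathway_size_range integer pair (min, max) of pathway sizes.
#' @param edge_density target edge density in (0, 1\].
#' @param n_responders,n_non_responders class sizes.
#' @param embedded list of embedded signals, each a list with elements
#'   `pathway` (index), `size` (connected subset size), `d_expression`,
#'   `d_cnv`, `d_methylation` (effects in SD units). `NULL` for a null
#'   cohort.
#' @param noise_sd latent-scale noise standard deviation.
#' @param seed integer seed; the whole generator is deterministic given it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pathways = 20L, pathway_size_range = c(8L, 15L),
                           edge_density = 0.25, n_responders = 60L,
                           n_non_responders = 60L,
                           embedded = list(list(pathway = 1L, size = 6L,
                                                d_expression = 1, d_cnv = 1,
                                                d_methylation = 1)),
                           noise_sd = 1, seed = 1L) {
  stopifnot(n_pathways >= 1, length(pathway_size_range) == 2L,
            pathway_size_range[1L] >= 2, diff(pathway_size_range) >= 0,
            edge_density > 0, edge_density <= 1,
            n_responders >= 1, n_non_responders >= 1, noise_sd > 0)
  for (e in embedded) {
    stopifnot(e$pathway >= 1, e$pathway <= n_pathways,
              e$size >= 1, e$size <= pathway_size_range[2L])
  }
  structure(list(n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 edge_density = edge_density,
                 n_responders = as.integer(n_responders),
                 n_non_responders = as.integer(n_non_responders),
                 embedded = embedded, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# uniform random labeled tree on n nodes via a Pruefer sequence
random_tree_edges <- function(n) {
  if (n == 1L) return(matrix(integer(), ncol = 2L))
  if (n == 2L) return(cbind(1L, 2L))
  pruefer <- sample.int(n, n - 2L, replace = TRUE)
  degree <- rep(1L, n)
  for (v in pruefer) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, nrow = n - 1L, ncol = 2L)
  for (i in seq_along(pruefer)) {
    leaf <- which(degree == 1L)[1L]
    edges[i, ] <- c(leaf, pruefer[i])
    degree[leaf] <- degree[leaf] - 1L
    degree[pruefer[i]] <- degree[pruefer[i]] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

#' Generate a synthetic pathway collection
#'
#' Each pathway is a connected graph: a uniform random spanning tree plus
#' random extra edges up to `edge_density * choose(n, 2)` total. Gene labels
#' are globally unique (`sp01_g01`, ...). Deterministic per `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return named list of pathway graphs.
#' @export
generate_pathway_set <- function(spec) {
  set.seed(spec$seed)
  size_choices <- seq(spec$pathway_size_range[1L], spec$pathway_size_range[2L])
  sizes <- size_choices[sample.int(length(size_choices), spec$n_pathways,
                                   replace = TRUE)]
  graphs <- lapply(seq_len(spec$n_pathways), function(k) {
    n <- sizes[k]
    m_target <- round(spec$edge_density * choose(n, 2))
    if (m_target < n - 1L) {
      abort(sprintf("edge_density %.3f gives %d edges for a %d-node pathway; a spanning tree needs %d.",
                    spec$edge_density, m_target, n, n - 1L))
    }
    tree <- random_tree_edges(n)
    have <- paste(pmin(tree[, 1L], tree[, 2L]), pmax(tree[, 1L], tree[, 2L]))
    all_pairs <- t(utils::combn(n, 2L))
    pool <- all_pairs[!(paste(all_pairs[, 1L], all_pairs[, 2L]) %in% have), ,
                      drop = FALSE]
    extra <- m_target - nrow(tree)
    if (extra > 0L && nrow(pool)) {
      pick <- sample.int(nrow(pool), min(extra, nrow(pool)))
      edges <- rbind(tree, pool[pick, , drop = FALSE])
    } else {
      edges <- tree
    }
    id <- sprintf("sp%02d", k)
    labels <- sprintf("%s_g%02d", id, seq_len(n))
    pathway_graph(id, edges = cbind(labels[edges[, 1L]], labels[edges[, 2L]]),
                  nodes = labels, name = sprintf("synthetic pathway %d", k))
  })
  setNames(graphs, sprintf("sp%02d", seq_len(spec$n_pathways)))
}

# random connected subset of given size: snowball growth from a random node
random_connected_subset <- function(graph, size) {
  nodes <- igraph::V(graph)$name
  if (size > length(nodes)) abort("embedded subset larger than its pathway.")
  members <- sample(nodes, 1L)
  while (length(members) < size) {
    nb <- unique(unlist(lapply(igraph::adjacent_vertices(graph, members),
                               function(v) v$name)))
    nb <- setdiff(nb, members)
    if (!length(nb)) abort("pathway not connected; cannot grow embedded subset.")
    members <- c(members, sample(nb, 1L))
  }
  sort(members)
}

#' Generate a synthetic multi-omics cohort with known embedded signal
#'
#' Per layer, each gene x sample value starts from latent Gaussian noise
#' `N(0, noise_sd)`; for embedded genes the responder-group latent mean is
#' shifted by `d_omic * noise_sd`. The latent values map to the observed
#' scale per layer: expression is exponentiated (lognormal, positive), CNV
#' stays on the latent scale (log-ratio-like), methylation is squashed
#' through the logistic function into (0, 1) — which keeps betas in range
#' while preserving a monotone group separation. Deterministic per
#' `spec$seed` (offset from the pathway-set stream so the two draws are
#' independent).
#'
#' @param spec a [synthetic_spec()].
#' @param pathways pathway list from [generate_pathway_set()] under the same
#'   spec.
#' @return list with `cohort` (a `drug_cohort`) and `truth` (embedded gene
#'   sets, effects, seed).
#' @export
generate_cohort <- function(spec, pathways) {
  set.seed(spec$seed + 1L)
  genes <- unlist(lapply(pathways, function(g) igraph::V(g)$name),
                  use.names = FALSE)
  n_r <- spec$n_responders
  n_n <- spec$n_non_responders
  n_s <- n_r + n_n
  samples <- sprintf("s%03d", seq_len(n_s))
  responder <- c(rep(TRUE, n_r), rep(FALSE, n_n))
  labels <- response_labels(samples,
                            ifelse(responder, "responder", "non_responder"))
  embedded_sets <- lapply(spec$embedded, function(e) {
    random_connected_subset(pathways[[e$pathway]], e$size)
  })
  names(embedded_sets) <- vapply(spec$embedded, function(e) {
    pathway_id(pathways[[e$pathway]])
  }, character(1L))

  layer_latent <- function(d_name) {
    lat <- matrix(rnorm(length(genes) * n_s, 0, spec$noise_sd),
                  nrow = length(genes), dimnames = list(genes, samples))
    for (i in seq_along(spec$embedded)) {
      d <- spec$embedded[[i]][[d_name]]
      if (d != 0) {
        lat[embedded_sets[[i]], responder] <-
          lat[embedded_sets[[i]], responder] + d * spec$noise_sd
      }
    }
    lat
  }
  expr <- omics_matrix(exp(layer_latent("d_expression")), "expression",
                       allow_na = FALSE)
  cnv <- omics_matrix(layer_latent("d_cnv"), "cnv", allow_na = FALSE)
  meth <- omics_matrix(plogis(layer_latent("d_methylation")), "methylation",
                       allow_na = FALSE)
  cohort <- suppressMessages(align_cohort(expr, cnv, meth, labels))
  truth <- structure(list(embedded = embedded_sets,
                          effects = spec$embedded, seed = spec$seed),
                     class = "ground_truth")
  list(cohort = cohort, truth = truth)
}

#' Gene-level recovery of an embedded signal
#'
#' Compares the union of embedded (true) genes with the union of genes in the
#' found subpathways: precision, recall, and the mean over embedded pathways
#' of the best Jaccard index against any found subpathway.
#'
#' @param truth a `ground_truth` from [generate_cohort()].
#' @param found a subpathway tibble (e.g. from [find_subpathways()] or a
#'   fitted model's `subpathways`).
#' @return one-row tibble: `gene_precision`, `gene_recall`,
#'   `subpathway_jaccard`.
#' @export
recovery_metrics <- function(truth, found) {
  true_genes <- unique(unlist(truth$embedded))
  found_sets <- if (nrow(found)) found$genes else list()
  found_genes <- unique(unlist(found_sets))
  inter <- intersect(true_genes, found_genes)
  precision <- if (length(found_genes)) length(inter) / length(found_genes) else 0
  recall <- if (length(true_genes)) length(inter) / length(true_genes) else 0
  jac <- vapply(truth$embedded, function(ts) {
    if (!length(found_sets)) return(0)
    max(vapply(found_sets, function(fs) {
      length(intersect(ts, fs)) / length(union(ts, fs))
    }, numeric(1L)))
  }, numeric(1L))
  tibble::tibble(gene_precision = precision, gene_recall = recall,
                 subpathway_jaccard = if (length(jac)) mean(jac) else 0)
}
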