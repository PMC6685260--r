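#' Construct a pathway graph
#'
#' Pathways are simple undirected gene graphs (igraph objects) tagged with a
#' pathway id and display name. Duplicate edges are collapsed and self-loops
#' dropped with a warning; every edge endpoint becomes a node.
#'
#' @param pathway_id single string.
#' @param edges two-column character matrix or data frame of gene pairs; may
#'   be empty when `nodes` is given.
#' @param nodes optional character vector of genes (isolated nodes allowed).
#' @param name display name (defaults to the id).
#' @return an `igraph` object with graph attributes `pathway_id` and `name`.
#' @export
pathway_graph <- function(pathway_id, edges = NULL, nodes = NULL, name = pathway_id) {
  el <- if (is.null(edges)) matrix(character(), ncol = 2L) else as.matrix(edges)
  storage.mode(el) <- "character"
  if (nrow(el) && any(el == "" | is.na(el))) {
    abort(sprintf("pathway '%s': edge with blank gene id.", pathway_id))
  }
  verts <- unique(c(nodes, as.vector(t(el))))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(verts, igraph::V(g)$name)),
                            name = setdiff(verts, igraph::V(g)$name))
  n_loops <- sum(igraph::which_loop(g))
  if (n_loops) {
    warn(sprintf("pathway '%s': dropped %d self-loop(s).", pathway_id, n_loops))
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g <- igraph::set_graph_attr(g, "pathway_id", pathway_id)
  igraph::set_graph_attr(g, "name", name)
}

pathway_id <- function(g) igraph::graph_attr(g, "pathway_id")

#' Read pathway graphs from an edge-list TSV or GML files
#'
#' The TSV format has columns `pathway_id`, `pathway_name` (optional),
#' `gene_a`, `gene_b`; one [pathway_graph()] is built per distinct
#' `pathway_id`. Alternatively, a character vector of `.gml` paths is
#' accepted, one graph per file (the file stem is the pathway id unless the
#' graph carries one).
#'
#' @param path a single TSV path, or a vector of GML paths.
#' @return a named list of `igraph` pathway graphs.
#' @export
read_pathway_graphs <- function(path) {
  if (length(path) > 1L || grepl("\\.gml$", path[1L], ignore.case = TRUE)) {
    graphs <- lapply(path, function(p) {
      g <- igraph::read_graph(p, format = "gml")
      g <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
      if (is.null(igraph::graph_attr(g, "pathway_id"))) {
        g <- igraph::set_graph_attr(g, "pathway_id", sub("\\.gml$", "", basename(p)))
      }
      if (is.null(igraph::vertex_attr(g, "name"))) {
        lab <- igraph::vertex_attr(g, "label")
        if (is.null(lab)) abort(sprintf("'%s': GML nodes must carry gene labels.", p))
        g <- igraph::set_vertex_attr(g, "name", value = as.character(lab))
      }
      g
    })
    return(setNames(graphs, vapply(graphs, pathway_id, character(1L))))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!nrow(tab)) abort(sprintf("'%s': empty pathway file.", path))
  needed <- c("pathway_id", "gene_a", "gene_b")
  if (!all(needed %in% names(tab))) {
    abort(sprintf("'%s': need columns %s.", path, paste(needed, collapse = ", ")))
  }
  if (!"pathway_name" %in% names(tab)) tab$pathway_name <- tab$pathway_id
  split_tab <- split(tab, factor(tab$pathway_id, levels = unique(tab$pathway_id)))
  graphs <- lapply(split_tab, function(d) {
    pathway_graph(d$pathway_id[1L], edges = cbind(d$gene_a, d$gene_b),
                  name = d$pathway_name[1L])
  })
  graphs
}

#' Write pathway graphs to an edge-list TSV
#'
#' @param graphs named list of pathway graphs (see [pathway_graph()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pathway_graphs <- function(graphs, path) {
  rows <- purrr::map_dfr(graphs, function(g) {
    el <- igraph::as_edgelist(g)
    tibble::tibble(pathway_id = pathway_id(g),
                   pathway_name = igraph::graph_attr(g, "name") %||% pathway_id(g),
                   gene_a = el[, 1L], gene_b = el[, 2L])
  })
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}
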