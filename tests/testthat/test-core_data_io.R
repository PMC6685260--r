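test_that("omics TSV round-trip is value-exact and preserves missing markers", {
  set.seed(3)
  vals <- matrix(rnorm(12), 3, 4,
                 dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  vals[2, 3] <- NA
  m <- omics_matrix(vals, "cnv")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_omics_matrix(m, path)
  back <- read_omics_matrix(path, "cnv")
  expect_identical(dim(back), c(3L, 4L))
  expect_equal(as.matrix(back), vals)
  expect_true(is.na(back["gB", "s3"]))
  expect_identical(omic_kind(back), "cnv")
})

test_that("omics reader rejects duplicate genes and names bad cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(read_omics_matrix(path, "expression"), "duplicate gene")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\toops"), path)
  expect_error(read_omics_matrix(path, "expression"), "gA.*s2")
})

test_that("expression zero-fraction filter removes strictly-above-threshold genes only", {
  vals <- rbind(
    many_zero = c(0, 0, 0, 1, 1, 1, 1, 1, 1, 1),   # 30% zeros: out
    some_zero = c(0, 0, 1, 1, 1, 1, 1, 1, 1, 1),   # exactly 20%: kept
    none_zero = rep(2, 10)
  )
  colnames(vals) <- paste0("s", 1:10)
  m <- omics_matrix(vals, "expression")
  f <- filter_expression(m)
  expect_identical(rownames(f), c("some_zero", "none_zero"))
  # idempotent, and identity on an all-nonzero matrix
  expect_equal(unclass(filter_expression(f)), unclass(f))
  all_pos <- omics_matrix(vals["none_zero", , drop = FALSE], "expression")
  expect_equal(unclass(filter_expression(all_pos)), unclass(all_pos))
  expect_error(filter_expression(omics_matrix(vals * 0, "expression")), "unusable")
})

test_that("methylation preprocessing filters, imputes and collapses CpGs to genes", {
  vals <- rbind(
    cg1 = c(0.2, 0.4), cg2 = c(0.4, 0.6),           # both map to G1
    cg3 = c(0.5, 0.5),                              # maps to G2
    cg4 = c(NA, 0.9)                                # 50% missing: dropped
  )
  colnames(vals) <- c("s1", "s2")
  map <- c(cg1 = "G1", cg2 = "G1", cg3 = "G2", cg4 = "G3")
  out <- suppressMessages(preprocess_methylation(vals, map))
  expect_identical(rownames(out), c("G1", "G2"))
  expect_equal(unname(unclass(out)["G1", ]), c(0.3, 0.5))
  expect_equal(unname(unclass(out)["G2", ]), c(0.5, 0.5))
  expect_false(anyNA(out))
  # identity on a complete one-CpG-per-gene matrix, hence idempotent
  idmap <- setNames(c("G1", "G2"), c("G1", "G2"))
  again <- suppressMessages(preprocess_methylation(unclass(out)[1:2, ], idmap))
  expect_equal(as.matrix(again), as.matrix(out)[1:2, ])
})

test_that("knn imputation fills all gaps with neighbour means", {
  set.seed(5)
  base <- matrix(rep(seq(0.1, 0.9, length.out = 8), each = 6), nrow = 8,
                 byrow = TRUE) + matrix(rnorm(48, 0, 0.01), 8)
  rownames(base) <- paste0("cg", 1:8)
  colnames(base) <- paste0("s", 1:6)
  holed <- base
  holed[2, 3] <- NA
  filled <- impute_knn(holed, k = 2)
  expect_false(anyNA(filled))
  # rows are near-identical profiles, so the imputed value tracks the truth
  expect_lt(abs(filled[2, 3] - base[2, 3]), 0.05)
})

test_that("replicate collapsing averages per patient and is identity otherwise", {
  vals <- matrix(c(1, 3, 0, 0, 0, 6), nrow = 1,
                 dimnames = list("g", paste0("a", 1:6)))
  m <- omics_matrix(vals, "expression")
  map <- setNames(c("p1", "p1", "p2", "p2", "p2", "p2"), paste0("a", 1:6))
  out <- collapse_replicates(m, map)
  expect_equal(unname(unclass(out)["g", ]), c(2, 1.5))
  distinct <- setNames(paste0("q", 1:6), paste0("a", 1:6))
  expect_equal(as.vector(as.matrix(collapse_replicates(m, distinct))), as.vector(vals))
  expect_error(collapse_replicates(m, map[1:3]), "without a patient")
})

test_that("RECIST labeling maps CR/PR to responder and drops unknown categories", {
  lab <- label_recist(c(s1 = "CR", s2 = "PD", s3 = "PR", s4 = "SD"))
  expect_identical(as.character(lab$response),
                   c("responder", "non_responder", "responder", "non_responder"))
  expect_warning(lab2 <- label_recist(c(s1 = "PR", s2 = "unknown")), "unrecognised")
  expect_identical(lab2$sample_id, "s1")
  expect_error(suppressWarnings(label_recist(c(s1 = "mystery"))), "no sample")
})

test_that("GI50 labeling takes top/bottom quartiles with NA and top-k rules", {
  g <- setNames(as.numeric(1:8), paste0("c", 1:8))
  lab <- label_gi50(g)
  expect_setequal(lab$sample_id[lab$response == "responder"], c("c8", "c7"))
  expect_setequal(lab$sample_id[lab$response == "non_responder"], c("c1", "c2"))
  expect_identical(nrow(lab), 2L * as.integer(ceiling(0.25 * 8)))

  g_na <- g
  g_na[1:3] <- NA  # 37.5% missing > 20%
  expect_error(label_gi50(g_na), "drug excluded")

  g60 <- setNames(rnorm(60), paste0("c", 1:60))
  lab15 <- label_gi50(g60, top_k = 15)
  expect_identical(sum(lab15$response == "responder"), 15L)
  expect_identical(sum(lab15$response == "non_responder"), 15L)
  expect_error(label_gi50(g, top_k = 5), "overlap")
})

test_that("cohort alignment intersects samples, keeps one ordering, flags imbalance", {
  mk <- function(samples, kind) {
    omics_matrix(matrix(seq_along(samples) / 10, 1,
                        dimnames = list("g1", samples)), kind)
  }
  labels <- response_labels(c("b", "c"), c("responder", "non_responder"))
  co <- suppressMessages(align_cohort(mk(c("a", "b", "c"), "expression"),
                                      mk(c("b", "c", "d"), "cnv"),
                                      mk(c("b", "c"), "methylation"), labels))
  expect_identical(cohort_samples(co), c("b", "c"))
  expect_identical(colnames(co$expression), colnames(co$cnv))
  expect_identical(colnames(co$cnv), colnames(co$methylation))

  only_resp <- response_labels(c("b", "c"), c("responder", "responder"))
  expect_error(suppressMessages(
    align_cohort(mk(c("b", "c"), "expression"), mk(c("b", "c"), "cnv"),
                 mk(c("b", "c"), "methylation"), only_resp)), "class is empty")

  skewed <- response_labels(paste0("s", 1:10),
                            c("responder", rep("non_responder", 9)))
  big <- function(kind) mk(paste0("s", 1:10), kind)
  expect_warning(suppressMessages(
    align_cohort(big("expression"), big("cnv"), big("methylation"), skewed)),
    "imbalance")
})

test_that("pathway graph reading collapses duplicates and drops self-loops", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway_id\tgene_a\tgene_b",
               "P1\ta\tb", "P1\tb\tc", "P1\ta\tb", "P1\td\td", "P2\tx\ty"),
             path)
  graphs <- suppressWarnings(read_pathway_graphs(path))
  expect_named(graphs, c("P1", "P2"))
  expect_equal(igraph::vcount(graphs$P1), 4)   # d kept as isolated node
  expect_equal(igraph::ecount(graphs$P1), 2)   # duplicate collapsed, loop dropped
  expect_equal(igraph::vcount(graphs$P2), 2)
  expect_warning(pathway_graph("P1", edges = cbind("a", "a")), "self-loop")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("pathway_id\tgene_a\tgene_b", empty)
  expect_error(read_pathway_graphs(empty), "empty")
  expect_error(pathway_graph("P", edges = cbind("a", "")), "blank")
})

test_that("pathway graphs round-trip through the edge-list TSV and GML", {
  set.seed(8)
  graphs <- list(p1 = random_connected_pathway(6, id = "p1"),
                 p2 = random_connected_pathway(4, id = "p2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pathway_graphs(graphs, path)
  back <- read_pathway_graphs(path)
  expect_named(back, c("p1", "p2"))
  for (nm in names(graphs)) {
    expect_true(igraph::isomorphic(graphs[[nm]], back[[nm]]))
    expect_setequal(igraph::V(graphs[[nm]])$name, igraph::V(back[[nm]])$name)
  }
  gml <- withr::local_tempfile(fileext = ".gml")
  g <- igraph::set_vertex_attr(graphs$p1, "label", value = igraph::V(graphs$p1)$name)
  igraph::write_graph(g, gml, format = "gml")
  from_gml <- read_pathway_graphs(gml)
  expect_length(from_gml, 1L)
  expect_equal(igraph::vcount(from_gml[[1]]), 6)
})
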