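reduced_sa <- function() sa_params(iterations = 800, restarts = 1)

test_that("AUC follows the Mann-Whitney formulation with tie handling", {
  expect_identical(compute_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_identical(compute_auc(c(10, 9, 2, 1), c(1, 1, 0, 0)), 1.0)
  expect_identical(compute_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(compute_auc(1:4, c(1, 1, 1, 1)), "both response classes")
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(14)
    s <- rnorm(40)
    y <- rbinom(40, 1, 0.5)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
    expect_equal(compute_auc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("stratified splits halve each class with the odd sample in training", {
  labs <- response_labels(paste0("s", 1:20),
                          rep(c("responder", "non_responder"), each = 10))
  sp <- stratified_random_split(labs, 5)
  expect_length(sp$train_samples, 10L)
  expect_length(sp$test_samples, 10L)
  expect_length(intersect(sp$train_samples, sp$test_samples), 0L)
  expect_setequal(c(sp$train_samples, sp$test_samples), labs$sample_id)
  cls <- function(ids) table(labs$response[match(ids, labs$sample_id)])
  expect_identical(unname(cls(sp$train_samples)), unname(cls(sp$test_samples)))

  odd <- response_labels(paste0("s", 1:9),
                         c(rep("responder", 5), rep("non_responder", 4)))
  sp_odd <- stratified_random_split(odd, 1)
  tr <- table(odd$response[match(sp_odd$train_samples, odd$sample_id)])
  expect_identical(unname(tr[["responder"]]), 3L)
  expect_identical(unname(tr[["non_responder"]]), 2L)

  expect_identical(stratified_random_split(labs, 5), sp)
  tiny <- response_labels(c("a", "b", "c"),
                          c("responder", "non_responder", "non_responder"))
  expect_error(stratified_random_split(tiny, 1), "fewer than 2")
})

test_that("a repeat recovers an embedded signal and is seed-reproducible", {
  spec <- synthetic_spec(n_pathways = 8, seed = 60)
  pw <- generate_pathway_set(spec)
  gen <- generate_cohort(spec, pw)
  split <- stratified_random_split(gen$cohort$labels, 61)
  rr <- suppressMessages(run_repeat(gen$cohort, pw, split, params = reduced_sa(),
                                    n_perm = 30, n_trees = 300, seed = 61))
  expect_gt(rr$test_auc, 0.8)
  rec <- recovery_metrics(gen$truth, rr$subpathways)
  expect_gte(rec$gene_recall, 0.8)
  # training touched only training samples: the score table ignores test data
  sc_train <- score_genes(subpathsig:::subset_cohort(gen$cohort, split$train_samples))
  expect_identical(rr$scores, sc_train)
  rr2 <- suppressMessages(run_repeat(gen$cohort, pw, split, params = reduced_sa(),
                                     n_perm = 30, n_trees = 300, seed = 61))
  expect_identical(rr$test_auc, rr2$test_auc)
  expect_identical(rr$subpathways$genes, rr2$subpathways$genes)
  expect_identical(predict(rr$classifier, type = "prob"),
                   predict(rr2$classifier, type = "prob"))
})

test_that("selection returns the best-AUC repeat with a full trace", {
  spec <- synthetic_spec(n_pathways = 6, seed = 70)
  pw <- generate_pathway_set(spec)
  gen <- generate_cohort(spec, pw)
  model <- suppressMessages(select_signature(gen$cohort, pw, n_repeats = 3,
                                             base_seed = 70, params = reduced_sa(),
                                             n_perm = 25, n_trees = 300))
  expect_identical(nrow(model$auc_trace), 3L)
  expect_identical(model$repeat_index,
                   which.max(model$auc_trace$test_auc))
  expect_identical(model$best_auc, max(model$auc_trace$test_auc))
  expect_s3_class(tidy(model), "tbl_df")
  expect_identical(glance(model)$n_repeats, 3L)
  expect_s3_class(autoplot(model), "ggplot")
})

test_that("prediction with a frozen model is consistent and handles unlabeled cohorts", {
  spec <- synthetic_spec(n_pathways = 6, seed = 80)
  pw <- generate_pathway_set(spec)
  gen <- generate_cohort(spec, pw)
  model <- suppressMessages(select_signature(gen$cohort, pw, n_repeats = 1,
                                             base_seed = 80, params = reduced_sa(),
                                             n_perm = 25, n_trees = 300))
  # applying to the training cohort reproduces training-time activities exactly
  train <- subpathsig:::subset_cohort(gen$cohort, model$split$train_samples)
  act <- build_activity_matrices(train, model$scores, model$subpathways)
  pr <- predict_response(model, train)
  expect_identical(pr$predictions$sample_id, colnames(act))
  expect_false(is.na(pr$auc))

  unlabeled <- list(expression = gen$cohort$expression, cnv = gen$cohort$cnv,
                    methylation = gen$cohort$methylation)
  pr2 <- predict_response(model, unlabeled)
  expect_true(is.na(pr2$auc))
  expect_identical(nrow(pr2$predictions), 120L)

  # a cohort missing every signature gene errors with the gene list
  small <- toy_cohort(n_genes = 4, n_samples = 8, seed = 3)
  expect_error(predict_response(model, small), "missing genes")
})

test_that("model directories round-trip the frozen signature", {
  spec <- synthetic_spec(n_pathways = 5, seed = 90)
  pw <- generate_pathway_set(spec)
  gen <- generate_cohort(spec, pw)
  model <- suppressMessages(select_signature(gen$cohort, pw, n_repeats = 1,
                                             base_seed = 90, params = reduced_sa(),
                                             n_perm = 25, n_trees = 200))
  dir <- withr::local_tempdir()
  save_signature_model(model, dir)
  back <- load_signature_model(dir)
  expect_identical(back$mode, model$mode)
  expect_equal(back$subpathways$genes, model$subpathways$genes)
  expect_equal(back$best_auc, model$best_auc)
  p1 <- predict_response(model, gen$cohort)
  p2 <- predict_response(back, gen$cohort)
  expect_equal(p1$predictions$probability, p2$predictions$probability)
})

test_that("the pathway-free baseline keeps only training-significant genes", {
  co <- toy_cohort(n_genes = 10, n_samples = 24, seed = 55)
  split <- stratified_random_split(co$labels, 2)
  train <- subpathsig:::subset_cohort(co, split$train_samples)
  sc <- subpathsig:::score_genes_expression(train)
  n_sig <- sum(sc$p_expression < 0.05)
  if (n_sig > 0) {
    rr <- suppressMessages(run_repeat(co, split = split, n_trees = 200, seed = 2,
                                      mode = "gene_without_pathway"))
    expect_identical(length(rr$signature_genes), n_sig)
    expect_identical(dim(rr$classifier$importance)[1], n_sig)
  } else {
    rr <- suppressMessages(run_repeat(co, split = split, n_trees = 200, seed = 2,
                                      mode = "gene_without_pathway"))
    expect_true(rr$empty)
    expect_identical(rr$test_auc, 0.5)
  }
})

test_that("an all-null scoring repeat yields the empty signature sentinel", {
  co <- toy_cohort(n_genes = 6, n_samples = 16, seed = 8)
  pw <- list(px = random_connected_pathway(4, id = "px"))  # genes absent from cohort
  pw$px <- igraph::set_vertex_attr(pw$px, "name",
                                   value = rownames(co$expression)[1:4])
  split <- stratified_random_split(co$labels, 3)
  # with pure-noise features the permutation filter almost surely rejects all
  rr <- suppressMessages(run_repeat(co, pw, split, params = reduced_sa(),
                                    n_perm = 60, n_trees = 100, seed = 3))
  if (rr$empty) {
    expect_identical(rr$test_auc, 0.5)
    expect_identical(nrow(rr$subpathways), 0L)
    expect_null(rr$classifier)
  } else {
    succeed("noise repeat found a candidate by chance; sentinel path covered elsewhere")
  }
})
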