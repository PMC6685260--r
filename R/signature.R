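#' Area under the ROC curve
#'
#' Mann-Whitney formulation via midranks: the probability that a randomly
#' chosen responder outscores a randomly chosen non-responder, with ties
#' contributing 1/2.
#'
#' @param score numeric vector of predicted scores/probabilities.
#' @param labels a `response_labels` tibble aligned with `score` (or matched
#'   by names), or a 0/1 / two-level factor vector.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' compute_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
compute_auc <- function(score, labels) {
  if (inherits(labels, "response_labels") || is.data.frame(labels)) {
    if (!is.null(names(score))) score <- score[labels$sample_id]
    y <- as.integer(labels$response == "responder")
  } else {
    y <- if (is.factor(labels)) as.integer(labels == levels(labels)[2L]) else as.integer(labels)
  }
  stopifnot(length(score) == length(y), !anyNA(score), all(y %in% 0:1))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) abort("AUC needs both response classes.")
  r <- rank(score)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Split a labeled cohort into equal random halves, stratified by response
#'
#' Each response class is shuffled with the seed and split half/half between
#' training and test; an odd class count gives the extra sample to training.
#' Deterministic per seed.
#'
#' @param labels a `response_labels` tibble.
#' @param seed integer seed.
#' @return a `split_spec` list with `seed`, `train_samples`, `test_samples`.
#' @export
stratified_random_split <- function(labels, seed) {
  set.seed(seed)
  train <- character()
  test <- character()
  for (cls in levels(labels$response)) {
    ids <- labels$sample_id[labels$response == cls]
    if (length(ids) < 2L) {
      abort(sprintf("class '%s' has fewer than 2 samples; cannot split.", cls))
    }
    perm <- sample(ids)
    n_train <- ceiling(length(ids) / 2)
    train <- c(train, perm[seq_len(n_train)])
    test <- c(test, perm[-seq_len(n_train)])
  }
  structure(list(seed = as.integer(seed),
                 train_samples = sort(train), test_samples = sort(test)),
            class = "split_spec")
}

# expression-only gene scoring used by the baseline models
score_genes_expression <- function(cohort, test = "wald") {
  universe <- rownames(cohort$expression)
  mat <- unclass(cohort$expression)
  res <- vapply(universe, function(g) {
    f <- fit_univariate_logistic(mat[g, ], cohort$labels, test = test)
    c(f$p_value, f$beta)
  }, numeric(2L))
  tibble::tibble(gene_id = universe, p_expression = res[1L, ],
                 beta_expression = res[2L, ],
                 score = -log(res[1L, ]))
}

empty_repeat <- function(split, scores, mode, seed) {
  structure(list(repeat_index = NA_integer_, split = split, scores = scores,
                 subpathways = subpathway_row("none", character(0), NA_real_)[0, ],
                 signature_genes = character(0), classifier = NULL,
                 test_auc = 0.5, empty = TRUE, mode = mode, seed = seed),
            class = "repeat_result")
}

#' One train/evaluate repeat of the signature pipeline
#'
#' On the training half only: genes are scored ([score_genes()]), candidate
#' subpathways located ([find_subpathways()]), the integrated activity matrix
#' built ([build_activity_matrices()]) and a random forest trained on it.
#' Test-sample activities are then computed with the *training* regression
#' slopes and subpathways, and the forest's responder probabilities are
#' scored by held-out AUC. A repeat in which no subpathway survives the
#' candidate filter records `test_auc = 0.5` with an empty signature, so it
#' can never win selection. Reproducible per seed.
#'
#' `mode` selects the model family: `"multiomics"` (default) uses all three
#' layers; `"gene_with_pathway"` restricts scoring and activities to gene
#' expression; `"gene_without_pathway"` skips the pathway step entirely and
#' feeds `X * beta` of training-significant genes (p < 0.05) to the forest.
#'
#' @param cohort a `drug_cohort`.
#' @param pathways named list of pathway graphs (ignored for
#'   `"gene_without_pathway"`).
#' @param split a `split_spec` from [stratified_random_split()].
#' @param params an [sa_params()] schedule.
#' @param n_perm permutations per pathway for significance.
#' @param n_trees random-forest size (default 10000).
#' @param seed integer seed governing search, permutations and forest.
#' @param alpha,min_size candidate filter, see [filter_candidates()].
#' @param mode model family, see Details.
#' @return a `repeat_result` list (`scores`, `subpathways`, `classifier`,
#'   `test_auc`, ...).
#' @export
run_repeat <- function(cohort, pathways = NULL, split, params = sa_params(),
                       n_perm = 100L, n_trees = 10000L, seed = 1L,
                       alpha = 0.05, min_size = 3L,
                       mode = c("multiomics", "gene_with_pathway",
                                "gene_without_pathway")) {
  mode <- match.arg(mode)
  set.seed(seed)
  train <- subset_cohort(cohort, split$train_samples)
  test <- subset_cohort(cohort, split$test_samples)
  y_train <- train$labels$response
  omics <- if (mode == "multiomics") c("expression", "cnv", "methylation") else "expression"

  if (mode == "multiomics") {
    scores <- score_genes(train)
  } else {
    scores <- score_genes_expression(train)
  }

  if (mode == "gene_without_pathway") {
    sig_genes <- scores$gene_id[scores$p_expression < 0.05]
    if (!length(sig_genes)) {
      inform("run_repeat: no gene passes p < 0.05; empty-signature repeat (AUC 0.5).")
      return(empty_repeat(split, scores, mode, seed))
    }
    beta <- setNames(scores$beta_expression, scores$gene_id)[sig_genes]
    act_train <- unclass(train$expression)[sig_genes, , drop = FALSE] * beta
    act_test <- unclass(test$expression)[sig_genes, , drop = FALSE] * beta
    subp <- subpathway_row("none", character(0), NA_real_)[0, ]
  } else {
    if (is.null(pathways)) abort("`pathways` required for pathway-based modes.")
    subp <- find_subpathways(scores, pathways, alpha = alpha,
                             min_size = min_size, n_perm = n_perm,
                             params = params)
    if (!nrow(subp)) {
      inform("run_repeat: no candidate subpathway; empty-signature repeat (AUC 0.5).")
      return(empty_repeat(split, scores, mode, seed))
    }
    act_train <- build_activity_matrices(train, scores, subp, omics = omics)
    act_test <- build_activity_matrices(test, scores, subp, omics = omics)
    sig_genes <- sort(unique(unlist(subp$genes)))
  }

  rf <- randomForest::randomForest(x = t(act_train), y = y_train,
                                   ntree = n_trees)
  prob <- predict(rf, newdata = t(act_test), type = "prob")[, "responder"]
  auc <- compute_auc(prob, test$labels)
  structure(list(repeat_index = NA_integer_, split = split, scores = scores,
                 subpathways = subp, signature_genes = sig_genes,
                 classifier = rf, test_auc = auc, empty = FALSE, mode = mode,
                 seed = seed),
            class = "repeat_result")
}

#' Select a subpathway signature over repeated random splits
#'
#' Runs [run_repeat()] for `n_repeats` independent stratified random splits
#' (repeat r is seeded `base_seed + r` for its split, annealing search,
#' permutations and forest) and returns the repeat with the highest held-out
#' AUC (ties: lowest repeat index) as the frozen `signature_model`, together
#' with the full AUC trace. Selecting by best test AUC mirrors the original
#' design but is optimistic; the retained trace lets users report
#' distributional summaries instead.
#'
#' @inheritParams run_repeat
#' @param n_repeats number of random-split repeats (default 100).
#' @param base_seed integer; repeat r uses seed `base_seed + r`.
#' @return a `signature_model` list: `subpathways`, `scores` (frozen slopes),
#'   `classifier`, `best_auc`, `repeat_index`, `auc_trace` tibble,
#'   provenance.
#' @export
select_signature <- function(cohort, pathways = NULL, n_repeats = 100L,
                             base_seed = 1L, params = sa_params(),
                             n_perm = 100L, n_trees = 10000L, alpha = 0.05,
                             min_size = 3L, mode = "multiomics") {
  stopifnot(n_repeats >= 1L)
  repeats <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    split <- stratified_random_split(cohort$labels, base_seed + r)
    rr <- run_repeat(cohort, pathways, split, params = params, n_perm = n_perm,
                     n_trees = n_trees, seed = base_seed + r, alpha = alpha,
                     min_size = min_size, mode = mode)
    rr$repeat_index <- r
    repeats[[r]] <- rr
  }
  trace <- tibble::tibble(
    repeat_index = seq_len(n_repeats),
    test_auc = vapply(repeats, `[[`, numeric(1L), "test_auc"),
    n_subpathways = vapply(repeats, function(r) nrow(r$subpathways), integer(1L)),
    empty = vapply(repeats, `[[`, logical(1L), "empty")
  )
  if (all(trace$empty)) abort("every repeat produced an empty signature.")
  best_idx <- which.max(trace$test_auc)  # first max: lowest repeat index wins ties
  best <- repeats[[best_idx]]
  structure(list(mode = best$mode, subpathways = best$subpathways,
                 signature_genes = best$signature_genes, scores = best$scores,
                 classifier = best$classifier, best_auc = best$test_auc,
                 repeat_index = best_idx, split = best$split,
                 auc_trace = trace,
                 provenance = list(base_seed = as.integer(base_seed),
                                   n_repeats = as.integer(n_repeats),
                                   n_perm = as.integer(n_perm),
                                   n_trees = as.integer(n_trees),
                                   alpha = alpha, min_size = as.integer(min_size),
                                   sa = unclass(params))),
            class = "signature_model")
}

#' @rdname select_signature
#' @export
baseline_gene_with_pathway <- function(cohort, pathways, n_repeats = 100L,
                                       base_seed = 1L, ...) {
  select_signature(cohort, pathways, n_repeats = n_repeats,
                   base_seed = base_seed, mode = "gene_with_pathway", ...)
}

#' @rdname select_signature
#' @export
baseline_gene_without_pathway <- function(cohort, n_repeats = 100L,
                                          base_seed = 1L, ...) {
  select_signature(cohort, pathways = NULL, n_repeats = n_repeats,
                   base_seed = base_seed, mode = "gene_without_pathway", ...)
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf(paste0("<signature_model: %s> best held-out AUC %.3f (repeat %d of %d)\n",
                     "  %d subpathway(s), %d signature gene(s)\n"),
              x$mode, x$best_auc, x$repeat_index, nrow(x$auc_trace),
              nrow(x$subpathways), length(x$signature_genes)))
  invisible(x)
}

#' Predict drug response of a new cohort with a frozen signature model
#'
#' Activities (or `X * beta` features for the pathway-free baseline) are
#' computed on the new cohort with the model's frozen training slopes and
#' subpathways — the per-sample internal standardization of the activity
#' statistic absorbs cross-cohort scale shifts — and the stored forest emits
#' responder probabilities. AUC is reported when labels are available.
#'
#' @param model a `signature_model`.
#' @param new_cohort a `drug_cohort`, or a bare list with the needed omic
#'   layers (and optionally `labels`).
#' @return list with `predictions` (tibble `sample_id`, `probability`) and
#'   `auc` (`NA` when unlabeled).
#' @export
predict_response <- function(model, new_cohort) {
  if (is.null(model$classifier)) abort("model has an empty signature; nothing to predict with.")
  omics <- if (model$mode == "multiomics") c("expression", "cnv", "methylation") else "expression"
  for (om in omics) {
    if (is.null(new_cohort[[om]])) abort(sprintf("new cohort lacks the %s layer.", om))
  }
  if (model$mode == "gene_without_pathway") {
    missing <- setdiff(model$signature_genes, rownames(new_cohort$expression))
    if (length(missing)) {
      abort(paste0("signature gene(s) absent from the new cohort: ",
                   paste(missing, collapse = ", ")))
    }
    beta <- setNames(model$scores$beta_expression, model$scores$gene_id)[model$signature_genes]
    feats <- unclass(new_cohort$expression)[model$signature_genes, , drop = FALSE] * beta
  } else {
    present <- unique(unlist(lapply(omics, function(om) rownames(new_cohort[[om]]))))
    missing_sets <- vapply(model$subpathways$genes,
                           function(gs) !any(gs %in% present), logical(1L))
    if (any(missing_sets)) {
      missing <- setdiff(unlist(model$subpathways$genes[missing_sets]), present)
      abort(paste0("subpathway(s) with no genes in the new cohort; missing genes: ",
                   paste(missing, collapse = ", ")))
    }
    feats <- build_activity_matrices(new_cohort, model$scores,
                                     model$subpathways, omics = omics)
  }
  prob <- predict(model$classifier, newdata = t(feats), type = "prob")[, "responder"]
  preds <- tibble::tibble(sample_id = colnames(feats), probability = unname(prob))
  auc <- NA_real_
  labs <- new_cohort$labels
  if (!is.null(labs) && all(levels(labs$response) %in% labs$response)) {
    auc <- compute_auc(setNames(preds$probability, preds$sample_id), labs)
  }
  list(predictions = preds, auc = auc)
}
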