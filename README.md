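# subpathsig

Subpathway signatures for individualized anticancer drug response from
multi-omics data.

Patients with the same tumour type respond very differently to the same
drug, and single-gene markers explain little of it. `subpathsig` looks for
**subpathways** — connected regions of genes inside larger pathway graphs —
whose joint state across gene expression, copy number (CNV) and DNA
methylation predicts a binary responder / non-responder phenotype, and
freezes the best-performing model as a reusable signature. It is aimed at
computational biologists working on pharmacogenomics with gene × sample
matrices per omic layer, binary response labels (RECIST classes or GI50
extremes), and pathway graphs as gene edge lists.

## The method

For each gene *g* and omic layer *m*, a univariate logistic regression
`logit P(responder) = b0 + b1 x` on the raw measurements yields a p-value
*P_m* and slope *beta_m*. Per-gene evidence is combined as

    Score(g) = -sum_m ln(P_m),   m in {expression, CNV, methylation}

Scores are z-standardized over the gene background and each pathway graph is
searched by simulated annealing for the connected subset *S* maximising
`s(S) = sum(z_g) / sqrt(|S|)`; a per-pathway permutation null gives an
empirical p, and candidates need `p < 0.05` with at least three connected
genes. Each candidate then gets a per-sample, per-layer activity

    Z_sp = ( mean_n(X_i * beta_i) - mean_N(X_i * beta_i) ) * sqrt(n) / sigma_p

(n subpathway genes against all N genes of the layer; sigma_p the per-sample
SD of the weighted values). The three activity matrices are stacked and fed
to a random forest; the whole train-search-classify loop runs on the
training half of a stratified random split, is scored by held-out AUC, is
repeated (100 splits by default), and the best-AUC repeat becomes the frozen
`signature_model` used to predict new cohorts.

A seedable synthetic-cohort generator with known embedded signal, plus
recovery metrics, serve as the benchmark bed; expression-only
("gene with pathway") and pathway-free ("gene without pathway") baselines
are built in for comparison.

## A worked example

```r
library(subpathsig)

spec     <- synthetic_spec(n_pathways = 8, seed = 42)   # one embedded 6-gene module, d = 1
pathways <- generate_pathway_set(spec)
study    <- generate_cohort(spec, pathways)             # 60 responders + 60 non-responders

model <- select_signature(study$cohort, pathways,
                          n_repeats = 5, base_seed = 42,
                          params = sa_params(iterations = 1000, restarts = 1),
                          n_perm = 50, n_trees = 500)
model
#> <signature_model: multiomics> best held-out AUC 0.998 (repeat 4 of 5)
#>   1 subpathway(s), 6 signature gene(s)

tidy(model)
#> # A tibble: 1 × 6
#>   subpathway_id pathway_id genes     score  size p_value
#> 1 sp01          sp01       <chr [6]>  7.42     6  0.0196

recovery_metrics(study$truth, model$subpathways)
#> # A tibble: 1 × 3
#>   gene_precision gene_recall subpathway_jaccard
#> 1              1           1                  1
```

The selected signature is exactly the planted 6-gene module (precision and
recall 1), its annealing score is 7.42 with permutation p ≈ 0.02, and the
frozen forest separates held-out samples almost perfectly (AUC 0.998 —
synthetic unit-effect signal is easy; real cohorts are not). `glance(model)`
summarises the repeat trace, `autoplot(model)` plots it, and
`predict_response(model, new_cohort)` applies the frozen signature to new
samples.

Preprocessing helpers mirror the standard cleaning chain:
`filter_expression()` (zero-fraction filter), `preprocess_methylation()`
(CpG NA filter, k-NN imputation, CpG-to-gene averaging),
`collapse_replicates()`, `label_recist()` / `label_gi50()`, and
`align_cohort()`. A thin CLI over the same functions lives at
`inst/cli/subpathsig.R` (subcommands `simulate`, `score`, `search`,
`select`, `predict`).

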