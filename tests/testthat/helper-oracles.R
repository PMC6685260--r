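# Independent reference implementations used as test oracles. These are kept
# deliberately naive and separate from the package's code paths.

# Newton-Raphson maximiser of the logistic log-likelihood for (b0, b1),
# with Wald p from the inverse observed information.
logistic_oracle <- function(x, y, max_iter = 200L, tol = 1e-12) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(t(X) %*% (y - mu))
    W <- mu * (1 - mu)
    info <- t(X) %*% (X * W)
    step <- solve(info, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(info)))
  z <- unname(beta[2] / se[2])
  list(beta = unname(beta[2]), p_value = 2 * pnorm(-abs(z)))
}

# draw a non-separable logistic instance (the MLE does not exist under
# complete separation, so the oracle comparison is only defined without it)
random_logistic_instance <- function() {
  repeat {
    n <- sample(12:40, 1)
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    if (max(x[y == 0]) < min(x[y == 1]) || max(x[y == 1]) < min(x[y == 0])) next
    return(list(x = x, y = y))
  }
}

# straightforward transliteration of the subpathway activity statistic
zsp_oracle <- function(values, beta, sub_genes, sample_id) {
  Y <- values[, sample_id] * beta
  members <- intersect(sub_genes, rownames(values))
  n <- length(members)
  sigma <- sqrt(mean((Y - mean(Y))^2))
  (mean(Y[members]) - mean(Y)) * sqrt(n) / sigma
}

# small random connected graph built with igraph primitives (independent of
# the package's Pruefer-based generator)
random_connected_pathway <- function(n, extra_edges = n, id = "px") {
  g <- igraph::sample_tree(n)
  missing <- igraph::complementer(g)
  m <- min(extra_edges, igraph::ecount(missing))
  if (m > 0) {
    el <- igraph::as_edgelist(missing)
    pick <- sample.int(nrow(el), m)
    g <- igraph::add_edges(g, t(el[pick, , drop = FALSE]))
  }
  labels <- sprintf("%s_g%02d", id, seq_len(n))
  el <- igraph::as_edgelist(g)
  pathway_graph(id, edges = cbind(labels[el[, 1]], labels[el[, 2]]),
                nodes = labels)
}

# tiny deterministic cohort for IO/activity tests, built by hand
toy_cohort <- function(n_genes = 10, n_samples = 12, seed = 11) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  samples <- sprintf("s%02d", seq_len(n_samples))
  mk <- function(kind) {
    lat <- matrix(rnorm(n_genes * n_samples), n_genes,
                  dimnames = list(genes, samples))
    vals <- switch(kind, expression = exp(lat), cnv = lat,
                   methylation = plogis(lat))
    omics_matrix(vals, kind, allow_na = FALSE)
  }
  labels <- response_labels(samples, rep(c("responder", "non_responder"),
                                         length.out = n_samples))
  suppressMessages(align_cohort(mk("expression"), mk("cnv"), mk("methylation"),
                                labels))
}
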