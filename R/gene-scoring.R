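P_FLOOR <- 1e-300

#' Combine per-omic p-values into a single gene score
#'
#' The multi-omics gene score is the sum of the negative natural logarithms of
#' the per-layer p-values, `-sum(log(p))` — a Fisher-style evidence sum that
#' grows as any layer's association strengthens. It is permutation-invariant
#' in its arguments and additive over layers.
#'
#' @param p_values numeric vector of p-values, each in (0, 1\].
#' @return non-negative scalar score.
#' @export
#' @examples
#' combined_score(c(exp(-1), exp(-2), exp(-3)))  # exactly 6
combined_score <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  -sum(log(p))
}

# Wald standard errors from the observed information at the fitted
# coefficients (binomial dispersion fixed at 1)
wald_se_logistic <- function(X, beta) {
  mu <- plogis(drop(X %*% beta))
  info <- crossprod(X, X * (mu * (1 - mu)))
  sqrt(diag(solve(info)))
}

# IRLS for logistic regression with an L2 penalty on the slope terms only;
# used as the fallback under (quasi-)separation, where the unpenalised MLE
# diverges. Wald covariance is the inverse penalised information.
ridge_logit <- function(X, y, lambda = 1e-4, max_iter = 200L, tol = 1e-10) {
  penalty <- c(0, rep(lambda, ncol(X) - 1L))
  beta <- numeric(ncol(X))
  H <- NULL
  for (it in seq_len(max_iter)) {
    mu <- plogis(drop(X %*% beta))
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X, X * w) + diag(penalty, ncol(X))
    g <- drop(crossprod(X, y - mu)) - penalty * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, se = sqrt(diag(solve(H))))
}

#' Univariate logistic association of one feature with drug response
#'
#' Fits `logit P(responder) = b0 + b1 * x` on the raw feature values
#' (responder coded 1) and returns the slope and its p-value. The default
#' test is the Wald z-test; a likelihood-ratio test is available. When the
#' fit does not converge or the classes are (quasi-)separated, the model is
#' refit with a small L2 penalty on the slope (`lambda = 1e-4`) and the
#' penalised Wald p is returned, which keeps p-values away from exact zero.
#' P-values are clamped to `[1e-300, 1]`. A constant feature carries no
#' information and yields `p = 1`, `beta = 0` with `degenerate = TRUE`.
#'
#' @param feature numeric vector; if named, names must match the label table's
#'   sample ids (any order), otherwise positional alignment is assumed.
#' @param labels a `response_labels` tibble, or a 0/1 (or two-level factor)
#'   vector aligned with `feature`.
#' @param test `"wald"` (default) or `"lrt"`.
#' @param lambda ridge penalty used by the separation fallback.
#' @return list with `p_value`, `beta`, `degenerate`, `method`.
#' @export
fit_univariate_logistic <- function(feature, labels, test = c("wald", "lrt"),
                                    lambda = 1e-4) {
  test <- match.arg(test)
  if (inherits(labels, "response_labels") || is.data.frame(labels)) {
    if (!is.null(names(feature))) {
      if (!setequal(names(feature), labels$sample_id)) {
        abort("feature and labels cover different sample sets.")
      }
      feature <- feature[labels$sample_id]
    } else if (length(feature) != nrow(labels)) {
      abort("feature and labels cover different sample sets.")
    }
    y <- as.integer(labels$response == "responder")
  } else {
    if (length(feature) != length(labels)) {
      abort("feature and labels cover different sample sets.")
    }
    y <- if (is.factor(labels)) as.integer(labels == levels(labels)[2L]) else as.integer(labels)
  }
  if (!all(y %in% c(0L, 1L)) || length(unique(y)) < 2L) {
    abort("labels must contain both classes.")
  }
  x <- as.numeric(feature)
  if (anyNA(x)) abort("feature contains missing values.")
  if (diff(range(x)) == 0) {
    return(list(p_value = 1.0, beta = 0.0, degenerate = TRUE, method = "constant"))
  }
  X <- cbind(1, x)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100L)),
    warning = function(w) {
      separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged || separated) {
    rf <- ridge_logit(X, y, lambda = lambda)
    z <- rf$beta[2L] / rf$se[2L]
    p <- 2 * pnorm(-abs(z))
    return(list(p_value = min(max(p, P_FLOOR), 1), beta = unname(rf$beta[2L]),
                degenerate = FALSE, method = "ridge"))
  }
  beta <- unname(fit$coefficients[2L])
  if (test == "wald") {
    se <- wald_se_logistic(X, fit$coefficients)[2L]
    p <- 2 * pnorm(-abs(beta / se))
  } else {
    p <- pchisq(fit$null.deviance - fit$deviance, df = 1L, lower.tail = FALSE)
  }
  list(p_value = min(max(p, P_FLOOR), 1), beta = beta, degenerate = FALSE,
       method = test)
}

#' Score every gene of a cohort against drug response
#'
#' For each gene of the universe (by default the genes present in all three
#' layers) the univariate logistic model is fit per omic layer on the raw
#' measurements, and the per-layer p-values are combined with
#' [combined_score()]. Deterministic given its input.
#'
#' @param cohort a `drug_cohort` (see [align_cohort()]).
#' @param gene_universe optional character vector restricting the genes scored.
#' @param test association test passed to [fit_univariate_logistic()].
#' @return a tibble with one row per gene: `gene_id`, `p_expression`,
#'   `beta_expression`, `p_cnv`, `beta_cnv`, `p_methylation`,
#'   `beta_methylation`, `score`.
#' @export
score_genes <- function(cohort, gene_universe = NULL, test = "wald") {
  universe <- gene_universe %||% cohort_gene_universe(cohort)
  if (!length(universe)) abort("empty gene universe.")
  missing <- universe[!(universe %in% rownames(cohort$expression) &
                          universe %in% rownames(cohort$cnv) &
                          universe %in% rownames(cohort$methylation))]
  if (length(missing)) {
    abort(paste0("gene(s) absent from some layer: ",
                 paste(head(missing, 5L), collapse = ", ")))
  }
  layers <- c("expression", "cnv", "methylation")
  per_layer <- lapply(layers, function(layer) {
    mat <- unclass(cohort[[layer]])[universe, , drop = FALSE]
    res <- vapply(universe, function(g) {
      f <- fit_univariate_logistic(mat[g, ], cohort$labels, test = test)
      c(f$p_value, f$beta)
    }, numeric(2L))
    tibble::tibble(!!paste0("p_", layer) := res[1L, ],
                   !!paste0("beta_", layer) := res[2L, ])
  })
  out <- dplyr::bind_cols(tibble::tibble(gene_id = universe), per_layer)
  out$score <- -(log(out$p_expression) + log(out$p_cnv) + log(out$p_methylation))
  out
}

#' Standardize combined gene scores over a background universe
#'
#' Converts combined scores to z-scores, `z = (score - mu) / sigma`, with
#' `mu` and `sigma` the mean and standard deviation over the whole gene
#' universe. This makes subnetwork scores comparable across subset sizes. A
#' degenerate universe (all scores equal) maps to all-zero z.
#'
#' @param scores a gene score tibble from [score_genes()] (or any tibble with
#'   `gene_id` and `score` columns).
#' @param universe gene ids defining the background (default: all scored genes).
#' @return named numeric vector of z-scores over `universe`.
#' @export
standardize_scores <- function(scores, universe = scores$gene_id) {
  if (length(universe) < 2L) abort("need at least 2 genes to standardize.")
  idx <- match(universe, scores$gene_id)
  if (anyNA(idx)) {
    abort(paste0("gene(s) without a score: ",
                 paste(head(universe[is.na(idx)], 5L), collapse = ", ")))
  }
  s <- scores$score[idx]
  mu <- mean(s)
  sigma <- sqrt(mean((s - mu)^2))  # population SD: the universe IS the background
  z <- if (sigma == 0) rep(0, length(s)) else (s - mu) / sigma
  setNames(z, universe)
}
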