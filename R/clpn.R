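#' Estimation configuration for cross-lagged panel networks
#'
#' Node-wise L1-penalized (LASSO) regression with K-fold cross-validated
#' lambda. `cv_min` picks the prediction-error-minimizing lambda, `cv_1se`
#' the one-standard-error rule, `fixed` uses `fixed_lambda` as given
#' (0 yields the unpenalized least-squares fit).
#'
#' @param lambda_rule `"cv_min"` (default), `"cv_1se"`, or `"fixed"`.
#' @param fixed_lambda nonnegative lambda, required when
#'   `lambda_rule = "fixed"`.
#' @param nfolds number of CV folds (default 10, minimum 2).
#' @param seed integer seed controlling the fold assignment (shared across
#'   the 24 node regressions).
#' @param standardize passed to glmnet's internal predictor standardization.
#' @param penalize_covariates if `FALSE` (default) covariates enter with
#'   penalty factor 0 so adjustment is never shrunk away.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(lambda_rule = c("cv_min", "cv_1se", "fixed"),
                       fixed_lambda = NULL, nfolds = 10L, seed = 1L,
                       standardize = TRUE, penalize_covariates = FALSE) {
  lambda_rule <- match.arg(lambda_rule)
  if (nfolds < 2) fail("fit_config: nfolds must be at least 2")
  if (lambda_rule == "fixed") {
    if (is.null(fixed_lambda) || fixed_lambda < 0)
      fail("fit_config: lambda_rule = 'fixed' needs fixed_lambda >= 0")
  }
  structure(list(lambda_rule = lambda_rule, fixed_lambda = fixed_lambda,
                 nfolds = as.integer(nfolds), seed = as.integer(seed),
                 standardize = isTRUE(standardize),
                 penalize_covariates = isTRUE(penalize_covariates)),
            class = "fit_config")
}

#' Z-standardize node scores
#'
#' Centers and scales every node column to mean 0, variance 1 using the
#' population convention (denominator n). Standardizing within each analysis
#' group makes edge weights comparable across nodes of heterogeneous scales.
#'
#' @param scores a `node_scores` object or numeric matrix.
#' @return object of the same kind with standardized columns.
#' @export
standardize_nodes <- function(scores) {
  m <- as_node_matrix(scores)
  mu <- colMeans(m)
  s <- col_pop_sd(m)
  zero <- which(s == 0)
  if (length(zero) > 0)
    fail("standardize_nodes: zero-variance node(s): %s",
         paste(colnames(m)[zero] %||% zero, collapse = ", "))
  z <- sweep(sweep(m, 2, mu), 2, s, "/")
  if (inherits(scores, "node_scores")) {
    scores$scores <- z
    scores
  } else z
}

# Single-lambda glmnet fit along a short descending path for numerical
# stability; returns coefficients at exactly `lam`.
glmnet_at <- function(x, y, lam, pf, standardize) {
  path <- sort(unique(c(pmax(lam, 1e-4) * c(16, 8, 4, 2), lam)),
               decreasing = TRUE)
  # the unpenalized limit needs a gentler descent and a tighter tolerance
  # to agree with the normal-equations solution to ~1e-8
  thresh <- if (lam == 0) 1e-14 else 1e-11
  if (lam == 0)
    path <- c(path[path > 0], 1e-4 / c(4, 16, 64, 256), 0)
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                        lambda = path, penalty.factor = pf,
                        standardize = standardize, thresh = thresh,
                        maxit = 1e6)
  as.numeric(coef(fit, s = lam, exact = FALSE))
}

#' Fit one node's lagged regression
#'
#' Regresses a wave-2 node on all wave-1 nodes (plus covariates) with an L1
#' penalty. Covariate coefficients are returned separately and never enter
#' the network matrix. Fold assignment is seed-deterministic.
#'
#' @param y numeric wave-2 node column.
#' @param X numeric matrix of wave-1 nodes (first) and covariate columns.
#' @param config a [fit_config()].
#' @param n_penalized number of leading columns of `X` that are penalized
#'   network predictors (default: all).
#' @return list with `coef` (penalized predictors), `covariate_coef`,
#'   `intercept`, and `lambda` (the selected value).
#' @export
fit_node_regression <- function(y, X, config = fit_config(),
                                n_penalized = ncol(X)) {
  X <- as.matrix(X)
  n <- length(y)
  if (ncol(X) < 1) fail("fit_node_regression: X needs at least one column")
  sds <- col_pop_sd(X)
  if (any(sds == 0))
    fail("fit_node_regression: constant predictor column(s): %s",
         paste(colnames(X)[sds == 0] %||% which(sds == 0), collapse = ", "))
  pf <- c(rep(1, n_penalized),
          rep(if (config$penalize_covariates) 1 else 0,
              ncol(X) - n_penalized))

  if (config$lambda_rule == "fixed") {
    lam <- config$fixed_lambda
    beta <- glmnet_at(X, y, lam, pf, config$standardize)
  } else {
    if (n <= 2 * config$nfolds)
      fail("fit_node_regression: need n > 2 * nfolds (n = %d, folds = %d)",
           n, config$nfolds)
    foldid <- withr::with_seed(config$seed,
                               sample(rep(seq_len(config$nfolds),
                                          length.out = n)))
    cvfit <- tryCatch(
      glmnet::cv.glmnet(X, y, family = "gaussian", alpha = 1,
                        foldid = foldid, penalty.factor = pf,
                        standardize = config$standardize),
      error = function(e)
        fail("fit_node_regression failed: %s", conditionMessage(e)))
    lam <- if (config$lambda_rule == "cv_min") cvfit$lambda.min
           else cvfit$lambda.1se
    beta <- as.numeric(coef(cvfit, s = lam))
  }
  list(intercept = beta[1],
       coef = setNames(beta[1 + seq_len(n_penalized)],
                       colnames(X)[seq_len(n_penalized)]),
       covariate_coef = if (ncol(X) > n_penalized)
         setNames(beta[-(seq_len(1 + n_penalized))],
                  colnames(X)[-seq_len(n_penalized)]) else numeric(0),
       lambda = lam)
}

# Dummy-code a covariate data.frame (first level of each factor is the
# reference); drops zero-variance columns, which arise in small resamples.
covariate_design <- function(covariates) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0)
    return(NULL)
  covariates <- as.data.frame(covariates)
  chr <- vapply(covariates, is.character, TRUE)
  covariates[chr] <- lapply(covariates[chr], factor)
  mm <- model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  keep <- col_pop_sd(mm) > 0
  mm[, keep, drop = FALSE]
}

#' Estimate a cross-lagged panel network
#'
#' Runs one L1-penalized regression per wave-2 node on all 24 wave-1 nodes
#' plus (unpenalized, dummy-coded) covariates, and assembles the directed
#' weight matrix `W` with `W[i, j]` the standardized lagged effect of wave-1
#' node i on wave-2 node j. The diagonal holds autoregressive coefficients.
#' Node columns of both waves are z-standardized (population convention)
#' before fitting; analysis is complete-case. Deterministic given the config
#' seed.
#'
#' @param w1,w2 `node_scores` objects (or matrices with identical rownames)
#'   for waves 1 and 2, same participants in the same order.
#' @param covariates optional data.frame of covariates, rows aligned with
#'   the score matrices.
#' @param config a [fit_config()].
#' @return object of class `clpn`: list with `W` (24 x 24), `nodes`,
#'   `lambda` (per-node selected value), `covariate_coef`, `n`, `config`.
#' @export
fit_clpn <- function(w1, w2, covariates = NULL, config = fit_config()) {
  m1 <- as_node_matrix(w1); m2 <- as_node_matrix(w2)
  if (!identical(dim(m1), dim(m2)))
    fail("fit_clpn: wave matrices differ in dimension")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    fail("fit_clpn: participant mismatch between waves")
  info <- clpn_node_info()
  p <- nrow(info)
  if (ncol(m1) != p) fail("fit_clpn: expected %d node columns", p)

  cov_mm <- covariate_design(covariates)
  ok <- complete.cases(m1) & complete.cases(m2)
  if (!is.null(cov_mm)) ok <- ok & complete.cases(cov_mm)
  m1 <- m1[ok, , drop = FALSE]; m2 <- m2[ok, , drop = FALSE]
  if (!is.null(cov_mm)) cov_mm <- cov_mm[ok, , drop = FALSE]
  n <- nrow(m1)

  z1 <- standardize_nodes(m1)
  z2 <- standardize_nodes(m2)
  X <- if (is.null(cov_mm)) z1 else cbind(z1, cov_mm)

  W <- matrix(0, p, p, dimnames = list(info$node, info$node))
  lambda <- setNames(numeric(p), info$node)
  cov_coef <- NULL
  for (j in seq_len(p)) {
    fit <- tryCatch(
      fit_node_regression(z2[, j], X, config, n_penalized = p),
      error = function(e)
        fail("fit_clpn: node '%s' failed: %s", info$node[j],
             conditionMessage(e)))
    W[, j] <- fit$coef
    lambda[j] <- fit$lambda
    if (length(fit$covariate_coef) > 0) {
      if (is.null(cov_coef))
        cov_coef <- matrix(0, length(fit$covariate_coef), p,
                           dimnames = list(names(fit$covariate_coef),
                                           info$node))
      cov_coef[, j] <- fit$covariate_coef
    }
  }
  if (any(!is.finite(W))) fail("fit_clpn: non-finite weight produced")
  structure(list(W = W, nodes = info, lambda = lambda,
                 covariate_coef = cov_coef, n = n, config = config),
            class = "clpn")
}

#' @export
print.clpn <- function(x, ...) {
  off <- x$W[row(x$W) != col(x$W)]
  cat(sprintf("<clpn> %d nodes, n = %d, %d nonzero cross-lagged edges (density %.2f)\n",
              ncol(x$W), x$n, sum(off != 0), mean(off != 0)))
  invisible(x)
}

#' Edge list above a display threshold
#'
#' Returns edges with `|weight| >= threshold` (and nonzero) for export or
#' plotting; the network matrix itself is never modified. The conventional
#' display threshold is 0.05.
#'
#' @param net a `clpn` object (or bare weight matrix).
#' @param threshold nonnegative absolute-weight threshold.
#' @return data.frame: `from`, `to`, `weight`, `from_construct`,
#'   `to_construct`, `autoregressive`, ordered by decreasing `|weight|`.
#' @export
display_threshold <- function(net, threshold = 0.05) {
  if (threshold < 0) fail("display_threshold: threshold must be >= 0")
  W <- if (inherits(net, "clpn")) net$W else as.matrix(net)
  info <- clpn_node_info()
  idx <- which(W != 0 & abs(W) >= threshold, arr.ind = TRUE)
  out <- data.frame(
    from = info$node[idx[, 1]],
    to = info$node[idx[, 2]],
    weight = W[idx],
    from_construct = info$construct[idx[, 1]],
    to_construct = info$construct[idx[, 2]],
    autoregressive = idx[, 1] == idx[, 2],
    stringsAsFactors = FALSE)
  out[order(-abs(out$weight)), , drop = FALSE]
}

#' Export a network as GraphML
#'
#' Writes the thresholded edge list as a directed GraphML graph (node
#' attribute `construct`, edge attribute `weight`) for use in graph tools.
#'
#' @param net a `clpn` object.
#' @param path output file path.
#' @param threshold display threshold applied to the exported edges.
#' @return `path`, invisibly.
#' @export
write_clpn_graphml <- function(net, path, threshold = 0) {
  info <- clpn_node_info()
  edges <- display_threshold(net, threshold)
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "weight")], directed = TRUE,
    vertices = data.frame(name = info$node, construct = info$construct))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
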