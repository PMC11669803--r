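# Shared internals for the resampling machinery -------------------------

# Re-estimate the network on a row subset with per-node lambdas frozen at
# their full-sample values (the default bootstrap mode, in which lambda is
# treated as part of the estimator); re-running CV per resample is available
# through refit_lambda = TRUE in the public functions.
refit_fixed_clpn <- function(m1, m2, cov_mm, lambdas, standardize) {
  p <- ncol(m1)
  z1 <- standardize_nodes(m1)
  z2 <- standardize_nodes(m2)
  if (!is.null(cov_mm)) {
    keep <- col_pop_sd(cov_mm) > 0
    cov_mm <- cov_mm[, keep, drop = FALSE]
    if (ncol(cov_mm) == 0) cov_mm <- NULL
  }
  X <- if (is.null(cov_mm)) z1 else cbind(z1, cov_mm)
  pf <- c(rep(1, p), rep(0, ncol(X) - p))
  W <- matrix(0, p, p, dimnames = list(colnames(m1), colnames(m1)))
  for (j in seq_len(p)) {
    beta <- glmnet_at(X, z2[, j], lambdas[j], pf, standardize)
    W[, j] <- beta[1 + seq_len(p)]
  }
  W
}

# Draw a row index set whose node columns all retain variance; redraws (with
# a count) when a degenerate resample appears. Errors if the *input* data is
# degenerate, since no resample could then succeed.
draw_valid_rows <- function(m1, m2, n_out, replace, max_redraw = 100L) {
  n <- nrow(m1)
  if (any(col_pop_sd(m1) == 0) || any(col_pop_sd(m2) == 0))
    fail("resampling rejected: a node column has zero variance in the input data")
  redraws <- 0L
  repeat {
    idx <- sample.int(n, n_out, replace = replace)
    ok <- all(col_pop_sd(m1[idx, , drop = FALSE]) > 0) &&
      all(col_pop_sd(m2[idx, , drop = FALSE]) > 0)
    if (ok) return(list(idx = idx, redraws = redraws))
    redraws <- redraws + 1L
    if (redraws > max_redraw)
      fail("resampling failed: %d consecutive degenerate resamples", max_redraw)
  }
}

prepare_boot_inputs <- function(w1, w2, covariates, config) {
  net <- fit_clpn(w1, w2, covariates, config)
  m1 <- as_node_matrix(w1); m2 <- as_node_matrix(w2)
  cov_mm <- covariate_design(covariates)
  ok <- complete.cases(m1) & complete.cases(m2)
  if (!is.null(cov_mm)) ok <- ok & complete.cases(cov_mm)
  list(net = net,
       m1 = m1[ok, , drop = FALSE],
       m2 = m2[ok, , drop = FALSE],
       cov_mm = if (is.null(cov_mm)) NULL else cov_mm[ok, , drop = FALSE])
}

# Public API -------------------------------------------------------------

#' Nonparametric bootstrap confidence intervals for edge weights
#'
#' Resamples participants with replacement, re-estimates the network per
#' resample, and returns percentile (2.5% / 97.5%) confidence bounds and the
#' bootstrap mean for every edge. Wider intervals indicate poorer precision
#' of the edge estimate. Resamples in which any node loses all variance are
#' redrawn, with a logged count. Deterministic given `seed`.
#'
#' @param w1,w2 `node_scores` (or matrices), as in [fit_clpn()].
#' @param covariates optional covariate data.frame.
#' @param config a [fit_config()] for the full-sample fit.
#' @param iterations number of bootstrap resamples (1000 for full runs).
#' @param seed integer seed.
#' @param refit_lambda re-run lambda selection inside every resample
#'   (slower); default `FALSE` reuses the full-sample per-node lambdas.
#' @return object of class `clpn_boot`: the full-sample `net`, arrays
#'   `boot` (iterations x 24 x 24), matrices `lower`, `mean`, `upper`,
#'   plus `iterations`, `seed`, `n_redraws`.
#' @export
bootstrap_edge_cis <- function(w1, w2, covariates = NULL,
                               config = fit_config(), iterations = 1000L,
                               seed = 1L, refit_lambda = FALSE) {
  if (iterations < 2) fail("bootstrap_edge_cis: need at least 2 iterations")
  inp <- prepare_boot_inputs(w1, w2, covariates, config)
  p <- ncol(inp$m1); n <- nrow(inp$m1)
  boot <- array(NA_real_, c(iterations, p, p),
                dimnames = list(NULL, colnames(inp$m1), colnames(inp$m1)))
  n_redraws <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(iterations)) {
      dr <- draw_valid_rows(inp$m1, inp$m2, n, replace = TRUE)
      n_redraws <- n_redraws + dr$redraws
      idx <- dr$idx
      W <- if (refit_lambda) {
        cfg <- config; cfg$seed <- derive_seed(seed, paste0("boot", b))
        fit_clpn(inp$m1[idx, , drop = FALSE], inp$m2[idx, , drop = FALSE],
                 if (is.null(inp$cov_mm)) NULL else
                   as.data.frame(inp$cov_mm[idx, , drop = FALSE]), cfg)$W
      } else {
        refit_fixed_clpn(inp$m1[idx, , drop = FALSE],
                         inp$m2[idx, , drop = FALSE],
                         if (is.null(inp$cov_mm)) NULL else
                           inp$cov_mm[idx, , drop = FALSE],
                         inp$net$lambda, config$standardize)
      }
      boot[b, , ] <- W
    }
  })
  structure(list(net = inp$net,
                 boot = boot,
                 lower = apply(boot, c(2, 3), quantile, 0.025),
                 mean = apply(boot, c(2, 3), mean),
                 upper = apply(boot, c(2, 3), quantile, 0.975),
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 n_redraws = n_redraws),
            class = "clpn_boot")
}

#' @export
print.clpn_boot <- function(x, ...) {
  cat(sprintf("<clpn_boot> %d iterations, n = %d, median CI width %.3f\n",
              x$iterations, x$net$n, stats::median(x$upper - x$lower)))
  invisible(x)
}

parse_edge <- function(e) {
  if (is.character(e) && length(e) == 1 && grepl("->", e, fixed = TRUE))
    e <- trimws(strsplit(e, "->", fixed = TRUE)[[1]])
  if (length(e) != 2) fail("an edge must be c(from, to) or 'from->to'")
  info <- clpn_node_info()
  c(node_index(e[1], info), node_index(e[2], info))
}

#' Bootstrap test for a difference between two edge weights
#'
#' Two edges differ significantly when the bootstrap percentile CI of their
#' per-resample difference excludes zero.
#'
#' @param boot a `clpn_boot` object.
#' @param edge_a,edge_b edges given as `c(from, to)` label pairs or
#'   `"from->to"` strings; must be distinct.
#' @param level CI level (default 0.95).
#' @return list with `significant` (logical), `ci`, and `difference` (the
#'   full-sample difference).
#' @export
edge_difference_test <- function(boot, edge_a, edge_b, level = 0.95) {
  a <- parse_edge(edge_a); b <- parse_edge(edge_b)
  if (identical(a, b)) fail("edge_difference_test: the two edges are identical")
  d <- boot$boot[, a[1], a[2]] - boot$boot[, b[1], b[2]]
  alpha <- (1 - level) / 2
  ci <- unname(quantile(d, c(alpha, 1 - alpha)))
  list(significant = ci[1] > 0 || ci[2] < 0, ci = ci,
       difference = boot$net$W[a[1], a[2]] - boot$net$W[b[1], b[2]])
}

#' Case-drop bootstrap for centrality stability
#'
#' For each drop proportion in the grid, repeatedly subsamples participants
#' without replacement, re-estimates the network, and records the Pearson
#' correlation (across the 24 nodes) between subsample and full-sample
#' centrality for each index (autoregressive effects removed throughout).
#'
#' @inheritParams bootstrap_edge_cis
#' @param grid drop proportions, all in `[0, 1)` (default 10%..75% by 5%).
#' @param iterations subsamples per grid level (1000 for full runs; 250 is
#'   the conventional reduced setting).
#' @return object of class `clpn_stability`: `grid`, `correlations`
#'   (levels x iterations x 4 indices), the full-sample `centrality`,
#'   `iterations`, `seed`, `n`, `n_redraws`.
#' @export
case_drop_bootstrap <- function(w1, w2, covariates = NULL,
                                config = fit_config(),
                                grid = seq(0.10, 0.75, by = 0.05),
                                iterations = 250L, seed = 1L,
                                refit_lambda = FALSE) {
  if (any(grid < 0 | grid >= 1))
    fail("case_drop_bootstrap: drop proportions must lie in [0, 1)")
  inp <- prepare_boot_inputs(w1, w2, covariates, config)
  p <- ncol(inp$m1); n <- nrow(inp$m1)
  if (floor((1 - max(grid)) * n) < 10 * p)
    fail("case_drop_bootstrap: smallest retained subsample (%d) is below 10 x node count (%d)",
         floor((1 - max(grid)) * n), 10 * p)
  full_cent <- centrality_table(inp$net)
  idxn <- centrality_indices()
  cors <- array(NA_real_, c(length(grid), iterations, length(idxn)),
                dimnames = list(paste0("drop_", grid), NULL, idxn))
  n_redraws <- 0L
  withr::with_seed(seed, {
    for (g in seq_along(grid)) {
      n_keep <- floor((1 - grid[g]) * n)
      for (b in seq_len(iterations)) {
        dr <- draw_valid_rows(inp$m1, inp$m2, n_keep, replace = FALSE)
        n_redraws <- n_redraws + dr$redraws
        idx <- dr$idx
        W <- if (refit_lambda) {
          cfg <- config
          cfg$seed <- derive_seed(seed, sprintf("drop%d_%d", g, b))
          fit_clpn(inp$m1[idx, , drop = FALSE], inp$m2[idx, , drop = FALSE],
                   if (is.null(inp$cov_mm)) NULL else
                     as.data.frame(inp$cov_mm[idx, , drop = FALSE]), cfg)$W
        } else {
          refit_fixed_clpn(inp$m1[idx, , drop = FALSE],
                           inp$m2[idx, , drop = FALSE],
                           if (is.null(inp$cov_mm)) NULL else
                             inp$cov_mm[idx, , drop = FALSE],
                           inp$net$lambda, config$standardize)
        }
        cent <- centrality_table(W)
        for (k in seq_along(idxn))
          cors[g, b, k] <- suppressWarnings(
            cor(full_cent[[idxn[k]]], cent[[idxn[k]]]))
      }
    }
  })
  structure(list(grid = grid, correlations = cors,
                 centrality = full_cent,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed), n = n, n_redraws = n_redraws),
            class = "clpn_stability")
}

#' @export
print.clpn_stability <- function(x, ...) {
  cs <- vapply(centrality_indices(), function(i) cs_coefficient(x, i), 0)
  cat("<clpn_stability> CS coefficients:",
      paste(sprintf("%s = %.2f", names(cs), cs), collapse = ", "), "\n")
  invisible(x)
}

#' Correlation-stability (CS) coefficient
#'
#' The CS coefficient is the largest drop proportion in the grid at which at
#' least `prob` (default 95%) of the subsample centrality correlations stay
#' at or above `cor_threshold` (default 0.7); 0 if no level qualifies. By
#' convention, CS >= 0.25 is acceptable stability and CS > 0.5 strong
#' stability. Subsamples with undefined correlations count as failures.
#'
#' @param stab a `clpn_stability` object.
#' @param index one of `"in_ei"`, `"out_ei"`, `"bridge_in_ei"`,
#'   `"bridge_out_ei"`.
#' @param cor_threshold,prob the criterion constants.
#' @return the CS coefficient (an element of the grid, or 0).
#' @export
cs_coefficient <- function(stab, index, cor_threshold = 0.7, prob = 0.95) {
  if (!index %in% dimnames(stab$correlations)[[3]])
    fail("cs_coefficient: no stability results for index '%s'", index)
  cc <- stab$correlations[, , index, drop = FALSE]
  okshare <- apply(cc, 1, function(v) mean(!is.na(v) & v >= cor_threshold))
  qualifying <- stab$grid[okshare >= prob]
  if (length(qualifying) == 0) 0 else max(qualifying)
}

#' Tidy stability curves
#'
#' Per-level summary of the subsample correlations of each centrality index,
#' for export or plotting.
#'
#' @param stab a `clpn_stability` object.
#' @return data.frame: `drop`, `index`, `mean`, `q025`, `q975`.
#' @export
stability_curves <- function(stab) {
  idxn <- dimnames(stab$correlations)[[3]]
  out <- expand.grid(drop = stab$grid, index = idxn,
                     stringsAsFactors = FALSE)
  stats_f <- function(g, k) {
    v <- stab$correlations[g, , k]
    c(mean(v, na.rm = TRUE),
      quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
  }
  s <- t(mapply(stats_f, match(out$drop, stab$grid), out$index))
  out$mean <- s[, 1]; out$q025 <- s[, 2]; out$q975 <- s[, 3]
  out
}
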