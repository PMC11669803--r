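# Shared fixtures: everything is generated in code at test time.

cape_cols <- sprintf("cape_%02d", 1:15)

# A small scored cohort (node matrices for both waves + covariates).
scored_cohort <- function(n, seed, truth = default_truth_matrix(), ...) {
  cohort <- generate_cohort(sim_config(n_participants = n, seed = seed,
                                       truth_matrix = truth, ...))
  d <- cohort$data
  covars <- d[d$wave == 1, , drop = FALSE]
  covars <- covars[order(covars$id),
                   c("age", "sex", "mental_history"), drop = FALSE]
  list(w1 = node_scores(d, 1), w2 = node_scores(d, 2),
       covariates = covars, data = d, truth = cohort$truth)
}

# Independent least-squares oracle: per-node OLS by explicit normal
# equations, on already-standardized matrices.
ols_oracle <- function(z1, z2) {
  X <- cbind(1, z1)
  B <- solve(crossprod(X), crossprod(X, z2))
  B[-1, , drop = FALSE]
}

# Build a minimal clpn_stability object with prescribed correlation values.
fake_stability <- function(grid, cor_by_level, iterations = 50) {
  idxn <- c("in_ei", "out_ei", "bridge_in_ei", "bridge_out_ei")
  cors <- array(rep(rep(cor_by_level, each = 1), iterations * length(idxn)),
                c(length(grid), iterations, length(idxn)),
                dimnames = list(paste0("drop_", grid), NULL, idxn))
  for (g in seq_along(grid)) cors[g, , ] <- cor_by_level[g]
  structure(list(grid = grid, correlations = cors, iterations = iterations,
                 seed = 1L, n = NA_integer_, n_redraws = 0L),
            class = "clpn_stability")
}

# Random weight matrix in canonical node layout.
random_W <- function(seed, density = 0.2, sd = 0.15) {
  withr::with_seed(seed, {
    W <- matrix(rnorm(576, sd = sd) * (runif(576) < density), 24, 24)
    info <- clpn_node_info()
    dimnames(W) <- list(info$node, info$node)
    W
  })
}
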