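test_that("standardization gives population moments and is idempotent", {
  m <- withr::with_seed(4, matrix(rnorm(600, 5, 3), 100, 6))
  z <- standardize_nodes(m)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_equal(unname(apply(z, 2, function(x) mean(x^2))), rep(1, 6))
  expect_equal(standardize_nodes(z), z, tolerance = 1e-12)
  # column (1,2,3): mean 0, population variance 1
  z3 <- standardize_nodes(cbind(a = c(1, 2, 3), b = c(2, 1, 5)))
  expect_equal(mean(z3[, "a"]), 0)
  expect_equal(mean(z3[, "a"]^2), 1)
  m[, 3] <- 7
  colnames(m) <- paste0("n", 1:6)
  expect_error(standardize_nodes(m), "n3")
})

test_that("unpenalized fit equals the normal-equations oracle", {
  withr::with_seed(11, {
    n <- 500
    X <- matrix(rnorm(n * 24), n, 24)
    colnames(X) <- clpn_node_info()$node
    y <- as.numeric(X %*% rnorm(24, 0, 0.2) + rnorm(n))
  })
  fit <- fit_node_regression(y, X, fit_config(lambda_rule = "fixed",
                                              fixed_lambda = 0))
  Xi <- cbind(1, X)
  beta_ols <- solve(crossprod(Xi), crossprod(Xi, y))[-1]
  expect_lt(max(abs(fit$coef - beta_ols)), 1e-6)
})

test_that("a large penalty shrinks everything to zero; a strong effect survives CV", {
  withr::with_seed(12, {
    X <- matrix(rnorm(2000 * 10), 2000, 10)
    colnames(X) <- paste0("x", 1:10)
    y_null <- rnorm(2000)
    y_sig <- 0.8 * X[, 1] + rnorm(2000, sd = 0.1)
  })
  fit0 <- fit_node_regression(y_null, X,
                              fit_config(lambda_rule = "fixed",
                                         fixed_lambda = 5))
  expect_true(all(fit0$coef == 0))
  fit1 <- fit_node_regression(y_sig, X, fit_config("cv_1se", seed = 2))
  expect_gte(fit1$coef["x1"], 0.7)
  expect_lte(fit1$coef["x1"], 0.9)
  expect_true(all(fit1$coef[-1] == 0))
})

test_that("the nonzero edge count is non-increasing in the penalty", {
  sc <- scored_cohort(800, seed = 31)
  counts <- vapply(c(0.005, 0.02, 0.05, 0.1, 0.3), function(l) {
    net <- fit_clpn(sc$w1, sc$w2,
                    config = fit_config("fixed", fixed_lambda = l))
    sum(net$W[row(net$W) != col(net$W)] != 0)
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("fit_clpn is seed-deterministic and recovers autoregression", {
  B <- matrix(0, 24, 24); diag(B) <- 0.5
  # near-noiseless measurement: recovery up to LASSO shrinkage only
  # (Likert discretization attenuates single-item nodes; that regime is
  # covered by the sign-recovery and support-recovery checks)
  sc <- scored_cohort(5000, seed = 17, truth = B,
                      item_noise_sd = 0.2, discretize = FALSE)
  cfg <- fit_config(seed = 9)
  net1 <- fit_clpn(sc$w1, sc$w2, sc$covariates, cfg)
  net2 <- fit_clpn(sc$w1, sc$w2, sc$covariates, cfg)
  expect_identical(net1$W, net2$W)
  expect_true(all(diag(net1$W) >= 0.35 & diag(net1$W) <= 0.65))
  expect_equal(net1$n, 5000)
  # covariate coefficients exist but are kept out of W
  expect_false(is.null(net1$covariate_coef))
  expect_equal(dim(net1$W), c(24, 24))
})

test_that("under a zero cross-lagged truth the estimate stays sparse", {
  B0 <- matrix(0, 24, 24)
  frac_zero <- function(rule, s) {
    sc <- scored_cohort(2000, seed = 200 + s, truth = B0)
    net <- fit_clpn(sc$w1, sc$w2, config = fit_config(rule, seed = s))
    mean(net$W[row(net$W) != col(net$W)] == 0)
  }
  z_1se <- vapply(1:3, function(s) frac_zero("cv_1se", s), 0)
  expect_true(all(z_1se >= 0.95))
  z_min <- vapply(1:3, function(s) frac_zero("cv_min", s), 0)
  expect_true(all(z_min >= 0.85))
})

test_that("a pure-noise covariate barely perturbs the network", {
  sc <- scored_cohort(5000, seed = 23)
  cfg <- fit_config(seed = 3)
  net_a <- fit_clpn(sc$w1, sc$w2, config = cfg)
  noise_cov <- data.frame(noise = withr::with_seed(5, rnorm(5000)))
  net_b <- fit_clpn(sc$w1, sc$w2, noise_cov, cfg)
  expect_lt(max(abs(net_a$W - net_b$W)), 0.02)
})

test_that("mismatched participants or degenerate inputs abort with context", {
  sc <- scored_cohort(300, seed = 41)
  w2_bad <- sc$w2
  rownames(w2_bad$scores) <- rev(rownames(w2_bad$scores))
  expect_error(fit_clpn(sc$w1, w2_bad), "participant mismatch")
  w1_flat <- sc$w1
  w1_flat$scores[, "PAs"] <- 2
  expect_error(fit_clpn(w1_flat, sc$w2), "PAs")
})

test_that("display_threshold filters for display without touching W", {
  W <- matrix(0, 24, 24)
  W[1, 4] <- 0.04; W[2, 5] <- 0.06; W[3, 3] <- -0.5
  net_edges <- display_threshold(W, 0.05)
  expect_equal(nrow(net_edges), 2)
  expect_setequal(net_edges$weight, c(0.06, -0.5))
  expect_true(net_edges$autoregressive[net_edges$from == "PAs"])
  # threshold 0 returns every nonzero edge; zero matrix gives none
  expect_equal(nrow(display_threshold(W, 0)), 3)
  expect_equal(nrow(display_threshold(matrix(0, 24, 24))), 0)
  expect_error(display_threshold(W, -1), ">= 0")
  # the matrix itself is never modified
  expect_equal(W[1, 4], 0.04)
})
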