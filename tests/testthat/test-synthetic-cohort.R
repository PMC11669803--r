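test_that("identical config and seed give bit-identical cohorts", {
  cfg <- sim_config(n_participants = 300, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- generate_cohort(sim_config(n_participants = 300, seed = 43))
  expect_false(identical(a$data, c2$data))
  # ground truth echoes the exact matrix used
  expect_identical(a$truth$truth_matrix, cfg$truth_matrix)
})

test_that("zero truth matrix yields independent waves", {
  B0 <- matrix(0, 24, 24)
  co <- generate_cohort(sim_config(n_participants = 10000, seed = 8,
                                   truth_matrix = B0))
  w1 <- node_scores(co$data, 1)$scores
  w2 <- node_scores(co$data, 2)$scores
  expect_lt(max(abs(cor(w1, w2))), 0.05)
})

test_that("prevalence calibration hits the target at both waves", {
  co <- generate_cohort(sim_config(n_participants = 5000, seed = 13,
                                   prevalence_target = 0.135))
  d1 <- co$data[co$data$wave == 1, ]
  prev <- mean(cape_weighted_score(d1[, cape_cols]) >= 1.57)
  expect_gte(prev, 0.115)
  expect_lte(prev, 0.155)
  expect_equal(co$truth$realized_prevalence, prev)
  # an unreachable target is rejected with an explicit message
  expect_error(generate_cohort(sim_config(n_participants = 500, seed = 1,
                                          prevalence_target = 0.5,
                                          cutoff = 4.5)),
               "outside the achievable range")
})

test_that("invalid covariance matrices are rejected", {
  S <- default_wave1_covariance()
  S[1, 2] <- 0.9  # asymmetric
  expect_error(sim_config(wave1_covariance = S), "not symmetric")
  S2 <- matrix(0.99, 24, 24); diag(S2) <- c(1e-12, rep(1, 23))
  expect_error(sim_config(wave1_covariance = S2), "positive definite")
  expect_error(sim_config(artifact_rates = list(duplicates = 1.5)),
               "\\[0, 1\\]")
})

test_that("artifact injection adds exactly the configured counts, and zero rates are a no-op", {
  cfg <- sim_config(n_participants = 1000, seed = 5,
                    artifact_rates = list(duplicates = 0.02, speeders = 0.01,
                                          psychotic_history = 0.005,
                                          refusals = 0.005,
                                          followup_loss = 0.05))
  co <- generate_cohort(cfg)
  inj <- inject_admin_artifacts(co$data, cfg)
  counts <- attr(inj, "artifact_counts")
  expect_equal(unlist(counts)[c("duplicates", "speeders", "psychotic_history",
                                "refusals")],
               c(duplicates = 20, speeders = 10, psychotic_history = 5,
                 refusals = 5))
  # exactly the flagged wave-1 rows are speeders
  expect_equal(sum(inj$response_time_seconds < 300 & inj$wave == 1), 10)
  # the exclusion report recovers the injected ledger exactly
  res <- apply_exclusions(inj)
  expect_equal(res$flow$removed, unname(unlist(counts))[1:4])
  kept <- complete_followup(res$data)
  expect_equal(attr(kept, "lost_to_followup"), counts$followup_loss)

  cfg0 <- sim_config(n_participants = 200, seed = 5,
                     artifact_rates = list(duplicates = 0, speeders = 0,
                                           psychotic_history = 0,
                                           refusals = 0, followup_loss = 0))
  co0 <- generate_cohort(cfg0)
  inj0 <- inject_admin_artifacts(co0$data, cfg0)
  expect_equal(inj0, co0$data, ignore_attr = TRUE)
})

test_that("ground truth export round-trips losslessly", {
  co <- generate_cohort(sim_config(n_participants = 200, seed = 77,
                                   truth_matrix = random_truth_matrix(3)))
  path <- withr::local_tempfile(fileext = ".csv")
  export_truth(co$truth, path)
  back <- read_truth(path)
  expect_identical(back$truth_matrix, co$truth$truth_matrix)
  expect_equal(back$realized_prevalence, co$truth$realized_prevalence)
  # zero matrix keeps its shape
  t0 <- co$truth; t0$truth_matrix <- matrix(0, 24, 24,
                                            dimnames = dimnames(co$truth$truth_matrix))
  export_truth(t0, path)
  expect_identical(read_truth(path)$truth_matrix, t0$truth_matrix)
})

test_that("with no noise or discretization, OLS recovers the truth matrix", {
  B <- default_truth_matrix()
  co <- generate_cohort(sim_config(n_participants = 20000, seed = 21,
                                   truth_matrix = B, noise_sd = 0,
                                   item_noise_sd = 0, discretize = FALSE))
  w1 <- node_scores(co$data, 1)$scores
  w2 <- node_scores(co$data, 2)$scores
  X <- cbind(1, w1)
  Bhat <- solve(crossprod(X), crossprod(X, w2))[-1, ]
  expect_lt(max(abs(Bhat - B)), 0.02)
})

test_that("Likert discretization preserves the sign of substantial effects", {
  hits <- vapply(1:20, function(s) {
    B <- random_truth_matrix(s, n_edges = 20, beta_range = c(0.15, 0.3))
    co <- generate_cohort(sim_config(n_participants = 10000, seed = 1000 + s,
                                     truth_matrix = B))
    w1 <- node_scores(co$data, 1)$scores
    w2 <- node_scores(co$data, 2)$scores
    X <- cbind(1, w1)
    Bhat <- solve(crossprod(X), crossprod(X, w2))[-1, ]
    big <- abs(B) >= 0.15
    mean(sign(Bhat[big]) == sign(B[big]))
  }, 0)
  expect_gte(mean(hits), 0.95)
})
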