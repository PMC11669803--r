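# A compact cohort with one strong planted edge for CI checks.
strong_edge_cohort <- function(n = 2000, seed = 61) {
  B <- matrix(0, 24, 24)
  diag(B) <- 0.3
  B[12, 1] <- 0.5  # PHQ9 -> PI
  scored_cohort(n, seed = seed, truth = B)
}

test_that("degenerate input data is rejected before resampling", {
  sc <- scored_cohort(300, seed = 3)
  flat1 <- sc$w1$scores
  flat1[] <- rep(flat1[1, ], each = nrow(flat1))  # every row identical
  flat2 <- sc$w2$scores
  flat2[] <- rep(flat2[1, ], each = nrow(flat2))
  expect_error(bootstrap_edge_cis(flat1, flat2, iterations = 5),
               "zero.variance|zero-variance")
})

test_that("bootstrap CIs separate a strong true edge from null edges", {
  sc <- strong_edge_cohort()
  boot <- bootstrap_edge_cis(sc$w1, sc$w2, config = fit_config(seed = 2),
                             iterations = 200, seed = 19)
  expect_equal(dim(boot$boot), c(200, 24, 24))
  # planted PHQ9 -> PI edge: CI excludes zero
  expect_gt(boot$lower["PHQ9", "PI"], 0)
  # null edges: CI contains zero
  for (e in list(c("GAD1", "A5"), c("A2", "PAs"), c("PHQ3", "GAD7")))
    expect_true(boot$lower[e[1], e[2]] <= 0 && boot$upper[e[1], e[2]] >= 0)
  # percentile bounds are ordered (note: the bootstrap mean can fall outside
  # the 95% band for edges selected in under 2.5% of resamples, so the
  # bounds are only guaranteed to bracket each other, not the mean)
  expect_true(all(boot$lower <= boot$upper))
  # reproducible from the seed
  boot2 <- bootstrap_edge_cis(sc$w1, sc$w2, config = fit_config(seed = 2),
                              iterations = 200, seed = 19)
  expect_identical(boot$boot, boot2$boot)

  diff_sig <- edge_difference_test(boot, "PHQ9->PI", "GAD1->A5")
  expect_true(diff_sig$significant)
})

test_that("edge difference test reads the bootstrap distribution", {
  fake <- list(boot = array(0, c(50, 24, 24)),
               net = list(W = matrix(0, 24, 24)))
  fake$boot[, 1, 2] <- 0.5
  class(fake) <- "clpn_boot"
  expect_true(edge_difference_test(fake, c("PI", "BEs"), c("PI", "PAs"))$significant)
  # identical distributions -> not significant
  fake$boot[, 1, 3] <- 0.5
  expect_false(edge_difference_test(fake, c("PI", "BEs"), c("PI", "PAs"))$significant)
  expect_error(edge_difference_test(fake, c("PI", "BEs"), c("PI", "BEs")),
               "identical")
})

test_that("case-drop at zero drop reproduces the full-sample centralities", {
  sc <- scored_cohort(400, seed = 51)
  st <- case_drop_bootstrap(sc$w1, sc$w2, config = fit_config(seed = 1),
                            grid = 0, iterations = 10, seed = 3)
  expect_equal(as.numeric(st$correlations), rep(1, 10 * 4), tolerance = 1e-6)
  expect_error(case_drop_bootstrap(sc$w1, sc$w2, grid = c(0.1, 1)),
               "\\[0, 1\\)")
})

test_that("case-drop bootstrap is seed-deterministic and degrades with depth", {
  sc <- scored_cohort(1000, seed = 52)
  cfg <- fit_config(seed = 4)
  st1 <- case_drop_bootstrap(sc$w1, sc$w2, config = cfg,
                             grid = c(0.1, 0.75), iterations = 40, seed = 6)
  st2 <- case_drop_bootstrap(sc$w1, sc$w2, config = cfg,
                             grid = c(0.1, 0.75), iterations = 40, seed = 6)
  expect_identical(st1$correlations, st2$correlations)
  # shallow drops preserve centralities better than deep drops
  for (k in c("in_ei", "out_ei"))
    expect_gt(mean(st1$correlations[1, , k], na.rm = TRUE),
              mean(st1$correlations[2, , k], na.rm = TRUE))
})

test_that("the CS coefficient scans the grid per its definition", {
  grid <- seq(0.10, 0.75, by = 0.05)
  expect_equal(cs_coefficient(fake_stability(grid, rep(1, length(grid))),
                              "in_ei"), 0.75)
  expect_equal(cs_coefficient(fake_stability(grid, rep(0, length(grid))),
                              "in_ei"), 0)
  # criterion holds up to 30% and fails beyond: brute-force over the grid
  vals <- ifelse(grid < 0.325, 0.9, 0.3)  # holds through the 0.30 level
  expect_equal(cs_coefficient(fake_stability(grid, vals), "out_ei"), 0.30)
  expect_error(cs_coefficient(fake_stability(grid, vals), "pagerank"),
               "no stability results")
})

test_that("bootstrap CI width shrinks with sample size", {
  widths <- vapply(c(1000, 4000), function(n) {
    sc <- strong_edge_cohort(n, seed = 71)
    boot <- bootstrap_edge_cis(sc$w1, sc$w2, config = fit_config(seed = 2),
                               iterations = 100, seed = 5)
    off <- row(boot$lower) != col(boot$lower)
    mean((boot$upper - boot$lower)[off])
  }, 0)
  expect_lt(widths[2], widths[1])
})
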