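test_that("CAPE weighted score is the mean over valid items", {
  expect_equal(cape_weighted_score(rep(1, 15)), 1.0)
  expect_equal(cape_weighted_score(rep(4, 15)), 4.0)
  # 14 valid items summing to 28, one missing
  expect_equal(cape_weighted_score(c(rep(2, 14), NA)), 2.0)
  # no valid items -> missing score
  expect_true(is.na(cape_weighted_score(rep(NA_real_, 15))))
  # matrix input scores row-wise
  m <- matrix(rep(2, 30), nrow = 2)
  expect_equal(cape_weighted_score(m), c(2, 2))
})

test_that("PLEs classification is inclusive at the cut-off and monotone", {
  cls <- classify_ples(c(1.00, 1.57, 4.00))
  expect_equal(as.character(cls), c("negative", "positive", "positive"))
  expect_equal(as.character(classify_ples(1.57, inclusive = FALSE)),
               "negative")
  expect_true(is.na(classify_ples(NA_real_)))
  # monotone: sorted scores never fall back from positive to negative
  s <- sort(runif(200, 1, 4))
  pos <- classify_ples(s) == "positive"
  expect_true(all(diff(as.integer(pos)) >= 0))
})

test_that("factor scores are valid-item means, permutation-invariant, with a completeness rule", {
  spec <- instrument_spec("toy", paste0("i", 1:10), 1L, 5L,
                          factors = list(F1 = paste0("i", 1:3),
                                         F2 = paste0("i", 4:10)))
  items <- data.frame(i1 = 2, i2 = 2, i3 = 2, i4 = 4, i5 = 4, i6 = 4,
                      i7 = 4, i8 = 4, i9 = 4, i10 = NA)
  sc <- score_factors(items, spec)
  expect_equal(sc$F1, 2.0)
  expect_equal(sc$F2, 4.0)  # one of seven missing: mean of the valid six
  # five-item ASLEC-style factor
  spec5 <- instrument_spec("toy5", paste0("j", 1:5), 1L, 5L,
                           factors = list(A = paste0("j", 1:5)))
  expect_equal(score_factors(setNames(as.data.frame(t(1:5)), paste0("j", 1:5)),
                             spec5)$A, 3.0)
  # permutation of items within a factor does not change the score
  spec_perm <- instrument_spec("toy", paste0("i", 1:10), 1L, 5L,
                               factors = list(F1 = c("i3", "i1", "i2"),
                                              F2 = paste0("i", c(6, 10, 4, 7, 9, 5, 8))))
  expect_equal(score_factors(items, spec_perm), sc[, c("F1", "F2")])
  # below 80% completeness the factor is missing (5 of 7 valid = 71%)
  items2 <- items
  items2$i8 <- NA; items2$i9 <- NA
  expect_true(is.na(score_factors(items2, spec)$F2))
  # unknown items in the map are a configuration error
  expect_error(instrument_spec("bad", paste0("i", 1:3), 1L, 4L,
                               factors = list(F = c("i1", "zzz"))),
               "unknown items")
})

test_that("Cronbach's alpha matches a brute-force variance oracle", {
  # k parallel duplicates of one non-constant item -> exactly 1
  x <- c(1, 2, 3, 4, 2, 3)
  expect_equal(cronbach_alpha(cbind(x, x, x, x)), 1.0)
  # hand-built 4 x 3 table against the formula computed independently
  tab <- matrix(c(1, 2, 3, 4,
                  2, 2, 4, 3,
                  1, 3, 3, 4), nrow = 4)
  k <- ncol(tab)
  oracle <- k / (k - 1) * (1 - sum(apply(tab, 2, var)) / var(rowSums(tab)))
  expect_equal(cronbach_alpha(tab), oracle)
  # independent items: alpha near 0 at large n
  ind <- withr::with_seed(42, matrix(rnorm(10000 * 5), ncol = 5))
  expect_lt(abs(cronbach_alpha(ind)), 0.05)
  # degenerate inputs are flagged
  expect_error(cronbach_alpha(cbind(x)), "at least 2 items")
  expect_error(cronbach_alpha(cbind(c(1, 1, 1), c(2, 2, 2))), "zero variance")
})

test_that("node_scores assembles the canonical 24-node layout", {
  sc <- scored_cohort(150, seed = 3)
  expect_s3_class(sc$w1, "node_scores")
  expect_equal(dim(sc$w1$scores), c(150, 24))
  expect_equal(colnames(sc$w1$scores), clpn_node_info()$node)
  expect_equal(table(clpn_node_info()$construct)[["PLEs"]], 3L)
  # factor nodes are means of their items
  d1 <- sc$data[sc$data$wave == 1, ]
  d1 <- d1[order(d1$id), ]
  expect_equal(unname(sc$w1$scores[, "PI"]),
               unname(rowMeans(d1[, sprintf("cape_%02d", 1:5)])))
  expect_equal(unname(sc$w1$scores[, "PHQ3"]), d1$phq_03)
  # duplicate wave rows are rejected
  dup <- rbind(sc$data, sc$data[1, ])
  expect_error(node_scores(dup, 1), "duplicate")
})
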