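test_that("spearmanTest recovers monotone association and handles ties", {
  r <- spearmanTest(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(statEstimate(r), 1.0)
  r <- spearmanTest(c(1, 2, 3, 4), c(40, 30, 20, 10))
  expect_equal(statEstimate(r), -1.0)
  set.seed(71)
  for (i in 1:20) {
    x <- sample(1:6, 12, replace = TRUE)       # tied sample
    y <- sample(1:6, 12, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(statEstimate(spearmanTest(x, y)), oracleSpearman(x, y),
                 tolerance = 1e-12)
  }
  expect_error(spearmanTest(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearmanTest(1:2, 1:2), "at least 3")
})

test_that("spearmanTest is symmetric and order-invariant", {
  set.seed(73)
  x <- rnorm(30); y <- x + rnorm(30)
  a <- spearmanTest(x, y); b <- spearmanTest(y, x)
  expect_equal(statEstimate(a), statEstimate(b))
  expect_equal(statPValue(a), statPValue(b))
  perm <- sample(30)
  c <- spearmanTest(x[perm], y[perm])
  expect_equal(statEstimate(a), statEstimate(c))
})

test_that("partial Spearman adjusts for the covariate as designed", {
  set.seed(79)
  n <- 2000
  ## independent covariate: partial ~ plain
  x <- rnorm(n); y <- x + rnorm(n); z <- rnorm(n)
  expect_lt(abs(statEstimate(partialSpearmanTest(x, y, z)) -
                  statEstimate(spearmanTest(x, y))), 0.05)
  ## y identical to z: association fully explained away
  expect_lt(abs(statEstimate(partialSpearmanTest(x, y, y))), 0.05)
  ## constant z: exact fallback to plain Spearman, with a warning
  expect_warning(res <- partialSpearmanTest(x, y, rep(1, n)), "constant")
  expect_equal(statEstimate(res), statEstimate(spearmanTest(x, y)))
})

test_that("Kruskal-Wallis matches the tie-corrected textbook formula", {
  r <- kruskalWallisTest(list(rep(2, 3), rep(2, 3), rep(2, 3)))
  expect_equal(statEstimate(r), 0)
  expect_equal(statPValue(r), 1)
  set.seed(83)
  for (i in 1:20) {
    g <- list(sample(1:5, 4, TRUE), sample(1:5, 5, TRUE),
              sample(1:5, 6, TRUE))
    if (length(unique(unlist(g))) == 1) next
    expect_equal(statEstimate(kruskalWallisTest(g)), oracleKruskalH(g),
                 tolerance = 1e-10)
  }
  sep <- list(rnorm(10, 0), rnorm(10, 10), rnorm(10, 20))
  expect_lt(statPValue(kruskalWallisTest(sep)), 0.001)
  expect_error(kruskalWallisTest(list(1:5)), "two groups")
})

test_that("rank-sum test is exact for small untied samples", {
  r <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(statPValue(r), 2 * (1 / 20))    # 1 of C(6,3)=20 assignments
  expect_identical(r@details$method, "exact")
  x <- c(3, 1, 4, 1)                           # identical samples
  expect_gt(statPValue(rankSumTest(x, x)), 0.99)
  ## large-sample approximation close to enumeration at n = 7, 7
  set.seed(89)
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(7, 0.5)
    exact <- oracleWilcoxP(a, b)
    approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(exact - approx), 0.02)
    expect_equal(statPValue(rankSumTest(a, b)), exact)  # untied, min n <= 8
  }
})

test_that("Fisher exact test matches enumeration and its invariances", {
  r <- fisherExactTest(matrix(c(10, 10, 10, 10), 2))
  expect_equal(statEstimate(r), 1)
  expect_equal(statPValue(r), 1)
  r <- fisherExactTest(matrix(c(5, 0, 0, 5), 2))
  expect_equal(statPValue(r), 2 / choose(10, 5))
  ## transposition invariance of the 2x2 p value
  set.seed(97)
  tab <- matrix(rpois(4, 8) + 1, 2)
  expect_equal(statPValue(fisherExactTest(tab)),
               statPValue(fisherExactTest(t(tab))))
  ## 2x3 table against full enumeration
  for (i in 1:10) {
    tab <- matrix(rpois(6, 4) + 1, 2)
    expect_equal(statPValue(fisherExactTest(tab)), oracleFisherP(tab),
                 tolerance = 1e-9)
  }
  expect_error(fisherExactTest(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "zero margin")
  expect_error(fisherExactTest(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("MMSE decline is the negated least-squares slope", {
  expect_equal(mmseDecline(cbind(c(0, 5), c(30, 20))), 2.0)
  expect_equal(mmseDecline(cbind(0:4, rep(25, 5))), 0.0)
  set.seed(101)
  t <- sort(runif(6, 0, 8)); s <- 28 - 1.7 * t + rnorm(6)
  beta <- cov(t, s) / var(t)
  expect_equal(mmseDecline(cbind(t, s)), -beta, tolerance = 1e-10)
  expect_true(is.na(mmseDecline(cbind(0, 28))))
  expect_error(mmseDecline(cbind(c(0, 0), c(28, 27))), "strictly increasing")
})

test_that("percentage reporting rounds half-up at the stated precision", {
  expect_equal(formatPercent(633, 1361, 0), 47)
  expect_equal(formatPercent(1282, 1361, 1), 94.2)
  expect_equal(formatPercent(1, 8, 1), 12.5)
  expect_equal(formatPercent(1, 800, 1), 0.1)  # 0.125 rounds half-up
  expect_error(formatPercent(1, 0), "positive")
})

test_that("analyzeCohort assembles the heterogeneity table", {
  co <- scoreCohort(simulateCohort(simConfig(nCases = 600, seed = 30)))
  res <- analyzeCohort(co)
  expect_true(all(c("age_onset_y", "education_y", "mmse_decline", "sex",
                    "apoe_e4", "atypical_syndrome") %in% res$variable))
  ageRow <- res[res$variable == "age_onset_y", ]
  expect_identical(ageRow$analysis, "spearman")
  expect_gt(ageRow$estimate, 0)                # older onset, higher CLix
  expect_lt(ageRow$p_value, 0.001)
  sexRow <- res[res$variable == "sex", ]
  expect_lt(sexRow$median1, sexRow$median2)    # male median below female
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("subtype comparisons run the omnibus and post hoc tests", {
  co <- scoreCohort(simulateCohort(simConfig(nCases = 500, seed = 31)))
  cd <- SummarizedExperiment::colData(co)
  cmp <- subtypeComparison(co, cd$age_onset_y)
  expect_s4_class(cmp$overall, "StatResult")
  expect_equal(nrow(cmp$pairwise), 3L)
  expect_lt(statPValue(cmp$overall), 0.05)     # onset differs by subtype
})
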