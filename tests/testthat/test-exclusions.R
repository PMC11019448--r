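test_that("cascade attributes each case to its first matching rule", {
  m <- randomCountMatrix(6)
  m[, 3] <- NA
  cov <- S4Vectors::DataFrame(
    case_id = paste0("C", 1:6),
    primary_dx_ad = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    neuropath_normal = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    ad_gene_variant = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    hippocampal_sclerosis = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  co <- CLixCohort(m, cov)
  res <- applyExclusions(co)
  ## C1 matches rules 1+2 -> not_ad; C3 matches 3+4 -> no_counts;
  ## C4 matches 4+5 -> gene_variant
  expect_identical(res$reasons$reason,
                   c("not_ad", "normal", "no_counts", "gene_variant",
                     "hipp_sclerosis", NA))
  expect_identical(tallyCounts(res$tally)[["n_remaining"]], 6L - 5L)
  expect_identical(SummarizedExperiment::colData(res$cohort)$case_id, "C6")
})

test_that("a flag-free complete cohort passes through unchanged", {
  co <- simulateCohort(simConfig(nCases = 40, seed = 2))
  res <- applyExclusions(co)
  expect_identical(res$tally@nExcluded, 0L)
  expect_identical(SummarizedExperiment::colData(res$cohort)$case_id,
                   SummarizedExperiment::colData(co)$case_id)
})

test_that("an empty cohort tallies all zeros", {
  co <- simulateCohort(simConfig(nCases = 10, seed = 2))[, integer(0)]
  res <- applyExclusions(co)
  expect_true(all(tallyCounts(res$tally) == 0L))
})

test_that("tally conservation holds over random flag configurations", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(30:80, 1)
    co <- simulateCohort(simConfig(nCases = n, seed = i))
    cd <- SummarizedExperiment::colData(co)
    cd$primary_dx_ad <- runif(n) > 0.2
    cd$neuropath_normal <- runif(n) < 0.1
    cd$ad_gene_variant <- runif(n) < 0.1
    cd$hippocampal_sclerosis <- runif(n) < 0.1
    SummarizedExperiment::colData(co) <- cd
    res <- applyExclusions(co)
    tc <- tallyCounts(res$tally)
    expect_identical(tc[["n_input"]],
                     tc[["n_remaining"]] + tc[["n_excluded_total"]])
    expect_identical(ncol(res$cohort), tc[["n_remaining"]])
    ## survivors are exactly the cases matching no rule, in input order
    survivors <- cd$primary_dx_ad & !cd$neuropath_normal &
      !cd$ad_gene_variant & !cd$hippocampal_sclerosis
    expect_identical(SummarizedExperiment::colData(res$cohort)$case_id,
                     cd$case_id[survivors])
  }
})

test_that("subgroup selection takes the extremes and the centre", {
  co <- scoreCohort(simulateCohort(simConfig(nCases = 400, seed = 12)))
  sub <- selectSubgroup(co, nPerSubtype = 20)
  expect_equal(ncol(sub), 60L)
  cd <- SummarizedExperiment::colData(co)
  cop <- cd$copathology_exclusion
  eligible <- !is.na(cd$clix_score) & !cop
  cs <- SummarizedExperiment::colData(sub)
  expect_false(any(cs$copathology_exclusion))
  ## hippocampal-sparing members are the 20 lowest eligible HS scores
  hsScores <- sort(cd$clix_score[eligible &
                                   cd$subtype == "HIPPOCAMPAL_SPARING"])
  expect_equal(sort(cs$clix_score[cs$subtype == "HIPPOCAMPAL_SPARING"]),
               hsScores[1:20])
  lpScores <- sort(cd$clix_score[eligible &
                                   cd$subtype == "LIMBIC_PREDOMINANT"],
                   decreasing = TRUE)
  expect_equal(sort(cs$clix_score[cs$subtype == "LIMBIC_PREDOMINANT"],
                    decreasing = TRUE), lpScores[1:20])
  ## typical members hug the eligible-cohort median
  med <- S4Vectors::metadata(sub)$cohort_median_score
  expect_equal(med, median(cd$clix_score[eligible]))
  typDist <- sort(abs(cd$clix_score[eligible & cd$subtype == "TYPICAL"] -
                        med))
  expect_equal(sort(abs(cs$clix_score[cs$subtype == "TYPICAL"] - med)),
               typDist[1:20])
})

test_that("subgroup selection is deterministic and reports shortfalls", {
  co <- scoreCohort(simulateCohort(simConfig(nCases = 300, seed = 13)))
  s1 <- selectSubgroup(co, 15)
  s2 <- selectSubgroup(co, 15)
  expect_identical(SummarizedExperiment::colData(s1)$case_id,
                   SummarizedExperiment::colData(s2)$case_id)
  expect_error(selectSubgroup(co, 200),
               "insufficient eligible HIPPOCAMPAL_SPARING")
  expect_error(selectSubgroup(scoreCohort(simulateCohort(
    simConfig(nCases = 50, seed = 14)))[, 1:5] , 20), "insufficient")
})

test_that("unscored cohorts are refused", {
  co <- simulateCohort(simConfig(nCases = 30, seed = 15))
  expect_error(selectSubgroup(co, 5), "scored first")
})
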