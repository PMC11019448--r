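test_that("referencePercentile follows the mid-rank ECDF convention", {
  ref <- sort(rnorm(10, 50, 10))
  expect_equal(referencePercentile(min(ref) - 1, ref), 0)
  expect_equal(referencePercentile(max(ref) + 1, ref), 100)
  ## middle element of an odd all-distinct reference: 4 below + half of 1
  ref9 <- c(1, 2, 3, 4, 5, 6, 7, 8, 9) * 2
  expect_equal(referencePercentile(10, ref9), 100 * (4 + 0.5) / 9)
  expect_error(referencePercentile(1, numeric(0)), "non-empty")
})

test_that("referencePercentile matches the counting-loop oracle with ties", {
  set.seed(101)
  for (i in 1:50) {
    ref <- sort(sample(0:20, 25, replace = TRUE))    # heavy ties
    v <- sample(0:20, 1) + sample(c(0, 0.5), 1)
    expect_equal(referencePercentile(v, ref), oraclePercentile(v, ref),
                 tolerance = 1e-12)
  }
  ## monotone non-decreasing and tie-consistent
  ref <- sort(rpois(40, 8))
  vs <- seq(0, 20, by = 0.25)
  p <- referencePercentile(vs, ref)
  expect_true(all(diff(p) >= 0))
  expect_equal(referencePercentile(c(7, 7), ref),
               rep(referencePercentile(7, ref), 2))
})

test_that("tangleRatio implements the pseudocount-stabilised mean ratio", {
  expect_equal(tangleRatio(regionCounts(10, 10, 10, 10, 10)), 1.0)
  expect_equal(tangleRatio(regionCounts(10, 10, 0, 0, 0)), 10.5 / 0.5)
  set.seed(7)
  for (i in 1:20) {
    x <- regionCounts(runif(1, 0, 50), runif(1, 0, 50), runif(1, 0, 50),
                      runif(1, 0, 50), runif(1, 0, 50))
    expect_equal(tangleRatio(x, pseudocount = 0.25),
                 (mean(x[1:2]) + 0.25) / (mean(x[3:5]) + 0.25))
  }
})

test_that("a case at every mid-rank-50 point scores exactly 20", {
  regs <- lapply(1:5, function(i) as.numeric(10:30))
  names(regs) <- c("ca1", "subiculum", "sup_temporal", "inf_parietal",
                   "mid_frontal")
  ratios <- c(seq(0.5, 0.95, length.out = 10), 1,
              seq(1.05, 1.5, length.out = 10))
  ref <- new("ReferenceModel", regions = regs, ratios = ratios,
             nReference = 21L, provenance = "symmetric synthetic")
  res <- computeCLix(regionCounts(20, 20, 20, 20, 20), ref)
  expect_equal(clixScore(res), 20.0)
  expect_identical(clixSubtype(res), "TYPICAL")
})

test_that("the all-extreme construction attains the score ceiling of 40", {
  set.seed(17)
  ref <- randomPositiveReference(30)
  top <- max(unlist(referenceRegions(ref)))
  res <- computeCLix(regionCounts(top + 1, top + 1, 0, 0, 0), ref)
  expect_equal(clixScore(res), 40.0)
  expect_identical(clixSubtype(res), "LIMBIC_PREDOMINANT")
  ## and the opposite extreme scores 0
  res0 <- computeCLix(regionCounts(0, 0, top + 1, top + 1, top + 1), ref)
  expect_equal(clixScore(res0), 0.0)
})

test_that("computeCLix agrees with the independent composite oracle", {
  set.seed(23)
  ref <- buildReference(randomCountMatrix(60))
  for (i in 1:30) {
    x <- regionCounts(rpois(1, 25), rpois(1, 20), rpois(1, 12),
                      rpois(1, 10), rpois(1, 9))
    expect_equal(clixScore(computeCLix(x, ref)), oracleCLix(as.list(x), ref),
                 tolerance = 1e-9)
  }
})

test_that("subtype bins follow the half-open boundary rule", {
  expect_identical(classifySubtype(5.0), "HIPPOCAMPAL_SPARING")
  expect_identical(classifySubtype(9.999999), "HIPPOCAMPAL_SPARING")
  expect_identical(classifySubtype(10.0), "TYPICAL")
  expect_identical(classifySubtype(29.999999), "TYPICAL")
  expect_identical(classifySubtype(30.0), "LIMBIC_PREDOMINANT")
  expect_identical(classifySubtype(40.0), "LIMBIC_PREDOMINANT")
  expect_error(classifySubtype(-0.1), "\\[0, 40\\]")
  expect_error(classifySubtype(40.1), "\\[0, 40\\]")
})

test_that("scores stay in [0, 40] and agree with their subtype label", {
  set.seed(29)
  for (i in 1:25) {
    ref <- buildReference(randomCountMatrix(25))
    m <- randomCountMatrix(20)
    df <- computeCLix(m, ref)
    expect_true(all(df$clix_score >= 0 & df$clix_score <= 40))
    expect_identical(df$subtype, classifySubtype(df$clix_score))
  }
})

test_that("score is monotone in single-region perturbations", {
  set.seed(37)
  ref <- buildReference(randomCountMatrix(40))
  for (i in 1:20) {
    x <- as.numeric(randomCountMatrix(1))
    names(x) <- names(referenceRegions(ref))
    base <- clixScore(computeCLix(x, ref))
    for (r in c("ca1", "subiculum")) {
      up <- x; up[r] <- up[r] + sample(1:10, 1)
      expect_gte(clixScore(computeCLix(up, ref)), base)
    }
    for (r in c("sup_temporal", "inf_parietal", "mid_frontal")) {
      up <- x; up[r] <- up[r] + sample(1:10, 1)
      expect_lte(clixScore(computeCLix(up, ref)), base)
    }
  }
})

test_that("missing regions are rejected unless partial scoring is opted in", {
  set.seed(43)
  ref <- buildReference(randomCountMatrix(30))
  x <- c(ca1 = 20, subiculum = NA, sup_temporal = 10, inf_parietal = 9,
         mid_frontal = 11)
  expect_error(computeCLix(x, ref), "missing")
  res <- computeCLix(x, ref, allowPartial = TRUE)
  ## with subiculum absent the hippocampal side is CA1 alone
  expect_equal(res@hippocampalPct,
               referencePercentile(20, referenceRegions(ref)$ca1))
  allNA <- c(ca1 = NA, subiculum = NA, sup_temporal = 10, inf_parietal = 9,
             mid_frontal = 11)
  expect_error(computeCLix(allNA, ref, allowPartial = TRUE),
               "at least one region per compartment")
})

test_that("custom composite weights shift the score as documented", {
  set.seed(47)
  ref <- buildReference(randomCountMatrix(30))
  x <- regionCounts(30, 28, 5, 6, 4)
  ## all weight on the (reversed) cortical percentile
  res <- computeCLix(x, ref, weights = c(ratio = 0, hippocampal = 0,
                                         cortical = 1))
  expect_equal(clixScore(res), 0.4 * (100 - res@corticalPct))
})

test_that("scoreCohort stores per-case results and the reference used", {
  set.seed(53)
  co <- simulateCohort(simConfig(nCases = 120, seed = 5))
  sc <- scoreCohort(co)
  cd <- SummarizedExperiment::colData(sc)
  expect_true(all(c("clix_score", "subtype", "hippocampal_pct",
                    "cortical_pct", "ratio_pct") %in% colnames(cd)))
  expect_true(all(cd$clix_score >= 0 & cd$clix_score <= 40))
  expect_identical(cd$subtype, classifySubtype(cd$clix_score))
  expect_s4_class(S4Vectors::metadata(sc)$reference, "ReferenceModel")
  ## scoring against the stored reference reproduces the column
  ref <- S4Vectors::metadata(sc)$reference
  m <- SummarizedExperiment::assay(sc, "tangles")
  expect_equal(computeCLix(m, ref)$clix_score, unname(cd$clix_score))
})
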