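#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<-
NULL

## Canonical region order used everywhere: hippocampal compartment first.
CLIX_REGIONS <- c("ca1", "subiculum", "sup_temporal", "inf_parietal",
                  "mid_frontal")
HIPP_REGIONS <- c("ca1", "subiculum")
CORT_REGIONS <- c("sup_temporal", "inf_parietal", "mid_frontal")

CLIX_SUBTYPES <- c("HIPPOCAMPAL_SPARING", "TYPICAL", "LIMBIC_PREDOMINANT")

#' ReferenceModel: reference tangle-count distributions for percentile scoring
#'
#' Holds, for each of the five corticolimbic regions (CA1, subiculum,
#' superior temporal, inferior parietal, middle frontal), the sorted tangle
#' counts of a reference case series, together with the sorted
#' hippocampal:cortical count ratios of the same cases. Percentiles of a new
#' case are mid-rank ECDF positions within these lists; the corticolimbic
#' index is computed from those percentiles.
#'
#' @slot regions named list of five sorted numeric vectors (one per region),
#'   all of length \code{nReference}, values finite and non-negative.
#' @slot ratios sorted numeric vector of per-case hippocampal:cortical
#'   ratios, positive, length \code{nReference}.
#' @slot nReference number of reference cases (at least 20).
#' @slot provenance free-text label describing where the reference came from.
#' @seealso [buildReference()], [referencePercentile()], [computeCLix()]
#' @export
setClass("ReferenceModel",
  slots = c(regions = "list", ratios = "numeric", nReference = "integer",
            provenance = "character"))

setValidity("ReferenceModel", function(object) {
  msgs <- character()
  if (!identical(names(object@regions), CLIX_REGIONS))
    msgs <- c(msgs, sprintf("regions must be a named list in the order: %s",
                            paste(CLIX_REGIONS, collapse = ", ")))
  n <- object@nReference
  if (length(n) != 1L || is.na(n) || n < 20L)
    msgs <- c(msgs, "nReference must be a single integer >= 20")
  for (r in names(object@regions)) {
    v <- object@regions[[r]]
    if (!is.numeric(v) || length(v) != n)
      msgs <- c(msgs, sprintf("region '%s' must be numeric of length nReference", r))
    else {
      if (any(!is.finite(v)) || any(v < 0))
        msgs <- c(msgs, sprintf("region '%s' has non-finite or negative counts", r))
      if (is.unsorted(v))
        msgs <- c(msgs, sprintf("region '%s' must be sorted ascending", r))
    }
  }
  if (length(object@ratios) != n)
    msgs <- c(msgs, "ratios must have length nReference")
  else {
    if (any(!is.finite(object@ratios)) || any(object@ratios <= 0))
      msgs <- c(msgs, "ratios must be finite and positive")
    if (is.unsorted(object@ratios))
      msgs <- c(msgs, "ratios must be sorted ascending")
  }
  if (length(msgs)) msgs else TRUE
})

#' CLixResult: corticolimbic index for a single case
#'
#' @slot score CLix score in [0, 40]; low values indicate relative cortical
#'   predominance (hippocampal sparing), high values relative cortical
#'   sparing (limbic predominance).
#' @slot hippocampalPct mean reference percentile of the CA1 and subiculum
#'   tangle counts, in [0, 100].
#' @slot corticalPct mean reference percentile of the three association
#'   cortex counts, in [0, 100].
#' @slot ratio pseudocount-stabilised hippocampal:cortical mean count ratio.
#' @slot ratioPct reference percentile of that ratio, in [0, 100].
#' @slot subtype one of HIPPOCAMPAL_SPARING, TYPICAL, LIMBIC_PREDOMINANT.
#' @export
setClass("CLixResult",
  slots = c(score = "numeric", hippocampalPct = "numeric",
            corticalPct = "numeric", ratio = "numeric", ratioPct = "numeric",
            subtype = "character"))

setValidity("CLixResult", function(object) {
  msgs <- character()
  chk1 <- function(x, lo, hi, what) {
    if (length(x) != 1L || !is.finite(x) || x < lo || x > hi)
      sprintf("%s must be a single value in [%g, %g]", what, lo, hi)
    else character()
  }
  msgs <- c(msgs,
            chk1(object@score, 0, 40, "score"),
            chk1(object@hippocampalPct, 0, 100, "hippocampalPct"),
            chk1(object@corticalPct, 0, 100, "corticalPct"),
            chk1(object@ratioPct, 0, 100, "ratioPct"))
  if (length(object@ratio) != 1L || !is.finite(object@ratio) ||
      object@ratio <= 0)
    msgs <- c(msgs, "ratio must be a single positive value")
  if (!(object@subtype %in% CLIX_SUBTYPES))
    msgs <- c(msgs, "unknown subtype label")
  else if (is.finite(object@score) && object@score >= 0 &&
           object@score <= 40 &&
           !identical(object@subtype, classifySubtype(object@score)))
    msgs <- c(msgs, "subtype inconsistent with score under the binning rule")
  if (length(msgs)) msgs else TRUE
})

#' CLixCohort: a case series of regional tangle counts plus covariates
#'
#' A \linkS4class{SummarizedExperiment} whose single assay, \code{"tangles"},
#' is a 5 x n matrix of per-region tangle counts (rows in the canonical
#' region order, columns are cases) and whose \code{colData} carries the
#' clinicopathologic covariates (age at onset, sex, APOE e4, Braak stage,
#' MMSE series, exclusion flags, ...). Missing counts are \code{NA}.
#'
#' @export
setClass("CLixCohort", contains = "SummarizedExperiment")

setValidity("CLixCohort", function(object) {
  msgs <- character()
  if (!"tangles" %in% SummarizedExperiment::assayNames(object))
    return("assay 'tangles' is required")
  m <- SummarizedExperiment::assay(object, "tangles")
  if (!identical(rownames(m), CLIX_REGIONS))
    msgs <- c(msgs, sprintf("assay rows must be exactly: %s",
                            paste(CLIX_REGIONS, collapse = ", ")))
  if (any(m[is.finite(m)] < 0))
    msgs <- c(msgs, "tangle counts must be non-negative")
  if (any(is.nan(m) | is.infinite(m)))
    msgs <- c(msgs, "tangle counts must be finite or NA")
  if (!"case_id" %in% colnames(colData(object)))
    msgs <- c(msgs, "colData must contain a 'case_id' column")
  else if (anyDuplicated(colData(object)$case_id))
    msgs <- c(msgs, "case_id values must be unique")
  if (length(msgs)) msgs else TRUE
})

#' ExclusionTally: bookkeeping for the cohort exclusion cascade
#'
#' Counts of cases removed by each rule of the neuropathology exclusion
#' cascade, applied in order with each case attributed to the first rule it
#' matches: (1) primary neuropathologic diagnosis not AD, (2)
#' neuropathologically normal, (3) thioflavin-S tangle counts absent, (4)
#' known AD gene variant, (5) hippocampal sclerosis.
#'
#' @slot nInput,nNotAD,nNormal,nNoCounts,nGeneVariant,nHippSclerosis
#'   per-rule counts.
#' @slot nExcluded total excluded; always the sum of the five rule counts.
#' @slot nRemaining cases surviving the cascade; \code{nInput - nExcluded}.
#' @export
setClass("ExclusionTally",
  slots = c(nInput = "integer", nNotAD = "integer", nNormal = "integer",
            nNoCounts = "integer", nGeneVariant = "integer",
            nHippSclerosis = "integer", nExcluded = "integer",
            nRemaining = "integer"))

setValidity("ExclusionTally", function(object) {
  cnts <- c(object@nNotAD, object@nNormal, object@nNoCounts,
            object@nGeneVariant, object@nHippSclerosis)
  if (any(c(object@nInput, cnts, object@nExcluded, object@nRemaining) < 0))
    return("all tallies must be non-negative")
  if (object@nExcluded != sum(cnts))
    return("nExcluded must equal the sum of the per-rule counts")
  if (object@nRemaining != object@nInput - object@nExcluded)
    return("nRemaining must equal nInput - nExcluded")
  TRUE
})

#' StatResult: a single hypothesis-test or correlation result
#'
#' @slot statisticName e.g. "spearman", "kruskal_wallis".
#' @slot estimate the point estimate (rho, H, W, odds ratio, ...); may be NA
#'   where the test has no natural estimate (Fisher on tables wider than 2x2).
#' @slot pValue two-sided p value in [0, 1].
#' @slot n number of observations used.
#' @slot groups optional group labels.
#' @slot details list of method notes (e.g. exact vs approximate).
#' @export
setClass("StatResult",
  slots = c(statisticName = "character", estimate = "numeric",
            pValue = "numeric", n = "integer", groups = "character",
            details = "list"))

setValidity("StatResult", function(object) {
  msgs <- character()
  p <- object@pValue
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    msgs <- c(msgs, "pValue must be a single value in [0, 1]")
  if (grepl("spearman", object@statisticName) && object@n < 3L)
    msgs <- c(msgs, "correlations require n >= 3")
  if (length(msgs)) msgs else TRUE
})

#' ImportanceReport: random-forest permutation variable importance
#'
#' Per-variable percent increase in out-of-bag mean squared error (%IncMSE)
#' when that variable's values are permuted, relative to the unpermuted
#' out-of-bag MSE, with variables ranked in descending importance.
#'
#' @slot importance data.frame with columns \code{variable},
#'   \code{pct_inc_mse} (may be slightly negative for irrelevant variables)
#'   and \code{rank} (a permutation of 1..k).
#' @slot modelMeta list: nTrees, oobMSE, seed, nPermutations, nCases,
#'   nDropped (listwise-deleted incomplete cases).
#' @export
setClass("ImportanceReport",
  slots = c(importance = "data.frame", modelMeta = "list"))

setValidity("ImportanceReport", function(object) {
  imp <- object@importance
  need <- c("variable", "pct_inc_mse", "rank")
  if (!all(need %in% colnames(imp)))
    return("importance must have columns variable, pct_inc_mse, rank")
  if (!setequal(imp$rank, seq_len(nrow(imp))))
    return("ranks must be a permutation of 1..k")
  TRUE
})

#' SimConfig: configuration of the synthetic cohort generator
#'
#' The generator draws a latent corticolimbic trait lambda in (0, 1) per case
#' (lambda near 1 = limbic predominant), negative-binomial regional tangle
#' counts whose means are log-linear in lambda (hippocampal increasing,
#' cortical decreasing), and covariates coupled to lambda by a Gaussian
#' copula at configured Spearman strengths or by logistic probability curves.
#'
#' @slot nCases number of cases to simulate.
#' @slot seed RNG seed.
#' @slot latentShape Beta(a, b) shape of the latent trait.
#' @slot regionCurves data.frame with columns region, baseMean, slope: the
#'   region mean at lambda = 0.5 and the log-linear slope in lambda.
#' @slot dispersion negative-binomial size parameter (shared by all regions).
#' @slot effects named list of covariate effect settings; see
#'   \code{\link{simConfig}}.
#' @slot exclusionCounts length-5 integer vector of per-rule exclusion flags
#'   to plant (zero-length for none).
#' @export
setClass("SimConfig",
  slots = c(nCases = "integer", seed = "integer", latentShape = "numeric",
            regionCurves = "data.frame", dispersion = "numeric",
            effects = "list", exclusionCounts = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (object@nCases < 1L) msgs <- c(msgs, "nCases must be positive")
  if (length(object@latentShape) != 2L || any(object@latentShape <= 0))
    msgs <- c(msgs, "latentShape must be two positive Beta parameters")
  if (!identical(object@regionCurves$region, CLIX_REGIONS))
    msgs <- c(msgs, "regionCurves must cover the five regions in order")
  if (any(object@regionCurves$baseMean <= 0))
    msgs <- c(msgs, "baseMean must be positive")
  if (length(object@dispersion) != 1L || object@dispersion <= 0)
    msgs <- c(msgs, "dispersion must be a single positive value")
  probs <- unlist(lapply(object@effects[c("sex_male", "apoe_e4", "trem2_r47h",
                                          "atypical", "tdp43")],
                         function(e) e$base))
  if (any(probs < 0 | probs > 1))
    msgs <- c(msgs, "base probabilities must lie in [0, 1]")
  if (length(object@exclusionCounts) &&
      (length(object@exclusionCounts) != 5L || any(object@exclusionCounts < 0)))
    msgs <- c(msgs, "exclusionCounts must be five non-negative integers")
  if (length(msgs)) msgs else TRUE
})
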