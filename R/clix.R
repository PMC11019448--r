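#' Construct and validate a set of regional tangle counts
#'
#' A convenience constructor for one case's five regional counts in the
#' canonical order. Counts are tangles per standardized microscopic field;
#' all five must be present, finite and non-negative.
#'
#' @param ca1,subiculum,sup_temporal,inf_parietal,mid_frontal non-negative
#'   tangle counts.
#' @return named numeric vector of length 5.
#' @examples
#' regionCounts(ca1 = 30, subiculum = 22, sup_temporal = 4,
#'              inf_parietal = 6, mid_frontal = 3)
#' @export
regionCounts <- function(ca1, subiculum, sup_temporal, inf_parietal,
                         mid_frontal) {
  x <- c(ca1 = ca1, subiculum = subiculum, sup_temporal = sup_temporal,
         inf_parietal = inf_parietal, mid_frontal = mid_frontal)
  .checkRegionCounts(x)
  x
}

.checkRegionCounts <- function(x, allowPartial = FALSE) {
  if (!is.numeric(x) || length(x) != 5L)
    stop("region counts must be five numeric values")
  if (is.null(names(x))) names(x) <- CLIX_REGIONS
  if (!identical(names(x), CLIX_REGIONS))
    x <- x[CLIX_REGIONS]
  if (anyNA(x) && !allowPartial)
    stop("missing region counts (set allowPartial = TRUE to score from ",
         "the available regions of each compartment)")
  ok <- !is.na(x)
  if (any(!is.finite(x[ok])) || any(x[ok] < 0))
    stop("region counts must be finite and >= 0")
  if (allowPartial &&
      (all(is.na(x[HIPP_REGIONS])) || all(is.na(x[CORT_REGIONS]))))
    stop("at least one region per compartment is required")
  x
}

#' Hippocampal:cortical tangle count ratio
#'
#' The ratio of the mean hippocampal count (CA1, subiculum) to the mean
#' cortical count (superior temporal, inferior parietal, middle frontal),
#' with a pseudocount added to both terms so the ratio stays finite and
#' positive when a compartment is tangle-free (as happens in extreme
#' limbic-predominant cortex).
#'
#' @param counts named numeric vector of five regional counts (see
#'   [regionCounts()]), or a 5 x n matrix.
#' @param pseudocount added to numerator and denominator means; default 0.5.
#' @param allowPartial if TRUE, compartment means use the available
#'   (non-missing) regions; at least one region per compartment is required.
#' @return positive numeric ratio(s).
#' @export
tangleRatio <- function(counts, pseudocount = 0.5, allowPartial = FALSE) {
  if (is.matrix(counts)) {
    stopifnot(identical(rownames(counts), CLIX_REGIONS))
    return(.tangleRatioVec(counts, pseudocount))
  }
  counts <- .checkRegionCounts(counts, allowPartial)
  hipp <- mean(counts[HIPP_REGIONS], na.rm = allowPartial)
  cort <- mean(counts[CORT_REGIONS], na.rm = allowPartial)
  (hipp + pseudocount) / (cort + pseudocount)
}

.tangleRatioVec <- function(m, pseudocount) {
  hipp <- colMeans(m[HIPP_REGIONS, , drop = FALSE])
  cort <- colMeans(m[CORT_REGIONS, , drop = FALSE])
  (hipp + pseudocount) / (cort + pseudocount)
}

#' Bin a CLix score into the three AD neuropathologic subtypes
#'
#' Scores below 10 indicate relative cortical predominance (hippocampal
#' sparing AD), scores of 30 or greater relative cortical sparing (limbic
#' predominant AD), and scores from 10 up to (but not including) 30 typical
#' AD. The boundary at 30 belongs to the limbic predominant bin.
#'
#' @param score numeric vector of CLix scores in [0, 40].
#' @return character vector of subtype labels.
#' @examples
#' classifySubtype(c(5, 10, 20, 30, 40))
#' @export
classifySubtype <- function(score) {
  if (any(!is.finite(score) | score < 0 | score > 40))
    stop("CLix scores must lie in [0, 40]")
  ifelse(score < 10, "HIPPOCAMPAL_SPARING",
         ifelse(score < 30, "TYPICAL", "LIMBIC_PREDOMINANT"))
}

## vectorized scoring core: m is 5 x n counts, ref a ReferenceModel.
## Returns a data.frame of component percentiles, ratio, score, subtype.
.clixScores <- function(m, ref, pseudocount = 0.5,
                        weights = c(ratio = 1, hippocampal = 1,
                                    cortical = 1)) {
  stopifnot(is(ref, "ReferenceModel"))
  weights <- weights / sum(weights)
  pct <- vapply(CLIX_REGIONS, function(r)
    referencePercentile(m[r, ], ref@regions[[r]]), numeric(ncol(m)))
  if (ncol(m) == 1L) pct <- matrix(pct, nrow = 1L,
                                   dimnames = list(NULL, CLIX_REGIONS))
  hippPct <- rowMeans(pct[, HIPP_REGIONS, drop = FALSE])
  cortPct <- rowMeans(pct[, CORT_REGIONS, drop = FALSE])
  ratio <- .tangleRatioVec(m, pseudocount)
  ratioPct <- referencePercentile(ratio, ref@ratios)
  q <- weights["ratio"] * ratioPct + weights["hippocampal"] * hippPct +
    weights["cortical"] * (100 - cortPct)
  score <- 0.4 * q
  data.frame(hippocampal_pct = hippPct, cortical_pct = cortPct,
             ratio = ratio, ratio_pct = ratioPct, clix_score = score,
             subtype = classifySubtype(score))
}

#' Compute the corticolimbic index (CLix) for one case
#'
#' Each regional count is converted to a mid-rank ECDF percentile within the
#' reference distribution; the hippocampal percentile is the mean over CA1
#' and subiculum, the cortical percentile the mean over the three
#' association cortices, and the case's hippocampal:cortical ratio is itself
#' converted to a percentile within the reference ratios. The composite
#'
#' \deqn{Q = w_r \cdot P_{ratio} + w_h \cdot P_{hipp} + w_c \cdot (100 - P_{cort})}
#'
#' (equal weights summing to 1 by default) is rescaled to \code{score = 0.4 Q},
#' so the score runs from 0 (extreme cortical predominance / hippocampal
#' sparing) to 40 (extreme cortical sparing / limbic predominance). The score
#' is non-decreasing in every hippocampal count and non-increasing in every
#' cortical count.
#'
#' @param counts named numeric vector of five regional counts, or a 5 x n
#'   matrix with region rownames for several cases.
#' @param reference a \linkS4class{ReferenceModel}.
#' @param pseudocount ratio stabiliser, as in [tangleRatio()]; use the same
#'   value the reference was built with.
#' @param weights positive weights for the ratio, hippocampal and
#'   (reversed) cortical percentile components; normalised to sum to 1.
#' @param allowPartial score cases with a missing region from the available
#'   regions of each compartment (at least one per compartment); default
#'   FALSE, which rejects missing counts.
#' @return a \linkS4class{CLixResult} for a single case; for matrix input, a
#'   data.frame with one row per case.
#' @examples
#' set.seed(1)
#' m <- matrix(rpois(5 * 50, c(25, 20, 12, 10, 9)), nrow = 5,
#'             dimnames = list(c("ca1", "subiculum", "sup_temporal",
#'                               "inf_parietal", "mid_frontal"), NULL))
#' ref <- buildReference(m)
#' computeCLix(regionCounts(40, 35, 2, 1, 0), ref)
#' @export
computeCLix <- function(counts, reference, pseudocount = 0.5,
                        weights = c(ratio = 1, hippocampal = 1, cortical = 1),
                        allowPartial = FALSE) {
  if (is.matrix(counts)) {
    m <- .asCountMatrix(counts)
    bad <- colSums(is.na(m)) > 0L
    if (any(bad) && !allowPartial)
      stop("missing region counts in ", sum(bad), " case(s)")
    return(.clixScoresPartial(m, reference, pseudocount, weights,
                              allowPartial))
  }
  counts <- .checkRegionCounts(counts, allowPartial)
  df <- .clixScoresPartial(matrix(counts, ncol = 1,
                                  dimnames = list(CLIX_REGIONS, NULL)),
                           reference, pseudocount, weights, allowPartial)
  new("CLixResult", score = df$clix_score, hippocampalPct = df$hippocampal_pct,
      corticalPct = df$cortical_pct, ratio = df$ratio,
      ratioPct = df$ratio_pct, subtype = df$subtype)
}

## partial-aware wrapper around .clixScores: compartment means over the
## available regions when allowPartial (missingness is otherwise rejected
## upstream).
.clixScoresPartial <- function(m, ref, pseudocount, weights, allowPartial) {
  if (!anyNA(m)) return(.clixScores(m, ref, pseudocount, weights))
  if (!allowPartial) stop("missing region counts")
  weights <- weights / sum(weights)
  n <- ncol(m)
  pct <- matrix(NA_real_, n, 5, dimnames = list(NULL, CLIX_REGIONS))
  for (r in CLIX_REGIONS) {
    ok <- !is.na(m[r, ])
    pct[ok, r] <- referencePercentile(m[r, ok], ref@regions[[r]])
  }
  hippPct <- rowMeans(pct[, HIPP_REGIONS, drop = FALSE], na.rm = TRUE)
  cortPct <- rowMeans(pct[, CORT_REGIONS, drop = FALSE], na.rm = TRUE)
  if (any(is.nan(hippPct)) || any(is.nan(cortPct)))
    stop("at least one region per compartment is required")
  hipp <- colMeans(m[HIPP_REGIONS, , drop = FALSE], na.rm = TRUE)
  cort <- colMeans(m[CORT_REGIONS, , drop = FALSE], na.rm = TRUE)
  ratio <- (hipp + pseudocount) / (cort + pseudocount)
  ratioPct <- referencePercentile(ratio, ref@ratios)
  q <- weights["ratio"] * ratioPct + weights["hippocampal"] * hippPct +
    weights["cortical"] * (100 - cortPct)
  score <- 0.4 * q
  data.frame(hippocampal_pct = hippPct, cortical_pct = cortPct,
             ratio = ratio, ratio_pct = ratioPct, clix_score = score,
             subtype = classifySubtype(score))
}

setMethod("show", "CLixResult", function(object) {
  cat(sprintf("CLix %.1f (%s)\n", object@score, object@subtype))
  cat(sprintf("  hippocampal pct %.1f | cortical pct %.1f | ratio %.3g (pct %.1f)\n",
              object@hippocampalPct, object@corticalPct, object@ratio,
              object@ratioPct))
})

#' @describeIn CLixResult-class the numeric CLix score
#' @param x a \code{CLixResult}
#' @export
setGeneric("clixScore", function(x) standardGeneric("clixScore"))

#' @rdname CLixResult-class
#' @export
setMethod("clixScore", "CLixResult", function(x) x@score)

#' @describeIn CLixResult-class the subtype label
#' @export
setGeneric("clixSubtype", function(x) standardGeneric("clixSubtype"))

#' @rdname CLixResult-class
#' @export
setMethod("clixSubtype", "CLixResult", function(x) x@subtype)

#' Score every case of a cohort and record the results in colData
#'
#' Builds (or accepts) a reference model and computes per-case CLix scores,
#' component percentiles and subtype labels, storing them as colData columns
#' \code{hippocampal_pct}, \code{cortical_pct}, \code{ratio},
#' \code{ratio_pct}, \code{clix_score} and \code{subtype}. Cases with
#' missing counts receive NA (unless \code{allowPartial}).
#'
#' @param cohort a \linkS4class{CLixCohort}.
#' @param reference a \linkS4class{ReferenceModel}; if NULL, one is built
#'   from the cohort's complete cases.
#' @inheritParams computeCLix
#' @return the cohort with scoring columns added; the reference used is
#'   stored in \code{metadata(cohort)$reference}.
#' @export
scoreCohort <- function(cohort, reference = NULL, pseudocount = 0.5,
                        weights = c(ratio = 1, hippocampal = 1, cortical = 1),
                        allowPartial = FALSE) {
  stopifnot(is(cohort, "CLixCohort"))
  m <- SummarizedExperiment::assay(cohort, "tangles")
  if (is.null(reference))
    reference <- buildReference(m, pseudocount = pseudocount)
  scorable <- if (allowPartial) {
    !(colSums(is.na(m[HIPP_REGIONS, , drop = FALSE])) == 2L |
        colSums(is.na(m[CORT_REGIONS, , drop = FALSE])) == 3L)
  } else colSums(is.na(m)) == 0L
  out <- data.frame(hippocampal_pct = rep(NA_real_, ncol(m)),
                    cortical_pct = NA_real_, ratio = NA_real_,
                    ratio_pct = NA_real_, clix_score = NA_real_,
                    subtype = NA_character_)
  if (any(scorable))
    out[scorable, ] <- .clixScoresPartial(m[, scorable, drop = FALSE],
                                          reference, pseudocount, weights,
                                          allowPartial)
  for (cl in colnames(out)) colData(cohort)[[cl]] <- out[[cl]]
  metadata(cohort)$reference <- reference
  cohort
}
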