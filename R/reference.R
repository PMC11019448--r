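#' Build a reference percentile model from a cohort of tangle counts
#'
#' Collects the per-region tangle counts of all complete cases into sorted
#' reference distributions, and computes each reference case's
#' hippocampal:cortical mean-count ratio (with the same pseudocount later
#' used for scoring). Percentiles of new cases are evaluated against these
#' lists by mid-rank ECDF, so the model is invariant to the input case order.
#'
#' @param x a \linkS4class{CLixCohort}, or a numeric matrix/data.frame with
#'   the five regions as columns (or rows, for a 5 x n matrix with region
#'   rownames) in the canonical order \code{ca1, subiculum, sup_temporal,
#'   inf_parietal, mid_frontal}.
#' @param pseudocount added to both ratio terms so the ratio stays finite
#'   when a compartment has zero counts; default 0.5.
#' @param provenance free-text label stored with the model.
#' @return a \linkS4class{ReferenceModel}.
#' @examples
#' set.seed(1)
#' m <- matrix(rpois(5 * 30, 10), nrow = 5, dimnames = list(
#'   c("ca1", "subiculum", "sup_temporal", "inf_parietal", "mid_frontal"),
#'   NULL))
#' ref <- buildReference(m)
#' referenceSize(ref)
#' @export
buildReference <- function(x, pseudocount = 0.5,
                           provenance = "cohort-derived") {
  m <- .asCountMatrix(x)
  if (any(is.nan(m)) || any(is.infinite(m)))
    stop("invalid reference counts: all values must be finite and >= 0")
  complete <- colSums(is.na(m)) == 0L
  m <- m[, complete, drop = FALSE]
  n <- ncol(m)
  if (n < 20L)
    stop("reference too small: need at least 20 complete cases, got ", n)
  if (any(!is.finite(m)) || any(m < 0))
    stop("invalid reference counts: all values must be finite and >= 0")
  regions <- lapply(seq_len(nrow(m)), function(i) sort(m[i, ]))
  names(regions) <- CLIX_REGIONS
  ratios <- sort(.tangleRatioVec(m, pseudocount))
  new("ReferenceModel", regions = regions, ratios = ratios,
      nReference = as.integer(n), provenance = provenance)
}

## coerce cohort / matrix / data.frame to a 5 x n region-by-case matrix
.asCountMatrix <- function(x) {
  if (is(x, "CLixCohort"))
    return(SummarizedExperiment::assay(x, "tangles"))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop("counts must be numeric")
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  if (nrow(x) == 5L && identical(rownames(x), CLIX_REGIONS)) return(x)
  if (ncol(x) == 5L) {
    if (!is.null(colnames(x))) {
      if (!all(CLIX_REGIONS %in% colnames(x)))
        stop("count table must have columns: ",
             paste(CLIX_REGIONS, collapse = ", "))
      x <- x[, CLIX_REGIONS, drop = FALSE]
    }
    return(t(x))
  }
  stop("cannot interpret counts: expected 5 regions per case")
}

#' Mid-rank ECDF percentile of values within a reference distribution
#'
#' The percentile of \code{value} is \code{100 * (n_below + 0.5 * n_equal) /
#' n}: strictly smaller reference values count fully, ties count half. The
#' result is monotone non-decreasing in \code{value}; tied inputs receive
#' identical percentiles; values below the whole reference get 0 and above
#' it 100.
#'
#' @param value numeric vector of non-negative values to score.
#' @param reference sorted numeric reference vector (non-empty).
#' @return numeric vector of percentiles in [0, 100].
#' @export
referencePercentile <- function(value, reference) {
  if (length(reference) == 0L) stop("reference values must be non-empty")
  if (is.unsorted(reference)) stop("reference values must be sorted")
  nle <- findInterval(value, reference)
  nlt <- findInterval(value, reference, left.open = TRUE)
  100 * (nlt + 0.5 * (nle - nlt)) / length(reference)
}

#' @describeIn ReferenceModel-class number of reference cases
#' @param object,x a \code{ReferenceModel}
#' @export
setGeneric("referenceSize", function(x) standardGeneric("referenceSize"))

#' @rdname ReferenceModel-class
#' @export
setMethod("referenceSize", "ReferenceModel", function(x) x@nReference)

#' @describeIn ReferenceModel-class named list of sorted per-region counts
#' @export
setGeneric("referenceRegions", function(x) standardGeneric("referenceRegions"))

#' @rdname ReferenceModel-class
#' @export
setMethod("referenceRegions", "ReferenceModel", function(x) x@regions)

#' @describeIn ReferenceModel-class sorted reference ratio values
#' @export
setGeneric("referenceRatios", function(x) standardGeneric("referenceRatios"))

#' @rdname ReferenceModel-class
#' @export
setMethod("referenceRatios", "ReferenceModel", function(x) x@ratios)

setMethod("show", "ReferenceModel", function(object) {
  cat("ReferenceModel with", object@nReference, "reference cases\n")
  cat("  provenance:", object@provenance, "\n")
  rng <- vapply(object@regions, function(v) range(v), numeric(2))
  for (r in CLIX_REGIONS)
    cat(sprintf("  %-13s counts in [%g, %g]\n", r, rng[1, r], rng[2, r]))
  cat(sprintf("  ratio         in [%.3g, %.3g]\n",
              min(object@ratios), max(object@ratios)))
})

#' Write / read a reference model as JSON
#'
#' The file holds one sorted array per region plus \code{ratio_values},
#' \code{n_reference} and \code{provenance}; reading the file back yields an
#' identical model, so a fixed reference can be shared across cohorts to
#' keep scores comparable.
#'
#' @param ref a \linkS4class{ReferenceModel}.
#' @param path file path.
#' @return \code{readReference} returns a \linkS4class{ReferenceModel};
#'   \code{writeReference} returns \code{path} invisibly.
#' @export
writeReference <- function(ref, path) {
  stopifnot(is(ref, "ReferenceModel"))
  obj <- c(ref@regions,
           list(ratio_values = ref@ratios,
                n_reference = ref@nReference,
                provenance = ref@provenance))
  ## I(17) significant digits: doubles survive the round trip bit-exactly,
  ## so percentile tie handling is stable across save/load
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeReference
#' @export
readReference <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c(CLIX_REGIONS, "ratio_values", "n_reference", "provenance")
  if (!all(need %in% names(obj)))
    stop("reference file is missing keys: ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  new("ReferenceModel",
      regions = lapply(stats::setNames(CLIX_REGIONS, CLIX_REGIONS),
                       function(r) as.numeric(obj[[r]])),
      ratios = as.numeric(obj$ratio_values),
      nReference = as.integer(obj$n_reference),
      provenance = as.character(obj$provenance))
}
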