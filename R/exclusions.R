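EXCLUSION_RULES <- c("not_ad", "normal", "no_counts", "gene_variant",
                     "hipp_sclerosis")

#' Apply the neuropathology exclusion cascade to a cohort
#'
#' Cases are removed, in order, when they (1) do not have AD as the primary
#' neuropathologic diagnosis, (2) are neuropathologically normal, (3) lack
#' thioflavin-S tangle counts, (4) carry a known AD gene variant, or (5)
#' have hippocampal sclerosis. A case matching several rules is attributed
#' to the first; survivors keep their input order. The surviving set is
#' independent of the rule order — only the per-rule attribution depends on
#' it.
#'
#' @param cohort a \linkS4class{CLixCohort} whose colData carries the flag
#'   columns \code{primary_dx_ad}, \code{neuropath_normal},
#'   \code{ad_gene_variant} and \code{hippocampal_sclerosis} (missing flag
#'   columns are treated as all-FALSE, except \code{primary_dx_ad} which
#'   defaults to TRUE).
#' @return a list with elements \code{cohort} (the filtered cohort),
#'   \code{tally} (an \linkS4class{ExclusionTally}) and \code{reasons} (a
#'   DataFrame of case_id and attributed rule, NA for survivors).
#' @export
applyExclusions <- function(cohort) {
  stopifnot(is(cohort, "CLixCohort"))
  cd <- colData(cohort)
  n <- ncol(cohort)
  flag <- function(name, default) {
    v <- if (name %in% colnames(cd)) cd[[name]] else rep(default, n)
    v[is.na(v)] <- default
    v
  }
  noCounts <- colSums(is.na(SummarizedExperiment::assay(cohort, "tangles"))) > 0L
  rules <- list(
    not_ad = !flag("primary_dx_ad", TRUE),
    normal = flag("neuropath_normal", FALSE),
    no_counts = noCounts,
    gene_variant = flag("ad_gene_variant", FALSE),
    hipp_sclerosis = flag("hippocampal_sclerosis", FALSE))
  reason <- rep(NA_character_, n)
  for (r in EXCLUSION_RULES)
    reason[is.na(reason) & rules[[r]]] <- r
  perRule <- vapply(EXCLUSION_RULES,
                    function(r) sum(reason == r, na.rm = TRUE), integer(1))
  tally <- new("ExclusionTally",
               nInput = as.integer(n),
               nNotAD = perRule[["not_ad"]],
               nNormal = perRule[["normal"]],
               nNoCounts = perRule[["no_counts"]],
               nGeneVariant = perRule[["gene_variant"]],
               nHippSclerosis = perRule[["hipp_sclerosis"]],
               nExcluded = as.integer(sum(perRule)),
               nRemaining = as.integer(n - sum(perRule)))
  list(cohort = cohort[, is.na(reason)], tally = tally,
       reasons = S4Vectors::DataFrame(case_id = cd$case_id, reason = reason))
}

setMethod("show", "ExclusionTally", function(object) {
  cat("Exclusion cascade:", object@nInput, "cases in\n")
  cat("  not primary-dx AD:      ", object@nNotAD, "\n")
  cat("  neuropathologically normal:", object@nNormal, "\n")
  cat("  no tangle counts:       ", object@nNoCounts, "\n")
  cat("  AD gene variant:        ", object@nGeneVariant, "\n")
  cat("  hippocampal sclerosis:  ", object@nHippSclerosis, "\n")
  cat("  excluded", object@nExcluded, "-> remaining", object@nRemaining, "\n")
})

#' @describeIn ExclusionTally-class tallies as a named integer vector
#' @param x an \code{ExclusionTally}
#' @export
setGeneric("tallyCounts", function(x) standardGeneric("tallyCounts"))

#' @rdname ExclusionTally-class
#' @export
setMethod("tallyCounts", "ExclusionTally", function(x)
  c(n_input = x@nInput, n_not_ad = x@nNotAD, n_normal = x@nNormal,
    n_no_thioflavin = x@nNoCounts, n_gene_variant = x@nGeneVariant,
    n_hippocampal_sclerosis = x@nHippSclerosis,
    n_excluded_total = x@nExcluded, n_remaining = x@nRemaining))

#' Select the extreme-phenotype digital-pathology subgroup
#'
#' From a scored cohort, selects \code{nPerSubtype} cases per AD subtype:
#' the lowest CLix scores among hippocampal sparing cases, the highest among
#' limbic predominant cases, and, for typical AD, the cases whose scores lie
#' closest to the cohort median score ("centralized" cases). Cases flagged
#' with a glial-relevant copathology (meningitis, encephalitis,
#' (micro)infarct, Lewy body disease; colData column
#' \code{copathology_exclusion}) are screened out first when
#' \code{excludeCopathology}. Ties are broken by case_id lexicographic
#' order, so selection is deterministic.
#'
#' @param cohort a scored \linkS4class{CLixCohort} (see [scoreCohort()]).
#' @param nPerSubtype cases to select per subtype.
#' @param excludeCopathology screen out copathology-flagged cases first.
#' @return the subgroup as a \linkS4class{CLixCohort} (3 * nPerSubtype
#'   cases), with \code{metadata(...)$subgroup_of} recording the source size.
#' @export
selectSubgroup <- function(cohort, nPerSubtype, excludeCopathology = TRUE) {
  stopifnot(is(cohort, "CLixCohort"))
  cd <- colData(cohort)
  if (!"clix_score" %in% colnames(cd))
    stop("cohort must be scored first (scoreCohort)")
  eligible <- !is.na(cd$clix_score)
  if (excludeCopathology && "copathology_exclusion" %in% colnames(cd)) {
    cop <- cd$copathology_exclusion
    cop[is.na(cop)] <- FALSE
    eligible <- eligible & !cop
  }
  idx <- which(eligible)
  score <- cd$clix_score[idx]
  id <- cd$case_id[idx]
  subtype <- cd$subtype[idx]
  med <- stats::median(score)
  pick <- function(label, key) {
    members <- subtype == label
    if (sum(members) < nPerSubtype)
      stop(sprintf("insufficient eligible %s cases: need %d, have %d",
                   label, nPerSubtype, sum(members)))
    ord <- order(key[members], id[members])
    which(members)[ord[seq_len(nPerSubtype)]]
  }
  sel <- c(pick("HIPPOCAMPAL_SPARING", score),
           pick("TYPICAL", abs(score - med)),
           pick("LIMBIC_PREDOMINANT", -score))
  sub <- cohort[, idx[sel]]
  metadata(sub)$subgroup_of <- ncol(cohort)
  metadata(sub)$cohort_median_score <- med
  sub
}
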