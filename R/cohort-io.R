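## Covariate columns recognised in cohort tables, with coercion class.
COHORT_COVARIATES <- c(
  primary_dx_ad = "logical", neuropath_normal = "logical",
  ad_gene_variant = "logical", hippocampal_sclerosis = "logical",
  copathology_exclusion = "logical",
  age_onset_y = "numeric", age_death_y = "numeric", education_y = "numeric",
  duration_y = "numeric", sex = "character", apoe_e4 = "logical",
  trem2_r47h = "logical", atypical_syndrome = "logical",
  braak = "numeric", thal = "numeric", kalaria = "numeric",
  brain_weight_g = "numeric", tdp43_positive = "logical",
  mmse = "character",
  ## scoring columns, so a scored cohort CSV round-trips silently
  hippocampal_pct = "numeric", cortical_pct = "numeric", ratio = "numeric",
  ratio_pct = "numeric", clix_score = "numeric", subtype = "character")

#' Construct a CLixCohort from counts and covariates
#'
#' @param counts 5 x n numeric matrix of regional tangle counts (rows in the
#'   canonical region order; NA = missing), or an n x 5 table with region
#'   columns.
#' @param covariates data.frame/DataFrame of per-case covariates including
#'   \code{case_id}; the \code{mmse} column, if present, is a list of
#'   two-column matrices \code{(time_y, score)} or their string encoding
#'   (see [encodeMMSE()]).
#' @return a \linkS4class{CLixCohort}.
#' @export
CLixCohort <- function(counts, covariates) {
  m <- .asCountMatrix(counts)
  cd <- S4Vectors::DataFrame(covariates, check.names = FALSE)
  if (!"case_id" %in% colnames(cd))
    stop("covariates must contain 'case_id'")
  if ("mmse" %in% colnames(cd) && is.character(cd$mmse))
    cd$mmse <- S4Vectors::SimpleList(lapply(cd$mmse, decodeMMSE))
  colnames(m) <- cd$case_id
  new("CLixCohort",
      SummarizedExperiment(assays = list(tangles = m), colData = cd))
}

#' Encode / decode an MMSE series for flat-file storage
#'
#' A longitudinal MMSE series (time in years from first assessment, score
#' 0-30) is stored in cohort CSVs as \code{"t1:s1;t2:s2;..."}; an empty
#' string means no series.
#'
#' @param series two-column numeric matrix \code{(time_y, score)} with
#'   strictly increasing times, or NULL.
#' @return \code{encodeMMSE}: a single string; \code{decodeMMSE}: a
#'   two-column matrix (0 rows for an empty string).
#' @export
encodeMMSE <- function(series) {
  if (is.null(series) || nrow(series) == 0L) return("")
  paste(sprintf("%.10g:%.10g", series[, 1], series[, 2]), collapse = ";")
}

#' @rdname encodeMMSE
#' @param text encoded series string.
#' @export
decodeMMSE <- function(text) {
  out <- matrix(numeric(0), ncol = 2,
                dimnames = list(NULL, c("time_y", "score")))
  if (is.na(text) || !nzchar(text)) return(out)
  parts <- strsplit(strsplit(text, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  vals <- vapply(parts, function(p) as.numeric(p), numeric(2))
  out <- t(vals)
  colnames(out) <- c("time_y", "score")
  if (nrow(out) > 1L && any(diff(out[, 1]) <= 0))
    stop("MMSE times must be strictly increasing")
  out
}

#' Read a cohort table from CSV
#'
#' Expects a header with \code{case_id} and the five region columns
#' \code{ca1, subiculum, sup_temporal, inf_parietal, mid_frontal}; any of
#' the recognised covariate columns may follow. Unknown columns trigger a
#' warning and are carried through untouched. Rows failing validation
#' (negative counts, Braak outside 0-6, Thal outside 0-5, onset after
#' death, malformed MMSE series) are dropped and reported, with their line
#' numbers, in \code{metadata(cohort)$rejected}; a duration inconsistent
#' with onset/death by more than 1 year only warns.
#'
#' @param path CSV file (UTF-8, "." decimal, NA for missing).
#' @return a \linkS4class{CLixCohort}.
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"case_id" %in% colnames(df))
    stop("cohort file must contain a 'case_id' column")
  df$case_id <- as.character(df$case_id)
  if (!all(CLIX_REGIONS %in% colnames(df)))
    stop("cohort file must contain the five region columns: ",
         paste(CLIX_REGIONS, collapse = ", "))
  known <- c("case_id", CLIX_REGIONS, names(COHORT_COVARIATES))
  unknown <- setdiff(colnames(df), known)
  if (length(unknown))
    warning("unknown cohort columns kept as-is: ",
            paste(unknown, collapse = ", "))
  for (cl in intersect(names(COHORT_COVARIATES), colnames(df))) {
    df[[cl]] <- switch(COHORT_COVARIATES[[cl]],
                       logical = as.logical(df[[cl]]),
                       numeric = as.numeric(df[[cl]]),
                       as.character(df[[cl]]))
  }
  ## row-level validation; line numbers count the header as line 1
  reasons <- rep(NA_character_, nrow(df))
  cnt <- as.matrix(df[, CLIX_REGIONS])
  bad <- rowSums(!is.na(cnt) & (cnt < 0 | is.infinite(cnt))) > 0
  reasons[bad & is.na(reasons)] <- "negative or non-finite tangle count"
  if ("braak" %in% colnames(df)) {
    bad <- !is.na(df$braak) & (df$braak < 0 | df$braak > 6)
    reasons[bad & is.na(reasons)] <- "Braak stage outside 0-6"
  }
  if ("thal" %in% colnames(df)) {
    bad <- !is.na(df$thal) & (df$thal < 0 | df$thal > 5)
    reasons[bad & is.na(reasons)] <- "Thal phase outside 0-5"
  }
  if (all(c("age_onset_y", "age_death_y") %in% colnames(df))) {
    bad <- !is.na(df$age_onset_y) & !is.na(df$age_death_y) &
      df$age_onset_y > df$age_death_y
    reasons[bad & is.na(reasons)] <- "age at onset exceeds age at death"
    if ("duration_y" %in% colnames(df)) {
      off <- abs(df$age_death_y - df$age_onset_y - df$duration_y)
      iffy <- which(!is.na(off) & off > 1 & is.na(reasons))
      if (length(iffy))
        warning(length(iffy), " case(s) with duration inconsistent with ",
                "onset/death by > 1 y (kept)")
    }
  }
  mmseList <- NULL
  if ("mmse" %in% colnames(df)) {
    mmseList <- vector("list", nrow(df))
    for (i in seq_len(nrow(df))) {
      s <- tryCatch(decodeMMSE(df$mmse[i]), error = function(e) e)
      if (inherits(s, "error")) {
        if (is.na(reasons[i])) reasons[i] <- "malformed MMSE series"
        mmseList[[i]] <- decodeMMSE("")
      } else mmseList[[i]] <- s
    }
  }
  keep <- is.na(reasons)
  rejected <- data.frame(line = which(!keep) + 1L,
                         case_id = df$case_id[!keep],
                         reason = reasons[!keep])
  if (nrow(rejected))
    warning(nrow(rejected), " row(s) failed validation and were dropped")
  df <- df[keep, , drop = FALSE]
  cov <- df[, setdiff(colnames(df), c(CLIX_REGIONS, "mmse")), drop = FALSE]
  cov <- S4Vectors::DataFrame(cov, check.names = FALSE)
  if (!is.null(mmseList))
    cov$mmse <- S4Vectors::SimpleList(mmseList[keep])
  cohort <- CLixCohort(as.matrix(df[, CLIX_REGIONS]), cov)
  metadata(cohort)$rejected <- rejected
  cohort
}

#' Write a cohort to CSV
#'
#' Inverse of [readCohort()]: one row per case with the region columns, all
#' covariates, and the MMSE series in its string encoding. Scoring columns
#' present in colData are written too.
#'
#' @param cohort a \linkS4class{CLixCohort}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "CLixCohort"))
  m <- t(SummarizedExperiment::assay(cohort, "tangles"))
  cd <- colData(cohort)
  df <- data.frame(case_id = cd$case_id, m, check.names = FALSE,
                   row.names = NULL)
  for (cl in setdiff(colnames(cd), c("case_id", "mmse"))) {
    v <- cd[[cl]]
    if (is.atomic(v)) df[[cl]] <- v
  }
  if ("mmse" %in% colnames(cd))
    df$mmse <- vapply(cd$mmse, encodeMMSE, character(1))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

setMethod("show", "CLixCohort", function(object) {
  cat("CLixCohort with", ncol(object), "cases\n")
  m <- SummarizedExperiment::assay(object, "tangles")
  cat("  complete tangle counts:", sum(colSums(is.na(m)) == 0L), "\n")
  if ("clix_score" %in% colnames(colData(object))) {
    sc <- colData(object)$clix_score
    cat(sprintf("  scored: %d cases, median CLix %.1f\n",
                sum(!is.na(sc)), stats::median(sc, na.rm = TRUE)))
    print(table(subtype = colData(object)$subtype))
  }
  invisible(NULL)
})
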