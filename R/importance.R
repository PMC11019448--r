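#' Random-forest permutation variable importance (%IncMSE)
#'
#' Fits a regression forest of \code{nTrees} trees to the CLix scores and
#' measures each variable's importance as the percentage increase in
#' out-of-bag (OOB) mean squared error when that variable's values are
#' permuted:
#' \deqn{\%IncMSE_j = 100 \cdot (\overline{MSE}^{perm}_j - MSE^{OOB}) / MSE^{OOB}}
#' where the permuted OOB MSE is averaged over \code{nPermutations}
#' independent permutations of column j and predictions for each case use
#' only the trees for which the case was out of bag. Irrelevant variables
#' score near zero (possibly slightly negative). Incomplete cases are
#' dropped listwise (no imputation); the number dropped is recorded in the
#' report metadata. Set \code{raw = TRUE} for the unnormalised MSE increase
#' instead of a percentage.
#'
#' @param features data.frame of predictors (numeric, logical, character or
#'   factor columns); at least 2 variables and 50 complete cases.
#' @param target numeric response (CLix scores); must not be constant.
#' @param nTrees ensemble size; default 500.
#' @param seed RNG seed for the forest and the permutations.
#' @param nPermutations permutation repeats per variable; default 50.
#' @param mtry,nodesize forest hyperparameters; defaults follow common
#'   regression-forest practice (\code{max(floor(p/3), 1)} and 5).
#' @param raw report the raw OOB MSE increase rather than a percentage.
#' @return an \linkS4class{ImportanceReport}.
#' @export
rfImportance <- function(features, target, nTrees = 500L, seed = 1L,
                         nPermutations = 50L,
                         mtry = max(floor(ncol(features) / 3), 1L),
                         nodesize = 5L, raw = FALSE) {
  features <- as.data.frame(features)
  if (ncol(features) < 2L) stop("need at least 2 predictor variables")
  for (cl in colnames(features)) {
    v <- features[[cl]]
    if (is.logical(v)) features[[cl]] <- factor(v, c(FALSE, TRUE))
    else if (is.character(v)) features[[cl]] <- factor(v)
  }
  ok <- stats::complete.cases(features) & !is.na(target)
  nDropped <- sum(!ok)
  features <- features[ok, , drop = FALSE]
  target <- target[ok]
  n <- length(target)
  if (n < 50L) stop("need at least 50 complete cases, got ", n)
  if (length(unique(target)) < 2L) stop("target is constant")

  set.seed(seed)
  rf <- randomForest::randomForest(
    x = features, y = target, ntree = nTrees, mtry = mtry,
    nodesize = nodesize, keep.inbag = TRUE, keep.forest = TRUE,
    importance = FALSE)
  oob <- rf$inbag == 0L            # n x ntree: case OOB for tree?
  oobTrees <- rowSums(oob)
  usable <- oobTrees > 0L
  oobPred <- function(x) {
    ind <- stats::predict(rf, x, predict.all = TRUE)$individual
    rowSums(ind * oob)[usable] / oobTrees[usable]
  }
  yUse <- target[usable]
  baseMSE <- mean((oobPred(features) - yUse)^2)

  inc <- vapply(colnames(features), function(j) {
    mses <- vapply(seq_len(nPermutations), function(rep) {
      xp <- features
      xp[[j]] <- xp[[j]][sample.int(n)]
      mean((oobPred(xp) - yUse)^2)
    }, numeric(1))
    mean(mses) - baseMSE
  }, numeric(1))
  val <- if (raw) inc else 100 * inc / baseMSE
  ord <- order(-val)
  imp <- data.frame(variable = colnames(features)[ord],
                    pct_inc_mse = unname(val[ord]),
                    rank = seq_along(val), row.names = NULL)
  new("ImportanceReport", importance = imp,
      modelMeta = list(nTrees = nTrees, oobMSE = baseMSE, seed = seed,
                       nPermutations = nPermutations, nCases = n,
                       nDropped = nDropped, mtry = mtry,
                       nodesize = nodesize, raw = raw))
}

setMethod("show", "ImportanceReport", function(object) {
  meta <- object@modelMeta
  cat(sprintf("ImportanceReport: %d trees, %d cases (%d dropped), OOB MSE %.4g\n",
              meta$nTrees, meta$nCases, meta$nDropped, meta$oobMSE))
  print(object@importance, row.names = FALSE)
})

#' @describeIn ImportanceReport-class the ranked importance table
#' @param x an \code{ImportanceReport}
#' @export
setGeneric("importanceTable", function(x) standardGeneric("importanceTable"))

#' @rdname ImportanceReport-class
#' @export
setMethod("importanceTable", "ImportanceReport", function(x) x@importance)

#' Variable importance for a scored cohort
#'
#' Assembles the default clinicopathologic feature table from a scored
#' cohort and runs [rfImportance()] against the CLix scores. Age at death
#' is omitted by default because of its collinearity with age at onset, and
#' the MMSE decline rate because of its missingness; both can be forced in.
#'
#' @param cohort a scored \linkS4class{CLixCohort}.
#' @param includeAgeAtDeath,includeDecline include the collinear /
#'   missingness-prone variables.
#' @param ... passed to [rfImportance()].
#' @return an \linkS4class{ImportanceReport}.
#' @export
cohortImportance <- function(cohort, includeAgeAtDeath = FALSE,
                             includeDecline = FALSE, ...) {
  stopifnot(is(cohort, "CLixCohort"))
  cd <- colData(cohort)
  if (!"clix_score" %in% colnames(cd))
    stop("cohort must be scored first (scoreCohort)")
  vars <- c("age_onset_y", "duration_y", "education_y", "sex", "apoe_e4",
            "atypical_syndrome", "braak", "thal", "kalaria",
            "brain_weight_g")
  if (includeAgeAtDeath) vars <- c(vars, "age_death_y")
  vars <- intersect(vars, colnames(cd))
  feats <- as.data.frame(cd[, vars, drop = FALSE])
  if (includeDecline && "mmse" %in% colnames(cd))
    feats$mmse_decline <- vapply(cd$mmse, mmseDecline, numeric(1))
  rfImportance(feats, cd$clix_score, ...)
}
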