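#' Clinicopathologic heterogeneity analysis of a scored cohort
#'
#' Reproduces the cohort-level analysis table: Spearman rank correlation of
#' the CLix score with each continuous clinicopathologic measure (education,
#' age at symptomatic onset, disease duration, MMSE decline rate, age at
#' death, brain weight, Braak stage, Thal phase, Kalaria scale), and
#' Wilcoxon rank sum comparisons of CLix between the levels of each binary
#' characteristic (sex, APOE e4 carriership, TREM2 R47H carriership,
#' atypical clinical syndrome, TDP-43 status) with group medians and IQRs.
#'
#' @param cohort a scored \linkS4class{CLixCohort}.
#' @return data.frame with columns \code{variable}, \code{analysis},
#'   \code{estimate} (rho or W), \code{p_value}, \code{n}, and for group
#'   comparisons \code{group1}/\code{group2} labels with their medians and
#'   IQR bounds.
#' @export
analyzeCohort <- function(cohort) {
  stopifnot(is(cohort, "CLixCohort"))
  cd <- colData(cohort)
  if (!"clix_score" %in% colnames(cd))
    stop("cohort must be scored first (scoreCohort)")
  score <- cd$clix_score
  rows <- list()
  addCor <- function(name, v) {
    ok <- !is.na(v) & !is.na(score)
    if (sum(ok) < 3L || length(unique(v[ok])) < 2L) return()
    r <- spearmanTest(score[ok], v[ok])
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = name, analysis = "spearman", estimate = r@estimate,
      p_value = r@pValue, n = r@n, group1 = NA, group2 = NA,
      median1 = NA, iqr1_lo = NA, iqr1_hi = NA,
      median2 = NA, iqr2_lo = NA, iqr2_hi = NA)
  }
  addGrp <- function(name, g, lab1, lab2) {
    ok <- !is.na(g) & !is.na(score)
    a <- score[ok & g]; b <- score[ok & !g]
    if (length(a) < 2L || length(b) < 2L) return()
    w <- rankSumTest(a, b)
    q <- function(v) stats::quantile(v, c(.5, .25, .75), names = FALSE)
    qa <- q(a); qb <- q(b)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = name, analysis = "wilcoxon", estimate = w@estimate,
      p_value = w@pValue, n = w@n, group1 = lab1, group2 = lab2,
      median1 = qa[1], iqr1_lo = qa[2], iqr1_hi = qa[3],
      median2 = qb[1], iqr2_lo = qb[2], iqr2_hi = qb[3])
  }
  cont <- c(education_y = "education_y", age_onset_y = "age_onset_y",
            duration_y = "duration_y", age_death_y = "age_death_y",
            brain_weight_g = "brain_weight_g", braak = "braak",
            thal = "thal", kalaria = "kalaria")
  for (nm in names(cont))
    if (cont[[nm]] %in% colnames(cd)) addCor(nm, cd[[cont[[nm]]]])
  if ("mmse" %in% colnames(cd))
    addCor("mmse_decline", vapply(cd$mmse, mmseDecline, numeric(1)))
  if ("sex" %in% colnames(cd))
    addGrp("sex", cd$sex == "male", "male", "female")
  for (nm in c("apoe_e4", "trem2_r47h", "atypical_syndrome",
               "tdp43_positive"))
    if (nm %in% colnames(cd))
      addGrp(nm, as.logical(cd[[nm]]), "positive", "negative")
  do.call(rbind, rows)
}

#' Compare a continuous measure across the three AD subtypes
#'
#' Kruskal-Wallis test across the subtype groups followed by pairwise
#' Wilcoxon rank sum post hoc comparisons.
#'
#' @param cohort a scored \linkS4class{CLixCohort}.
#' @param value numeric per-case measure (same order as the cohort).
#' @return list with \code{overall} (a \linkS4class{StatResult}) and
#'   \code{pairwise} (data.frame of post hoc comparisons).
#' @export
subtypeComparison <- function(cohort, value) {
  stopifnot(is(cohort, "CLixCohort"))
  cd <- colData(cohort)
  if (!"subtype" %in% colnames(cd))
    stop("cohort must be scored first (scoreCohort)")
  ok <- !is.na(cd$subtype) & !is.na(value)
  groups <- split(value[ok], factor(cd$subtype[ok], CLIX_SUBTYPES))
  groups <- groups[lengths(groups) > 0L]
  overall <- kruskalWallisTest(groups)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(p) {
    w <- rankSumTest(groups[[p[1]]], groups[[p[2]]])
    data.frame(group1 = p[1], group2 = p[2], W = w@estimate,
               p_value = w@pValue)
  }))
  list(overall = overall, pairwise = pairwise)
}
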