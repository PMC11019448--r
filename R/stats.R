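.statResult <- function(name, estimate, p, n, groups = character(0),
                        details = list()) {
  new("StatResult", statisticName = name, estimate = as.numeric(estimate),
      pValue = min(max(as.numeric(p), 0), 1), n = as.integer(n),
      groups = as.character(groups), details = details)
}

setMethod("show", "StatResult", function(object) {
  cat(sprintf("%s: estimate = %.4g, p = %.3g, n = %d\n",
              object@statisticName, object@estimate, object@pValue,
              object@n))
  if (length(object@details))
    cat("  ", paste(names(object@details), unlist(object@details),
                    sep = " = ", collapse = "; "), "\n")
})

#' @describeIn StatResult-class the point estimate
#' @param x a \code{StatResult}
#' @export
setGeneric("statEstimate", function(x) standardGeneric("statEstimate"))

#' @rdname StatResult-class
#' @export
setMethod("statEstimate", "StatResult", function(x) x@estimate)

#' @describeIn StatResult-class the two-sided p value
#' @export
setGeneric("statPValue", function(x) standardGeneric("statPValue"))

#' @rdname StatResult-class
#' @export
setMethod("statPValue", "StatResult", function(x) x@pValue)

.completePairs <- function(...) {
  vals <- list(...)
  ok <- Reduce(`&`, lapply(vals, function(v) !is.na(v)))
  lapply(vals, function(v) v[ok])
}

#' Spearman rank correlation
#'
#' Two-sided Spearman correlation with mid-rank tie handling (the p value
#' uses the t approximation, which accommodates ties).
#'
#' @param x,y numeric vectors of equal length; incomplete pairs are dropped;
#'   at least 3 complete pairs are required.
#' @return a \linkS4class{StatResult} with estimate rho.
#' @export
spearmanTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  v <- .completePairs(x, y)
  x <- v[[1]]; y <- v[[2]]
  n <- length(x)
  if (n < 3L) stop("spearman requires at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  .statResult("spearman", unname(ct$estimate), ct$p.value, n)
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms all three vectors (mid-ranks for ties), residualizes the
#' ranks of \code{x} and \code{y} on the ranks of the covariate \code{z} by
#' least squares, and correlates the residuals (Pearson); the two-sided p
#' value uses a t statistic on n - 3 degrees of freedom. With a constant
#' covariate the plain Spearman correlation is returned with a warning.
#'
#' @param x,y,z numeric vectors of equal length; incomplete triples dropped;
#'   at least 4 complete triples required.
#' @return a \linkS4class{StatResult}.
#' @export
partialSpearmanTest <- function(x, y, z) {
  if (length(unique(c(length(x), length(y), length(z)))) != 1L)
    stop("x, y and z must have equal length")
  v <- .completePairs(x, y, z)
  x <- v[[1]]; y <- v[[2]]; z <- v[[3]]
  n <- length(x)
  if (n < 4L) stop("partial spearman requires at least 4 complete triples")
  if (length(unique(z)) < 2L) {
    warning("constant covariate: returning plain Spearman correlation")
    res <- spearmanTest(x, y)
    res@statisticName <- "partial_spearman"
    res@details <- list(covariate = "constant")
    return(res)
  }
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- stats::residuals(stats::lm(rx ~ rz))
  ey <- stats::residuals(stats::lm(ry ~ rz))
  r <- stats::cor(ex, ey)
  tstat <- r * sqrt((n - 3) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 3)
  .statResult("partial_spearman", r, p, n,
              details = list(method = "residualized ranks"))
}

#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected H statistic with chi-square p value. When every
#' observation is identical across groups, H = 0 and p = 1 by convention.
#'
#' @param groups list of at least two numeric vectors (each non-empty,
#'   total n >= 5).
#' @return a \linkS4class{StatResult} with estimate H.
#' @export
kruskalWallisTest <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0L)) stop("each group must be non-empty")
  vals <- unlist(groups)
  if (length(vals) < 5L) stop("need at least 5 observations in total")
  if (length(unique(vals)) == 1L)
    return(.statResult("kruskal_wallis", 0, 1, length(vals),
                       details = list(note = "all values identical")))
  kt <- stats::kruskal.test(groups)
  .statResult("kruskal_wallis", unname(kt$statistic), kt$p.value,
              length(vals),
              details = list(df = unname(kt$parameter)))
}

#' Wilcoxon rank sum test (Mann-Whitney)
#'
#' Uses the exact distribution when the smaller sample has at most 8
#' observations and there are no ties across samples, otherwise the normal
#' approximation with continuity and tie correction. The method used is
#' recorded in the result details.
#'
#' @param a,b numeric vectors (non-empty; NAs dropped).
#' @return a \linkS4class{StatResult} with estimate W (rank-sum statistic
#'   of the first sample above its minimum).
#' @export
rankSumTest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- min(length(a), length(b)) <= 8L && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  .statResult("wilcoxon_rank_sum", unname(wt$statistic), wt$p.value,
              length(a) + length(b),
              details = list(method = if (exact) "exact"
                             else "normal approximation"))
}

#' Fisher exact test
#'
#' Two-sided exact test on a 2 x 2 (or 2 x K) contingency table of
#' non-negative integer counts with positive margins. For 2 x 2 tables the
#' estimate is the conditional maximum-likelihood odds ratio and the p
#' value sums hypergeometric tables no more probable than the observed one;
#' wider tables are evaluated by complete enumeration over tables with the
#' observed margins (no estimate reported).
#'
#' @param tab matrix of counts.
#' @return a \linkS4class{StatResult}.
#' @export
fisherExactTest <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)) || any(!is.finite(tab)))
    stop("table must contain non-negative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero margin")
  ft <- stats::fisher.test(tab)
  est <- if (!is.null(ft$estimate)) unname(ft$estimate) else NA_real_
  .statResult("fisher_exact", est, ft$p.value, sum(tab),
              details = list(dim = paste(dim(tab), collapse = "x")))
}

#' MMSE decline slope, in points lost per year
#'
#' The negated least-squares slope of MMSE score on time, so a positive
#' value means cognitive decline. Series with fewer than two assessments
#' yield NA (propagated as missing downstream).
#'
#' @param series two-column matrix \code{(time_y, score)} with strictly
#'   increasing times, or the time vector when \code{score} is given.
#' @param score optional score vector accompanying a time vector.
#' @return points lost per year (numeric scalar, NA if insufficient data).
#' @examples
#' mmseDecline(cbind(c(0, 5), c(30, 20)))  # 2 points/y
#' @export
mmseDecline <- function(series, score = NULL) {
  if (!is.null(score)) series <- cbind(series, score)
  if (is.null(series) || nrow(series) < 2L) return(NA_real_)
  t <- series[, 1]; s <- series[, 2]
  if (any(diff(t) <= 0)) stop("MMSE times must be strictly increasing")
  -unname(stats::coef(stats::lm(s ~ t))[2])
}

#' Format a printed proportion as a rounded percentage
#'
#' Reporting-layer rounding: percentages are rounded half-up (never
#' banker's rounding) at the stated number of decimals, e.g.
#' \code{formatPercent(633, 1361, 0)} is 47 and
#' \code{formatPercent(1282, 1361, 1)} is 94.2.
#'
#' @param count numerator.
#' @param total denominator (> 0).
#' @param digits decimals to keep; default 1.
#' @return numeric percentage on the 0-100 scale.
#' @export
formatPercent <- function(count, total, digits = 1L) {
  if (any(total <= 0)) stop("total must be positive")
  f <- 10^digits
  floor(100 * count / total * f + 0.5) / f
}
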