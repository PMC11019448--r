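## Independent brute-force oracles used to check the analysis layer.
## These deliberately avoid the code paths (and library calls) they verify.

## mid-rank percentile by explicit counting
oraclePercentile <- function(value, ref) {
  below <- 0; equal <- 0
  for (r in ref) {
    if (r < value) below <- below + 1
    else if (r == value) equal <- equal + 1
  }
  100 * (below + 0.5 * equal) / length(ref)
}

## Spearman rho as Pearson on mid-ranks
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## exact two-sided Wilcoxon rank-sum p by enumerating all C(n, n1)
## assignments of pooled ranks to the first sample
oracleWilcoxP <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  pLess <- mean(ws <= wObs)
  pMore <- mean(ws >= wObs)
  min(1, 2 * min(pLess, pMore))
}

## two-sided Fisher p for a 2 x K table by enumerating every table with the
## observed margins; table probability from products of binomial
## coefficients (conditional multivariate hypergeometric)
oracleFisherP <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  K <- ncol(tab)
  logProb <- function(row1) {
    if (any(row1 < 0) || any(cs - row1 < 0)) return(-Inf)
    sum(lchoose(cs, row1)) - lchoose(n, rs[1])
  }
  grid <- expand.grid(lapply(seq_len(K - 1), function(j) 0:min(rs[1], cs[j])))
  obs <- exp(logProb(as.numeric(tab[1, ])))
  tot <- 0
  for (i in seq_len(nrow(grid))) {
    row1 <- c(as.numeric(grid[i, ]), rs[1] - sum(grid[i, ]))
    p <- exp(logProb(row1))
    if (p <= obs * (1 + 1e-7)) tot <- tot + p
  }
  min(1, tot)
}

## tie-corrected Kruskal-Wallis H from the textbook formula
oracleKruskalH <- function(groups) {
  vals <- unlist(groups)
  N <- length(vals)
  r <- rank(vals)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (N + 1)
  t <- table(vals)
  H / (1 - sum(t^3 - t) / (N^3 - N))
}

## independent re-implementation of the composite score from the counting
## oracle (used against computeCLix)
oracleCLix <- function(counts, ref, pseudocount = 0.5) {
  regs <- referenceRegions(ref)
  p <- vapply(names(regs), function(r) oraclePercentile(counts[[r]], regs[[r]]),
              numeric(1))
  hp <- (p[["ca1"]] + p[["subiculum"]]) / 2
  cp <- (p[["sup_temporal"]] + p[["inf_parietal"]] + p[["mid_frontal"]]) / 3
  ratio <- (mean(c(counts[["ca1"]], counts[["subiculum"]])) + pseudocount) /
    (mean(c(counts[["sup_temporal"]], counts[["inf_parietal"]],
            counts[["mid_frontal"]])) + pseudocount)
  rp <- oraclePercentile(ratio, referenceRatios(ref))
  0.4 * (rp + hp + (100 - cp)) / 3
}

## small random count matrix in canonical region-by-case layout
randomCountMatrix <- function(n, lambda = c(25, 20, 12, 10, 9)) {
  m <- do.call(rbind, lapply(lambda, function(l) rpois(n, l)))
  m <- m * 1.0
  rownames(m) <- c("ca1", "subiculum", "sup_temporal", "inf_parietal",
                   "mid_frontal")
  m
}

## a reference whose per-region supports are strictly positive (so a zero
## count sits below the whole support)
randomPositiveReference <- function(n = 30) {
  m <- randomCountMatrix(n)
  buildReference(m + 0.5)
}
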