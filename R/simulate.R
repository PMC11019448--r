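#' Configure the synthetic cohort generator
#'
#' Builds a \linkS4class{SimConfig} describing an autopsy-series-like AD
#' cohort. Every case carries a latent corticolimbic trait lambda ~
#' Beta(a, b) on (0, 1): lambda near 1 means limbic-predominant pathology
#' (high hippocampal, low cortical tangle burden), lambda near 0
#' hippocampal-sparing. Regional tangle counts are negative binomial with
#' mean \code{baseMean * exp(slope * (lambda - 0.5))} — hippocampal slopes
#' positive, cortical negative — and shared dispersion (size) 1.5, i.e.
#' overdispersed as real tangle counts are. Continuous covariates are
#' coupled to lambda through a Gaussian copula at configured Spearman
#' strengths (the population Pearson correlation on the normal scale is
#' \code{2 sin(pi rho / 6)}, so the realized Spearman matches the target);
#' binary covariates follow logistic probability curves in lambda. Default
#' effect directions and strengths follow the reported clinicopathologic
#' associations: age at onset +0.39, MMSE decline rate -0.27 (faster
#' decline at the cortical-predominant end), education -0.11, disease
#' duration +0.07, Braak stage -0.18, Kalaria scale +0.10, Thal and brain
#' weight null; atypical syndrome, male sex and TREM2 R47H carriership
#' more likely at low lambda, APOE e4 and TDP-43 positivity at high lambda.
#'
#' @param nCases cohort size.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param latentShape Beta shape pair for lambda; default c(2, 2) gives a
#'   unimodal full-range score distribution.
#' @param regionCurves data.frame(region, baseMean, slope); defaults give
#'   an approximately 20-fold mean dynamic range across the continuum.
#' @param dispersion negative-binomial size; default 1.5.
#' @param effects named list overriding individual default effect settings.
#' @param exclusionCounts optional five per-rule exclusion counts to plant
#'   (see [plantExclusions()]).
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(nCases = 2000L, seed = 1L, latentShape = c(2, 2),
                      regionCurves = NULL, dispersion = 1.5,
                      effects = list(), exclusionCounts = integer(0)) {
  if (is.null(regionCurves))
    regionCurves <- data.frame(
      region = CLIX_REGIONS,
      baseMean = c(25, 20, 12, 10, 9),
      slope = c(3, 3, -3, -3, -3))
  defaults <- list(
    age_onset = list(rho = 0.39, mean = 72, sd = 9),
    decline_rate = list(rho = -0.27, shape = 3, mean = 2.5),
    education = list(rho = -0.11, mean = 14, sd = 2.7),
    duration = list(rho = 0.07, shape = 4, mean = 9),
    brain_weight = list(rho = 0, mean = 1050, sd = 120),
    braak = list(rho = -0.18, levels = 3:6, probs = c(.05, .15, .35, .45)),
    thal = list(rho = 0.01, levels = 2:5, probs = c(.10, .20, .35, .35)),
    kalaria = list(rho = 0.10, levels = 0:10,
                   probs = stats::dbinom(0:10, 10, 0.3)),
    sex_male = list(base = 0.47, slope = -1.2),
    apoe_e4 = list(base = 0.55, slope = 1.2),
    trem2_r47h = list(base = 0.032, slope = -2.0),
    atypical = list(base = 0.15, slope = -2.5),
    tdp43 = list(base = 0.55, slope = 1.5),
    copathology = list(base = 0.25, slope = 0),
    missing = list(apoe = 0.05, trem2 = 0.28, tdp43 = 0.10,
                   education = 0.15, mmse = 0.30),
    mmse = list(baselineMean = 24, baselineSD = 3, noiseSD = 1.2,
                visitsMin = 2, visitsMax = 5))
  unknown <- setdiff(names(effects), names(defaults))
  if (length(unknown))
    stop("unknown effect settings: ", paste(unknown, collapse = ", "))
  for (nm in names(effects))
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], effects[[nm]])
  new("SimConfig", nCases = as.integer(nCases), seed = as.integer(seed),
      latentShape = as.numeric(latentShape), regionCurves = regionCurves,
      dispersion = as.numeric(dispersion), effects = defaults,
      exclusionCounts = as.integer(exclusionCounts))
}

## Gaussian-copula draw coupled to the latent normal score zLam at Spearman
## target rho; qfun maps uniforms to the marginal.
.copulaDraw <- function(zLam, rho, qfun) {
  r <- 2 * sin(pi * rho / 6)
  z <- r * zLam + sqrt(1 - r^2) * stats::rnorm(length(zLam))
  qfun(stats::pnorm(z))
}

.qDiscrete <- function(levels, probs) {
  cum <- cumsum(probs / sum(probs))
  function(u) levels[findInterval(u, cum, left.open = TRUE) + 1L]
}

.logisticFlag <- function(lam, base, slope) {
  p <- stats::plogis(stats::qlogis(base) + slope * (lam - 0.5))
  stats::rbinom(length(lam), 1L, p) == 1L
}

#' Generate a synthetic AD autopsy cohort
#'
#' Draws the latent trait, regional tangle counts and coupled covariates
#' described in [simConfig()]. The per-case hidden truth (lambda and the
#' true MMSE decline rate) is stored in \code{metadata(cohort)$truth};
#' downstream analyses never see it. Output is fully reproducible from the
#' config seed. When \code{exclusionCounts} is set in the config, the
#' corresponding exclusion flags are planted after generation.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{CLixCohort}.
#' @examples
#' cohort <- simulateCohort(simConfig(nCases = 200, seed = 42))
#' cohort
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@nCases
  ef <- config@effects
  zLam <- stats::rnorm(n)
  lam <- stats::qbeta(stats::pnorm(zLam), config@latentShape[1],
                      config@latentShape[2])
  counts <- vapply(seq_len(5), function(i) {
    mu <- config@regionCurves$baseMean[i] *
      exp(config@regionCurves$slope[i] * (lam - 0.5))
    as.numeric(stats::rnbinom(n, mu = mu, size = config@dispersion))
  }, numeric(n))
  m <- t(counts)
  rownames(m) <- CLIX_REGIONS

  ageOnset <- .copulaDraw(zLam, ef$age_onset$rho, function(u)
    stats::qnorm(u, ef$age_onset$mean, ef$age_onset$sd))
  decline <- .copulaDraw(zLam, ef$decline_rate$rho, function(u)
    stats::qgamma(u, shape = ef$decline_rate$shape,
                  scale = ef$decline_rate$mean / ef$decline_rate$shape))
  education <- .copulaDraw(zLam, ef$education$rho, function(u)
    pmax(6, stats::qnorm(u, ef$education$mean, ef$education$sd)))
  duration <- .copulaDraw(zLam, ef$duration$rho, function(u)
    stats::qgamma(u, shape = ef$duration$shape,
                  scale = ef$duration$mean / ef$duration$shape))
  brainWeight <- .copulaDraw(zLam, ef$brain_weight$rho, function(u)
    stats::qnorm(u, ef$brain_weight$mean, ef$brain_weight$sd))
  braak <- .copulaDraw(zLam, ef$braak$rho,
                       .qDiscrete(ef$braak$levels, ef$braak$probs))
  thal <- .copulaDraw(zLam, ef$thal$rho,
                      .qDiscrete(ef$thal$levels, ef$thal$probs))
  kalaria <- .copulaDraw(zLam, ef$kalaria$rho,
                         .qDiscrete(ef$kalaria$levels, ef$kalaria$probs))

  sexMale <- .logisticFlag(lam, ef$sex_male$base, ef$sex_male$slope)
  apoe <- .logisticFlag(lam, ef$apoe_e4$base, ef$apoe_e4$slope)
  trem2 <- .logisticFlag(lam, ef$trem2_r47h$base, ef$trem2_r47h$slope)
  atypical <- .logisticFlag(lam, ef$atypical$base, ef$atypical$slope)
  tdp43 <- .logisticFlag(lam, ef$tdp43$base, ef$tdp43$slope)
  copath <- .logisticFlag(lam, ef$copathology$base, ef$copathology$slope)

  miss <- ef$missing
  naOut <- function(x, p) { x[stats::runif(length(x)) < p] <- NA; x }
  apoe <- naOut(apoe, miss$apoe)
  trem2 <- naOut(trem2, miss$trem2)
  tdp43 <- naOut(tdp43, miss$tdp43)
  education <- naOut(education, miss$education)

  mm <- ef$mmse
  mmse <- vector("list", n)
  hasSeries <- stats::runif(n) >= miss$mmse
  for (i in seq_len(n)) {
    if (!hasSeries[i]) { mmse[[i]] <- decodeMMSE(""); next }
    k <- sample(mm$visitsMin:mm$visitsMax, 1L)
    t <- round(cumsum(c(0, stats::runif(k - 1L, 0.6, 1.5))), 3)
    base <- min(30, max(12, stats::rnorm(1, mm$baselineMean, mm$baselineSD)))
    s <- pmin(30, pmax(0, base - decline[i] * t +
                         stats::rnorm(k, 0, mm$noiseSD)))
    mmse[[i]] <- cbind(time_y = t, score = round(s, 1))
  }

  cov <- S4Vectors::DataFrame(
    case_id = sprintf("SIM%05d", seq_len(n)),
    primary_dx_ad = TRUE, neuropath_normal = FALSE,
    ad_gene_variant = FALSE, hippocampal_sclerosis = FALSE,
    copathology_exclusion = copath,
    age_onset_y = ageOnset, age_death_y = ageOnset + duration,
    education_y = education, duration_y = duration,
    sex = ifelse(sexMale, "male", "female"),
    apoe_e4 = apoe, trem2_r47h = trem2, atypical_syndrome = atypical,
    braak = braak, thal = thal, kalaria = kalaria,
    brain_weight_g = brainWeight, tdp43_positive = tdp43)
  cov$mmse <- S4Vectors::SimpleList(mmse)
  cohort <- CLixCohort(m, cov)
  metadata(cohort)$truth <- S4Vectors::DataFrame(
    case_id = cov$case_id, lambda = lam, decline_rate = decline)
  metadata(cohort)$config <- config
  if (length(config@exclusionCounts))
    cohort <- plantExclusions(cohort, config@exclusionCounts,
                              seed = config@seed + 1L)
  cohort
}

#' Plant exclusion-rule flags at exact per-rule counts
#'
#' Randomly assigns disjoint exclusion flags so that the cascade of
#' [applyExclusions()] attributes exactly the requested number of cases to
#' each rule: not-AD primary diagnosis, neuropathologically normal, missing
#' tangle counts (the case's counts are blanked), AD gene variant, and
#' hippocampal sclerosis. No case receives two flags.
#'
#' @param cohort a \linkS4class{CLixCohort}.
#' @param counts five non-negative integers, in cascade order.
#' @param seed RNG seed for the assignment.
#' @return the flagged cohort.
#' @examples
#' cohort <- simulateCohort(simConfig(nCases = 100, seed = 1))
#' flagged <- plantExclusions(cohort, c(10, 5, 3, 1, 2), seed = 2)
#' applyExclusions(flagged)$tally
#' @export
plantExclusions <- function(cohort, counts, seed) {
  stopifnot(is(cohort, "CLixCohort"))
  counts <- as.integer(counts)
  if (length(counts) != 5L || any(counts < 0))
    stop("counts must be five non-negative integers")
  n <- ncol(cohort)
  if (sum(counts) > n)
    stop("requested exclusion flags (", sum(counts),
         ") exceed cohort size (", n, ")")
  set.seed(seed)
  idx <- sample.int(n, sum(counts))
  grp <- rep(seq_len(5L), counts)
  cd <- colData(cohort)
  for (cl in c("primary_dx_ad", "neuropath_normal", "ad_gene_variant",
               "hippocampal_sclerosis"))
    if (!cl %in% colnames(cd))
      cd[[cl]] <- cl == "primary_dx_ad"
  cd$primary_dx_ad[idx[grp == 1L]] <- FALSE
  cd$neuropath_normal[idx[grp == 2L]] <- TRUE
  cd$ad_gene_variant[idx[grp == 4L]] <- TRUE
  cd$hippocampal_sclerosis[idx[grp == 5L]] <- TRUE
  colData(cohort) <- cd
  blank <- idx[grp == 3L]
  if (length(blank)) {
    m <- SummarizedExperiment::assay(cohort, "tangles")
    m[, blank] <- NA_real_
    SummarizedExperiment::assay(cohort, "tangles") <- m
  }
  cohort
}
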