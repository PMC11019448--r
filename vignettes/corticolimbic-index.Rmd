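---
title: "The corticolimbic index: construction, simulation and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The corticolimbic index: construction, simulation and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CLixTools)
```

## The problem

Neurofibrillary-tangle pathology in Alzheimer disease (AD) does not affect
all brains alike. At autopsy, thioflavin-S tangle counts from five regions —
CA1 and subiculum in the posterior hippocampus, and the superior temporal,
inferior parietal and middle frontal association cortices — span a continuum
from relative cortical predominance with a spared hippocampus to relative
cortical sparing with heavy limbic involvement. The corticolimbic index
(CLix) flattens a case's five counts into one continuous score on [0, 40]
that locates it on this continuum; discrete subtype labels (hippocampal
sparing / typical / limbic predominant) are a secondary binning of the
score, retained because group comparisons and figure legends need them.

## Score construction

Scoring is relative to a **reference model**: per-region sorted count
distributions plus the per-case hippocampal:cortical ratios of the same
reference series (at least 20 complete cases; `buildReference()`). The
reference can be the cohort itself, or a fixed reference loaded from JSON
(`readReference()`) when scores must stay comparable across cohorts.

A value is placed on a reference distribution by the **mid-rank ECDF**,

$$P(v) = 100 \cdot \frac{\#\{r < v\} + \tfrac12 \#\{r = v\}}{n},$$

chosen over interpolation or the left/right-continuous ECDFs because tangle
counts are small integers with heavy ties: mid-ranking makes percentiles
symmetric (a value below the whole support gets 0, above it 100, the median
of an odd distinct reference exactly 50) and gives tied values identical
percentiles. `referencePercentile()` is the single implementation used for
regions and ratios alike.

The composite uses three components: the hippocampal percentile
$P_{hipp}$ (mean of CA1 and subiculum), the cortical percentile $P_{cort}$
(mean of the three cortices), and the percentile $P_{ratio}$ of the case
ratio $(\bar h + \varepsilon)/(\bar c + \varepsilon)$. The ratio term
captures the *relational* aspect — a case may be high in both compartments
absolutely yet clearly limbic-predominant relatively — while the two
compartment percentiles anchor the score in absolute burden. With weights
$w$ normalised to sum to one (equal by default),

$$\mathrm{CLix} = 0.4\,\big[w_r P_{ratio} + w_h P_{hipp} + w_c (100 - P_{cort})\big].$$

This is the simplest construction with the intended semantics — bounded on
[0, 40], non-decreasing in every hippocampal count, non-increasing in every
cortical count, 20 at the all-median point of a symmetric reference — and it
is deliberately isolated in one place (`computeCLix()`, with configurable
`weights`) so an alternative composite can be swapped in without touching
I/O, classification or analysis. The property tests (bounds, monotonicity,
attainment of 0 and 40 at the extremes) pin down the contract rather than
the particular algebra.

Numerical choices:

* **Pseudocount** $\varepsilon = 0.5$ keeps the ratio finite and positive
  when the cortical compartment is tangle-free, which genuinely occurs in
  extreme limbic-predominant cases. Build the reference with the same
  pseudocount used at scoring.
* **Subtype boundaries** are half-open: scores in [0, 10) are hippocampal
  sparing, [10, 30) typical, and [30, 40] limbic predominant — the boundary
  value 30 belongs to the limbic-predominant bin, 10 to the typical bin.
* **Missing regions** are rejected at scoring by default; the opt-in
  `allowPartial = TRUE` scores from the available regions of each
  compartment (at least one per compartment) for users who accept the
  extra variance.
* Reference JSON is written with 17 significant digits so doubles survive
  the round trip bit-exactly; otherwise a case tied with its own reference
  entry could shift by half a mid-rank step after save/load.
* Scores are carried at full precision and printed at one decimal.

## Cohort handling

`CLixCohort` extends `SummarizedExperiment`: the `tangles` assay is the
5 × n count matrix and `colData` carries covariates (demographics, APOE ε4,
TREM2 R47H, Braak stage, Thal phase, Kalaria scale, TDP-43 status, an MMSE
series stored as a list column). `readCohort()` validates rows rather than
files: a negative count, a Braak stage outside 0–6, an onset after death or
a non-increasing MMSE series drops that row into a line-numbered rejection
report; a disease duration disagreeing with onset/death by more than one
year warns but keeps the case.

The **exclusion cascade** (`applyExclusions()`) removes, in order: primary
neuropathologic diagnosis not AD; neuropathologically normal; tangle counts
absent; known AD gene variant; hippocampal sclerosis. The surviving set is
rule-order independent (the rules are case properties); only the per-rule
attribution depends on the order, and a case matching several rules is
counted once, under the first. This first-match convention is a design
choice — exclusion flow counts in the source material are printed as
disjoint without an attribution rule — and `plantExclusions()` plants flags
so that the cascade reproduces any requested per-rule tally exactly.

The digital-pathology **subgroup selector** (`selectSubgroup()`) takes, per
subtype, the n lowest-scoring hippocampal-sparing cases, the n
highest-scoring limbic-predominant cases, and the n typical cases closest
to the cohort median score — "centralized" is operationalised as minimal
|score − median| since no formal definition exists. Copathologies that
confound glial readouts (meningitis, encephalitis, (micro)infarcts, Lewy
body disease) are screened out first; ties break on case id, so selection
is deterministic without a seed.

## What the generator simulates — and what it does not

`simulateCohort()` exists so every downstream stage is testable without
restricted autopsy data. Each case has a latent corticolimbic trait
$\lambda \sim \mathrm{Beta}(2, 2)$; the symmetric unimodal default produces
a full-range, centre-heavy score distribution with both extremes populated.
Regional counts are negative binomial — tangle counts are overdispersed, so
Poisson is not an option — with dispersion (size) 1.5 and log-linear means
$\mu_r(\lambda) = \mathrm{base}_r \exp(s_r(\lambda - 0.5))$, $s_r = +3$ for
hippocampal and $-3$ for cortical regions (base means 25, 20, 12, 10, 9).
The ±3 slopes give an ~20-fold mean dynamic range across the continuum,
enough signal that the computed CLix tracks the latent trait (Spearman
ρ > 0.8 at n = 2000, verified in the acceptance suite) while per-region
counts stay realistically noisy.

Continuous covariates are coupled to $\lambda$ by a **Gaussian copula**: on
the latent normal scale the Pearson correlation is set to
$2\sin(\pi\rho_s/6)$, which makes the *population Spearman* equal the
target $\rho_s$ exactly, whatever the marginal. Default targets carry the
reported effect directions and magnitudes: age at onset +0.39, MMSE decline
rate −0.27 (faster decline toward the cortical-predominant end), education
−0.11, duration +0.07, Braak −0.18, Kalaria +0.10, Thal and brain weight
null. Realized Spearman lands within ±0.05 of target at n ≥ 5000 for the
continuous covariates; for the ordinal ones (Braak, Thal, Kalaria) the
coupling passes through the same copula but discretization into a few
levels attenuates the realized coefficient, so the ±0.05 fidelity check
applies only to the continuous set. Binary covariates follow logistic
curves in $\lambda$ chosen to reproduce the reported group-median
orderings: atypical syndrome, male sex and TREM2 R47H enriched at low
$\lambda$; APOE ε4 and TDP-43 positivity at high $\lambda$. MMSE series
have a per-case slope equal to the planted decline rate plus visit noise.

A note on one source ambiguity: the published correlation table prints the
MMSE-decline coefficient as +0.27 while the accompanying text describes
more rapid decline with lower scores; the generator follows the text's
direction (−0.27 between $\lambda$ and points lost per year).

The generator does **not** emulate: real per-region count distributions
(unpublished — base means and slopes are plausible stand-ins, exposed in
`simConfig()`), secular or site effects, covariate couplings beyond the
single latent trait (all cross-covariate correlation flows through
$\lambda$), informative missingness (dropout is uniform), neuroimaging
(SUVR/volumes would enter only as additional rank-coupled covariates), or
images of any kind. Passing tests therefore demonstrate that the machinery
recovers structure *of this planted form*; they cannot certify behaviour
on real cohorts with confounding the simulator lacks.

## Analysis layer

The statistical surface mirrors standard neuropathology practice: Spearman
correlation for continuous measures, Kruskal-Wallis with Wilcoxon rank sum
post hocs for group comparisons, Fisher's exact test for categorical
tables, all two-sided at α = .05 with no multiplicity correction by
default (mirroring the analysis convention of the source study; apply
`p.adjust` downstream if desired). Implementation rides on the stats
package (`cor.test`, `kruskal.test`, `wilcox.test`, `fisher.test`); the
test suite separately verifies each against brute-force
enumeration/counting oracles on small instances, and verifies nominal
type-I control (rejection rate 5% ± 2% under null simulation at n = 100,
1000 replicates). The Wilcoxon implementation switches from the exact
distribution to the tie-corrected normal approximation when the smaller
sample exceeds 8 or ties are present; the method used is recorded in each
result.

**Partial Spearman** (used for covariate-adjusted correlations, e.g.
adjusting imaging measures for scan-to-death time) is the residual-rank
construction: rank all three variables, residualize the ranks of x and y
on the ranks of z by least squares, correlate the residuals, and test with
n − 3 degrees of freedom. A copula-based alternative exists in the
literature; residual ranks were chosen for transparency and testability
(the self-adjustment null — y adjusted for itself — vanishes, and an
independent covariate leaves the plain Spearman essentially unchanged).

**Variable importance** uses a regression forest of 500 trees
(`randomForest`) and reports %IncMSE as a *percentage of the baseline
out-of-bag MSE*:

$$\%\mathrm{IncMSE}_j = 100\,\frac{\overline{\mathrm{MSE}}^{perm}_j - \mathrm{MSE}^{OOB}}{\mathrm{MSE}^{OOB}},$$

with the permuted MSE averaged over `nPermutations` whole-column
permutations and every prediction restricted to trees where the case was
out of bag. This realizes the "percentage increase in model error if the
variable were excluded" reading directly; the raw-difference variant (and
randomForest's sd-scaled native measure) answer subtly different questions,
so the raw increase is available via `raw = TRUE`. Listwise deletion is
used (no imputation), with the dropped count logged. In `cohortImportance()`
age at death is excluded by default (collinear with age at onset) and MMSE
decline by default (missingness), both overridable. Forest hyperparameters
beyond the tree count (mtry = ⌊p/3⌋, node size 5) follow common
regression-forest practice and are exposed.

## Problem sizes and runtime choices

The shipped test and acceptance workloads use: 10,000 extreme-input sweeps
for the score-bound property; 2000-case cohorts over 5 seeds for
latent-trait recovery and importance ranking (5 permutation repeats per
variable — ranking is stable far below the 50-repeat default); 5000-case
cohorts for copula-fidelity checks; 1000 null replicates at n = 100 for
type-I calibration; and ≥ 100 random small instances per enumeration
oracle. These sizes were chosen so the full suite runs on a laptop-class
single core in a few minutes while keeping Monte-Carlo error well inside
the asserted tolerances.

## Known limitations

* The exact composite formula of the originally published index is not
  public; this package's composite satisfies the published score semantics
  (0–40 range, direction, binning) but individual numeric scores are not
  comparable to published per-case values, and no claim of per-case
  equivalence is made.
* Whether published reference percentiles are fixed lookup tables or
  recomputed per cohort is unknown; both modes are supported, with
  cohort-derived as default.
* Scores depend only on ranks, so counting units (per field vs per mm²)
  do not affect them — but mixing units *within* one reference would.
* The occipital cortex is not part of the five-region panel, limiting
  sensitivity to posterior cortical atrophy phenotypes.
* Fisher's exact test is conservative at moderate n; its null rejection
  rate sits at the low end of the 5% ± 2% band.
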