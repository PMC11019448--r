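# CLixTools

Quantification of corticolimbic neurofibrillary-tangle distribution in
Alzheimer disease (AD) neuropathology, for brain-bank and autopsy-series
research.

Neuropathologically diagnosed AD is heterogeneous: some brains carry
disproportionate tangle pathology in association cortices with a relatively
spared hippocampus (*hippocampal sparing* AD), others show the converse
(*limbic predominant* AD), and most sit in between (*typical* AD). CLixTools
computes a **corticolimbic index (CLix)** — a continuous score from 0 to 40 —
from thioflavin-S tangle counts in five regions: CA1 and subiculum (posterior
hippocampus) and the superior temporal, inferior parietal and middle frontal
association cortices. Low scores indicate relative cortical predominance,
high scores relative cortical sparing.

## The score

Each regional count is placed on its reference distribution as a mid-rank
ECDF percentile, `P = 100 (n_below + ½ n_equal) / n`. With

- `P_hipp` — mean percentile of CA1 and subiculum,
- `P_cort` — mean percentile of the three cortical regions,
- `P_ratio` — percentile of the case's hippocampal:cortical mean-count ratio
  `(h̄ + ε) / (c̄ + ε)` (pseudocount ε = 0.5),

the index is

```
CLix = 0.4 × [ w_r·P_ratio + w_h·P_hipp + w_c·(100 − P_cort) ]  ,  w_r = w_h = w_c = 1/3
```

so CLix ∈ [0, 40], is non-decreasing in every hippocampal count and
non-increasing in every cortical count. Subtypes are binned as
CLix < 10 → hippocampal sparing, 10 ≤ CLix < 30 → typical,
CLix ≥ 30 → limbic predominant.

Around the score the package provides, as S4 / SummarizedExperiment
infrastructure:

- `CLixCohort` — tangle counts plus clinicopathologic covariates; CSV I/O
  with row-level validation (`readCohort`/`writeCohort`);
- the brain-bank exclusion cascade (`applyExclusions`) and the
  extreme-phenotype subgroup selector (`selectSubgroup`);
- a synthetic cohort generator (`simulateCohort`) with a latent
  corticolimbic trait, negative-binomial counts and copula-coupled
  covariates, for end-to-end testing without restricted autopsy data;
- the analysis layer: Spearman and partial Spearman correlation,
  Kruskal-Wallis, Wilcoxon rank sum, Fisher exact tests, MMSE decline
  slopes, and random-forest permutation variable importance (%IncMSE)
  (`analyzeCohort`, `cohortImportance`);
- a command-line pipeline (`inst/cli/clix.R`, or `clixCLI()` from R).

## Worked example

Score the bundled synthetic 40-case series (generated by
`simulateCohort`; no real patient data ship with the package):

```r
library(CLixTools)

path   <- system.file("extdata", "synthetic_cohort_n40.csv",
                      package = "CLixTools")
scored <- scoreCohort(readCohort(path))
scored
#> CLixCohort with 40 cases
#>   complete tangle counts: 40
#>   scored: 40 cases, median CLix 19.8
#> subtype
#> HIPPOCAMPAL_SPARING  LIMBIC_PREDOMINANT             TYPICAL
#>                   8                   7                  25

computeCLix(regionCounts(ca1 = 42, subiculum = 35, sup_temporal = 3,
                         inf_parietal = 5, mid_frontal = 2),
            S4Vectors::metadata(scored)$reference)
#> CLix 33.6 (LIMBIC_PREDOMINANT)
#>   hippocampal pct 81.2 | cortical pct 19.2 | ratio 10.2 (pct 90.0)
```

A case with heavy hippocampal (42, 35) but scant cortical (3, 5, 2) tangle
counts lands at CLix 33.6 — limbic predominant: its hippocampal burden sits
at the 81st percentile of the reference while its cortical burden sits at
the 19th, and its hippocampal:cortical ratio of 10.2 is above 90% of
reference cases.

On a simulated 2000-case series the analysis layer recovers the planted
clinicopathologic structure (older symptomatic onset and longer duration
with higher CLix, faster MMSE loss and higher education with lower CLix):

```r
big <- scoreCohort(simulateCohort(simConfig(nCases = 2000, seed = 1)))
head(analyzeCohort(big)[, 1:5], 9)
#>         variable analysis estimate  p_value    n
#> 1    education_y spearman  -0.0945 9.82e-05 1692
#> 2    age_onset_y spearman   0.3369 2.89e-54 2000
#> 3     duration_y spearman   0.0501 2.49e-02 2000
#> 4    age_death_y spearman   0.3224 1.34e-49 2000
#> 5 brain_weight_g spearman  -0.0100 6.54e-01 2000
#> 6          braak spearman  -0.1401 3.15e-10 2000
#> 7           thal spearman  -0.0127 5.72e-01 2000
#> 8        kalaria spearman   0.0877 8.60e-05 2000
#> 9   mmse_decline spearman  -0.1718 1.42e-10 1376
```

The same pipeline runs from a shell:

```sh
Rscript inst/cli/clix.R simulate --seed 1 --n 2000 --out cohort.csv
Rscript inst/cli/clix.R filter   --in cohort.csv  --out filtered.csv --tally tally.json
Rscript inst/cli/clix.R score    --in filtered.csv --out scored.csv
Rscript inst/cli/clix.R analyze  --in scored.csv  --out results.csv
```

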