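# metgains

Annual genetic gain for grain yield, estimated the way breeding programs
measure it from internationally distributed nursery series: replicated
α-lattice trials at many sites each year, a handful of long-term check
cultivars recurring across years, and new elite lines entering annually.
`metgains` implements the full analysis chain for such data, plus a
synthetic-data module so the whole chain is testable by parameter recovery
when the real multi-year raw data cannot be shipped.

The pipeline, in the order `run_pipeline()` executes it:

1. **Single-trial mixed models** — per trial,
   `y_ijk = μ + R_j + SB_k(R_j) + G_i + ε_ijk` (replicates fixed, sub-blocks
   random), fitted by REML; trials with entry-mean repeatability
   `σ²_g / (σ²_g + σ²_ε/r) < 0.05` are discarded.
2. **Yield-environment classification** — exact one-dimensional k-means
   (k = 3) on trial mean yield, pooled across years; labels LYE/MYE/HYE by
   ascending center; the high class is dropped.
3. **Factor-analytic multi-environment model** — per year within each class
   (and pooled "Across"),
   `y = Xb + Z_r r + Z_g g + Z_ge ge + e` with the between-site G×E
   covariance `ΛΛ' + D`; REML via an exact stratum factorization for
   balanced data; line predictions from the mixed-model equations.
4. **Check-relative yield and gain** —
   `GYC = (BLUP − MeanGY)/MeanGY × 100` against the checks present that
   year; top 10% of lines per year-by-class flagged; OLS of GYC on trial
   year gives %/yr, converted to kg/ha/yr through the class check mean.
5. **Coancestry grouping** — coefficient of parentage from a 3-column
   pedigree (recursive, memoized), PCA of the COP matrix, k-means grouping
   of the top lines (4 groups by default).

## Worked example

Simulate a 6-year series with a known 1.8 %/yr merit trend and run the whole
pipeline:

```r
library(metgains)
cfg <- sim_config(n_series = 6, sites_per_class = c(low = 4, medium = 3, high = 1),
                  entries_per_trial = 30, trend_pct_per_year = 1.8, seed = 11)
report <- run_pipeline(pipeline_config(sim = cfg, seed = 11, n_groups = 4))
report
```

```
Genetic-gain pipeline report
  trials: 48 in, 48 retained, 0 dropped (repeatability filter)
  environment cluster centers (t/ha): LYE=2.41  MYE=4.70  HYE=6.75
Genetic gain, LYE: 3.208 %/yr (72.55 kg/ha/yr)
  R^2 = 0.517, p(slope) = 0.000778, n = 18 points (per_line), check mean 2.26 t/ha
Genetic gain, MYE: 3.499 %/yr (150.28 kg/ha/yr)
  R^2 = 0.658, p(slope) = 4.43e-05, n = 18 points (per_line), check mean 4.29 t/ha
Genetic gain, Across: 3.671 %/yr (114.33 kg/ha/yr)
  R^2 = 0.731, p(slope) = 6.1e-06, n = 18 points (per_line), check mean 3.11 t/ha
  HYL coancestry groups:
 group LYE MYE Across total
     1   9   6      9    12
     2   6   5      4     7
     3   2   6      4     6
     4   1   1      1     2
```

Reading the output: 48 trials all passed the repeatability filter; k-means
found the three yield classes near their generating levels (2.4 / 4.6 / 6.5
t/ha) and dropped the high class; the estimated gain is the slope of the
top-decile lines' check-relative yield on year — at this tiny scale (4
low-class sites, 27 new lines/year, 6 years) the per-run estimate is noisy
around the injected 1.8 %/yr, which is why the shipped checks use seeded
ensembles; the kg/ha/yr figure is the %-slope times the class check mean
(2.26 t/ha for LYE here); and the 18 selected lines split into four
coancestry groups of sizes 12/7/6/2.

At the criterion scale used by the tests (12 series × 10 low-class sites,
50-entry trials, 20-run ensemble) the ensemble-mean LYE slope lands within
±0.3 of the injected 1.8 %/yr.

A hand-checkable end-to-end fixture (noise-free, two series × three sites)
ships in `inst/extdata/worked_example/` together with its expected slopes in
`expected.json`; `tests/testthat/test-pipeline.R` walks through the exact
arithmetic.

Individual stages are exported and classed (`fit_single_trial()`,
`fit_met()`, `blup_table()`, `compute_gyc()`, `select_hyl()`,
`gain_regression()`, `cop()`, `cop_matrix()`, `group_lines()`,
`kmeans1d()`), each with the usual `print`/`coef`/`summary` methods where
they apply.

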