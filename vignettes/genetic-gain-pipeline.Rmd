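---
title: "Estimating genetic gain from international yield-trial series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genetic gain from international yield-trial series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metgains` implements the statistical pipeline breeding programs use to
measure realized genetic gain from an annually distributed nursery: a series
of replicated yield trials grown at many sites each year, with a handful of
long-term check cultivars recurring across years. Because each year's new
lines are different, gain cannot be read off raw yields; it is estimated by
predicting every line's yield with a mixed model, expressing the prediction
relative to the checks grown beside it, and regressing that check-relative
yield on trial year.

This vignette records the models, every tunable constant, and the design
choices that were genuinely open, in enough detail to audit a run.

## Single-trial model and repeatability filtering

Each trial is an $\alpha$-lattice with $g$ entries (default 50), $r = 2$
replicates, and $b$ incomplete sub-blocks per replicate (default 5). The
plot-level model is

$$ y_{ijk} = \mu + R_j + SB_{k(j)} + G_i + \varepsilon_{ijk}, $$

with replicates fixed, sub-blocks within replicates random
$\mathcal{N}(0,\sigma^2_{sb})$, and iid residuals
$\mathcal{N}(0,\sigma^2_\varepsilon)$. Two companion fits are run:

* genotypes **fixed**, giving generalized-least-squares adjusted entry means
  at the REML variance estimates;
* genotypes **random**, giving $\sigma^2_g$ for the entry-mean repeatability
  $$ H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_\varepsilon / r}. $$

The repeatability basis (entry-mean rather than plot) is recorded in the
fitted object so downstream results are auditable. Trials with $H^2 < 0.05$
(strict inequality) or non-converged fits are discarded. A trial with neither
genetic nor residual variance would give $0/0$; its repeatability is defined
as 0 so degenerate trials are dropped rather than crashing the run.

REML is maximized on orthonormal error contrasts after profiling out the
residual scale, so only the variance *ratios* are optimized (on the log
scale, floored at $10^{-10}$, upper-bounded at $10^8$). The profiled
likelihood is evaluated in the low-rank subspace spanned by the random-effect
incidence columns (a Woodbury identity), which makes a 100-plot trial fit in
a few tens of milliseconds. A caveat of the filter worth knowing: with 50
entries and 2 replicates, a trial with *no* genetic signal still produces
$\hat\sigma^2_g > 0$ about half the time, and the 0.05 threshold is low
enough that roughly 40–45% of pure-noise trials pass it. The threshold is a
coarse guard against uninformative locations, not a hypothesis test.

## Environment classification

Retained trials are pooled across years and classified by k-means ($k = 3$)
on trial mean yield into low- (LYE), medium- (MYE) and high-yielding (HYE)
classes; the high class is excluded from all further analysis. Pooling
(rather than per-year clustering) keeps class labels comparable across years.
One-dimensional k-means has an exactly solvable structure — the optimal
partition is contiguous in sorted order — so the package uses an
$O(kn^2)$ dynamic program instead of Lloyd restarts. This removes the only
seed sensitivity in a stage the rest of the pipeline treats as
deterministic; multi-start Lloyd is retained in the test suite purely as a
cross-check that the dynamic program attains the optimum.

## Multi-environment model with factor-analytic G×E

Within each year, the sites of one class (and, for the "Across" analysis,
both retained classes pooled) are fitted jointly:

$$ \mathbf{y} = \mathbf{Xb} + \mathbf{Z}_r\mathbf{r} + \mathbf{Z}_g\mathbf{g}
   + \mathbf{Z}_{ge}\,\mathbf{ge} + \mathbf{e}, $$

with fixed site effects $\mathbf{b}$; random replicates within sites,
$\Sigma_r = \mathrm{diag}(\sigma^2_{r_j})$; random genotype main effects,
$G = \sigma^2_g I$ (no pedigree information enters here by design); and a
genotype-by-site deviation whose between-site covariance is factor-analytic,

$$ \Sigma_{ge} = \Lambda\Lambda' + D, $$

with $\Lambda$ an $s \times k$ loading matrix and $D$ diagonal. FA(k) spends
$sk - k(k-1)/2 + s$ parameters instead of the $s(s+1)/2$ of an unstructured
covariance. The default $k = 1$ is the smallest structure that models
between-site GE correlation; `compare_structures()` reports REML-based AIC
across $k$ (including the diagonal $k=0$ baseline) when the choice matters.
Identifiability uses the standard placement: zeros above the diagonal of the
leading $k \times k$ block of $\Lambda$, and the first nonzero entry of each
column nonnegative. Sub-block effects are deliberately absent from this
combined model; they are a within-trial nuisance already handled by the
single-trial stage.

### Estimation

The restricted likelihood is maximized by L-BFGS-B on log-variances and free
loadings. For complete balanced units — every genotype in every replicate of
every site, which is what the generator and most real nursery data provide —
the likelihood factorizes exactly into three independent strata:

1. the genotype-by-replicate interaction within sites (informs
   $\sigma^2_e$ alone);
2. the replicate contrasts within each site (inform
   $g\sigma^2_{r_j} + \sigma^2_e$);
3. the genotype-mean contrasts across sites, an $s$-dimensional Wishart
   problem with covariance
   $\sigma^2_g J + \Lambda\Lambda' + D + (\sigma^2_e/r) I$.

Every likelihood (and analytic gradient) evaluation then costs one
$s \times s$ Cholesky instead of an $n \times n$ one, which is what lets the
test suite run hundreds of end-to-end fits. Unbalanced or very small units
fall back to a dense covariance path; both paths compute the same orthonormal
error-contrast likelihood, and the tests verify they agree to numerical
precision. An EM formulation was considered and rejected: with the stratum
factorization available, direct quasi-Newton with an exact gradient is both
faster and simpler, and positive semidefiniteness of $\Lambda\Lambda' + D$
holds by construction at every iterate. Convergence uses `factr = 1e7`
(about $10^{-9}$ relative) with two deterministic moment-based starts; a
specific variance pinned at its $10^{-8}$ floor is flagged as a
Heywood-type collapse in the fit metadata.

BLUPs come from closed forms in the balanced case (they are algebraically
identical to Henderson's mixed-model equations; the tests check this against
an independent dense solve at $10^{-8}$) and from the dense equations
otherwise.

### Predicted line yield

The per-line prediction for an analysis unit is

mean fixed site effect + genotype BLUP + mean of the line's GE BLUPs over
the unit's sites.

Including the site-averaged GE term is a deliberate choice: with a genotype
main effect *plus* FA structure, a loading column that is nearly constant
across sites is statistically exchangeable with $\sigma^2_g$, so the
main-effect BLUP alone is not identifiable — but their sum is. The sum is
also the natural "expected performance of this line at an average site of
this class".

## Check-relative yield and gain

With $\mathrm{MeanGY}$ the mean predicted yield of the checks *present in
that year's trial set* (check rosters change across years; only checks
actually distributed that year count),

$$ \mathrm{GYC} = \frac{\mathrm{BLUP} - \mathrm{MeanGY}}{\mathrm{MeanGY}}
   \times 100 . $$

The checks' own GYC values average to zero in every unit by construction —
the tests assert this identity at $10^{-8}$. Within each year-by-class unit
the top $\lceil 0.10\,n \rceil$ non-check entries by GYC are flagged as the
highest yielding lines (HYLs), ties broken by identifier for
reproducibility. Pooling the HYL points of one class across years, ordinary
least squares of GYC on the series year gives the annual gain in %/yr; the
kg/ha/yr figure is slope/100 × (class mean predicted check yield), so the
ratio of the two slopes is the check mean by construction. Per-line points
are the default regression mode (a per-series-mean mode exists); selection
happens within year-by-class first precisely so that selection intensity is
constant across years and does not masquerade as trend.

Three estimation facts a user should expect to see in simulations: BLUP
shrinkage attenuates the recovered slope by the reliability of a line-mean
(about 8–12% at ten 2-replicate sites with the default variance components);
selecting the top decile on the same data that is regressed biases the
intercept upward but not the slope; and the per-line regression's standard
error is anti-conservative, because the selected lines of one year are a
positively correlated, selection-compressed cluster — in null simulations at
twelve series its nominal 95% interval covers zero only ~78% of the time,
while the per-series-mean mode's interval (one point per year, the actual
sampling unit of a trend) covers ~97%. Treat per-line $R^2$ and p-values as
descriptive; use the series-mean mode when calibrated inference on the slope
is needed.

## Coancestry grouping of the top lines

The coefficient of parentage is computed by the textbook recursion
($f(i,j) = \tfrac12[f(p_1(i),j) + f(p_2(i),j)]$,
$f(i,i) = \tfrac12[1 + f(p_1(i),p_2(i))]$), with unknown parents treated as
unique unrelated non-inbred founders and a selfed ancestor representable as
$p_1 = p_2$. The full matrix is built in one topological pass and memoized.
Input is a flat three-column table; breeder cross-string notation must be
flattened by the data provider beforehand (string grammars vary by
information system and are out of scope here).

Grouping of the HYLs is PCA on the column-centered COP matrix (centering is
a flag; centered is the default), keeping two component scores, then seeded
multi-start k-means with the default of four groups, relabeled in
decreasing size order. An automated rule necessarily differs from grouping
curated by eye from the pedigrees themselves; it is used because it is
reproducible.

## The synthetic-data generator

No raw multi-year nursery data ships with the package, so the generator is a
first-class module: it emits plot tables whose statistical structure is the
one the analysis assumes, together with the generating truth, so every stage
is testable by parameter recovery. Defaults (all overridable):

| constant | default | meaning |
|---|---|---|
| series × sites | 12 × (18 low, 18 medium, 5 high) | annual series and class sizes |
| entries | 50, of which 3 checks | per-trial entry list |
| design | 2 reps × 5 sub-blocks | alpha-lattice layout |
| class levels | 2.4 / 4.6 / 6.5 t/ha, site SD 0.35 | low/medium/high site means |
| trend | 1.8 %/yr of check yield | injected new-line merit trend |
| $\sigma^2_g$ | 0.08 (t/ha)² | line merit variance |
| GE | loadings $\mathcal{N}(0, 0.01)$, specific 0.02 | factor + specific G×E |
| $\sigma^2_{rep},\sigma^2_{sb},\sigma^2_e$ | 0.01, 0.01, 0.10 | design and plot noise |

The class sizes and centers mirror a twelve-year semi-arid nursery at desk
scale; the plot residual SD (0.32 t/ha on 2.4–4.6 t/ha yields, a 7–13% CV)
and the elite-line merit SD (0.28 t/ha) are values a trial analyst would
call ordinary for stress environments. The generating magnitude of G×E
relative to genetic variance at real sites is not derivable from summary
publications; the defaults here are chosen for testability (the FA stage is
well identified), not fidelity to any particular nursery.

Two generator choices deserve emphasis:

* **Merit scales with site level.** A line's contribution at a site with
  expected level $m_s$ is $(m_s/M)\,g_i$, $M$ being the mean level of the
  target classes. The injected trend is defined in percent of check yield,
  and only a proportional merit makes "x %/yr" mean the same thing in a
  2.4 t/ha and a 4.6 t/ha environment simultaneously — which is also the
  premise of regressing check-relative yield in the first place. The
  proportional part is exactly a rank-one GE component, so the analysis
  model accommodates it.
* **Checks are frozen.** Check merits are drawn once and reused in every
  series; the entire method rests on the checks being a fixed yardstick.
  Sub-block assignment is a seeded random partition per replicate — the
  analysis only needs the nesting, not an optimized alpha-design.

What the generator does **not** emulate: spatial field trend, weather-driven
site covariances, disease pressure, and check ageing (real checks can drift
as pathogens evolve). Passing recovery tests therefore certifies the
statistical machinery, not robustness to those field realities.

The pedigree generator produces founders plus lines mating within their
ancestor group with probability 0.98 (two founders per group at the
default); that concentration is what makes four groups separable in two
principal components. Weaker assortment or more founders per group blurs the
group structure — as it would in real germplasm.

## Problem sizes used by the shipped checks

The packaged test suite and acceptance script run, among other things: a
20-instance dense-oracle equivalence sweep; 200 single-trial REML fits at
$\sigma^2_g = \sigma^2_\varepsilon = 1$; 200 FA(1) recovery fits at 8 sites
× 100 genotypes; and 20-run (trend 1.8) plus 100-run (trend 0) end-to-end
ensembles, both at 12 series × 10 low-class sites × 50 entries. These
sizes were chosen so the whole suite completes on a single CPU in well under
half an hour while keeping Monte-Carlo error far below the tolerances being
asserted.

## Known limitations

* Genotype main effects assume unrelated lines ($G = \sigma^2_g I$); the
  coancestry matrix is computed but deliberately not used in prediction.
* The dense path is quadratic in memory and is capped at ~2,500 plots;
  seriously unbalanced large units are out of scope.
* The repeatability filter at 0.05 is permissive under the null (see above).
* Gain regressions are unweighted; series with fewer sites get no less
  weight (a weighted mode is a natural extension).
* The number of FA factors is a configuration knob, not an estimated
  quantity; `compare_structures()` is provided for that judgment.
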