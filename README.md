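# paleoxeno

Analysis of tea- and tobacco-related xenobiotics quantified in hair from
historical individuals.

## The problem

Hair preserves xenobiotics for centuries.  In frozen burials from Yakutia
(eastern Siberia, 1600–1900 AD), five compounds quantified in proximal
hair segments trace two consumption habits through the contact and
assimilation periods:

* the **methylxanthines** theobromine, caffeine and theophylline, whose
  joint detection pattern distinguishes beverage types (local herbal
  teas carry theobromine only; green tea adds caffeine; black tea all
  three; coffee caffeine only);
* **nicotine** and its metabolite **cotinine**, whose mean indexes
  tobacco exposure and whose within-person correlation separates genuine
  use from passive exposure.

paleoxeno is a toolbox for this kind of cohort, built around the
published 47-individual Yakutia reference panel that it embeds.  It is
aimed at biostatisticians and archaeometric toxicologists who need the
complete chain: a censoring-aware data model for left-censored
(non-detect) concentrations, calibration-validation math for the
underlying LC-MS/MS assay, deterministic consumption classification,
era-stratified statistics, correlation comparison across age classes,
geography-aware permutation tests, and spatial consumption surfaces — all
validated end to end on synthetic cohorts with known truth.

## The statistics at the core

* **Censoring model.** A measurement is a positive value in pg/mg *xor* a
  non-detect; descriptive summaries use detected values only, while
  exposure models (correlations, regressions, PCA) score non-detects
  as 0.
* **Classification rules.** Beverage type is a pure function of the
  methylxanthine detection pattern; tobacco tier cuts the
  nicotine/cotinine mean at 200 / 501 / 2500 pg/mg.
* **Era contrasts.** Two-sided Fisher exact tests on methylxanthine
  combination patterns across the 1800 AD split, and maximum-likelihood
  logistic regression of era on concentrations with Wald inference and
  separation diagnostics.
* **Correlation comparison.** Fisher r-to-z tests,
  `z = (atanh r₁ − atanh r₂) / √(1/(n₁−3) + 1/(n₂−3))`,
  with Zou's confidence interval for the difference of two independent
  correlations.
* **Geographic association.** Spearman rank correlation of concentration
  (or pipe presence) against great-circle distance to historical trade
  gateways; one-way permutation ANOVA over burial regions; and a
  perturbation-robustness probe that permutes 10% of values per
  replicate and reports how often |rs| stays above 0.5.
* **Consumption surfaces.** Correlation-matrix PCA (log scale) collapses
  each product's analytes to an axis-1 use index, interpolated over a
  lat/lon grid by barycentric linear interpolation on a Delaunay
  triangulation and normalized to [0, 0.7].

The methods vignette (`vignettes/paleoxeno-methods.Rmd`) documents every
modelling decision and the known discrepancies between recomputed and
published values.

## Worked example

```r
library(paleoxeno)

cohort <- load_cohort()        # the embedded 47-individual panel
detection_summary(cohort)$counts
#>   analyte      n_detected
#> 1 theobromine          31
#> 2 caffeine             29
#> 3 theophylline         19
#> 4 nicotine             43
#> 5 cotinine             47

head(classify_cohort(cohort), 3)
#>   sample_id drink                   drink_flagged tobacco_index tobacco_tier
#> 1         4 herbal_tea              FALSE                  15   low
#> 2        46 coffee_and_theophylline FALSE                 103   low
#> 3        37 nothing                 FALSE                  19.5 low

corr_by_age_class(cohort)      # nicotine/cotinine correlation per age class
#>   age_class     n     r
#> 1 0-15          8 0.555
#> 2 15-30        12 0.453
#> 3 30-50        14 0.662
#> 4 >50          10 0.918

cmp <- fisher_z_compare(0.5555, 8, 0.9183, 10)
cmp$z                          # -1.6255: children correlate less than seniors
zou_interval(0.5555, 8, 0.9183, 10)
#>   lower   upper
#> -1.1659  0.0583

fit_logistic(cohort)$coefficients   # era (post-1800) ~ TP + TB + CAF, ND -> 0
#>   term         estimate std_error      z      p
#> 1 (Intercept)  -1.06      0.445   -2.37  0.0177
#> 2 theophylline -0.00242   0.0195  -0.124 0.901
#> 3 theobromine  -0.00318   0.00430 -0.739 0.460
#> 4 caffeine      0.00682   0.00408  1.67  0.0943

pca_correlation(cohort)$eigenvalues # tea-use index spectrum
#> [1] 2.159 0.593 0.248
```

The detection counts say theobromine is the most widespread tea marker
(31/47, including pre-contact-style herbal teas), the per-age
correlations show the nicotine/cotinine coupling strengthening from
childhood (0.56) to seniority (0.92) — passive versus habitual exposure —
and the positive caffeine coefficient captures the post-1800
generalization of tea.  The leading PCA eigenvalue (2.16 of 3) says one
axis carries most methylxanthine co-variation: a single tea-use index is
a fair summary.

Synthetic cohorts with known truth exercise the same pipeline:

```r
sim <- generate_cohort(generator_spec(n_individuals = 200, seed = 1))
truth_check(sim)$gradient   # the built-in NE-SW caffeine gradient, recovered
```

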