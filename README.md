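# swdecomp

Wealth inequality in child severe wasting: risk differences,
random-effects pooling, and Blinder–Oaxaca decomposition.

## What this package is for

Severe wasting (SW) — a weight-for-height z-score below −3 SD of a
growth-standard median — concentrates among children from poor
households in most low- and middle-income countries. For analysts
working with child-level household-survey microdata (one record per
under-five child, with cluster ids, sampling weights, asset indicators
and sociodemographic covariates), `swdecomp` answers two questions:

1. **How unequal is the burden?** Survey-weighted SW prevalences by the
   poor/non-poor wealth dichotomy, per-country risk differences
   `RD = (prev_poor − prev_nonpoor) × 10` per 1000 children with
   cluster-robust confidence intervals, Breslow–Day (Tarone) odds-ratio
   homogeneity tests, DerSimonian–Laird random-effects pooling across
   countries, and a four-quadrant classification of countries by
   prevalence level × inequality direction.

2. **What drives the gap?** The Blinder–Oaxaca decomposition of the
   poor/non-poor gap in mean outcomes. Threefold, from the viewpoint of
   the non-poor group B:

   `gap = (X̄_A − X̄_B)'β_B + X̄_B'(β_A − β_B) + (X̄_A − X̄_B)'(β_A − β_B)`
   `     =      E (endowments) + C (coefficients) + I (interaction)`

   and twofold against a nondiscriminatory reference vector β*:

   `gap = (X̄_A − X̄_B)'β* + [X̄_A'(β_A − β*) + X̄_B'(β* − β_B)]`
   `     =  Q (explained)  +  U (unexplained)`

   For the binary SW outcome both are evaluated on the probability
   scale from weighted logistic group models via counterfactual mean
   predictions, with per-covariate detail through Yun weights and
   cluster-bootstrap standard errors.

Supporting modules build the inputs: an asset-based wealth index by
principal components (weighted correlation matrix, weight-balanced
quintiles, poor = bottom two quintiles), a neighbourhood
socioeconomic-disadvantage index per survey cluster, LMS
weight-for-height z-scores with the restricted tail adjustment and
plausibility flags, and a synthetic multi-country survey generator
whose decomposition ground truth is known analytically.

## Worked example

Published country-level prevalence tables are enough to recompute
per-country inequality:

```r
library(swdecomp)
cs <- country_summary()   # packaged country summary, DHS 2010-2018
rd <- risk_difference(cs$prev_poor, cs$prev_nonpoor)
head(data.frame(country = cs$country, rd = rd))
#>      country rd
#> 1    Burundi  9
#> 2     Comoro 14
#> 3   Ethiopia  9
#> 4      Kenya  6
#> 5     Malawi -2
#> 6 Mozambique 15
```

An end-to-end synthetic study (3 countries, 50 clusters each, known
generating models):

```r
cfg <- sim_config(n_countries = 3, clusters_per_country = 50,
                  children_per_cluster = 30, seed = 1)
report <- run_study(study_config(input = cfg, seed = 1))
report
#> Study report: 4445 records, 3 countries
#> Random-effects (DerSimonian-Laird) pooled RD: 7.16 per 1000 (95% CI -11.59 to 25.92)
#> tau^2 = 149.196 across 3 countries
#> Twofold decomposition (logit link, reference = B)
#>   gap = 0.0072
#>   explained   Q = 0.0060
#>   unexplained U = 0.0012
```

The pooled RD of 7.16 per 1000 says that, across the three simulated
countries, about 7 more children per 1000 have severe wasting among the
poor than among the non-poor; the wide CI reflects only three
countries. Of the 0.72-percentage-point poor/non-poor gap, 0.60 points
are explained by covariate composition (Q) and 0.12 points by differing
returns (U). Per-covariate detail of the endowments component:

```r
detailed_contributions(report$decomposition_threefold)[, c("term", "E", "share_E")]
#>                term       E share_E
#>         (Intercept)  0.0000  0.0000
#>  maternal_education  0.0010  0.1453
#>        media_access  0.0006  0.0855
#>           residence  0.0044  0.6166
#>           child_age -0.0001 -0.0106
```

Here rural/urban residence accounts for ~62% of the gap, maternal
education ~15%. The country table mirrors published summary layouts:

```r
format_summary_table(report$table1)[, c("country", "n", "prev_all",
                                        "prev_poor", "prev_nonpoor", "rd")]
#>    country    n prev_all prev_poor prev_nonpoor         rd
#>  country_1 1523      3.4       3.8          3.0   8.501210
#>  country_2 1448      5.9       7.3          4.7  25.856641
#>  country_3 1474      5.0       4.4          5.5 -10.958416
#>        All 4445      4.7       5.1          4.4   7.179609
```

Ground truth for any configuration comes from
`true_decomposition(cfg)`, which enumerates the generator's covariate
distribution analytically — the validation suite checks that estimated
components recover it across seeds.

A thin command-line wrapper lives at `inst/cli/swdecomp-cli.R`
(`simulate` and `run` subcommands over the same functions).

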