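# mrpstrat

Small-area estimation of a binary physical-activity outcome from survey
data by **multilevel regression and poststratification (MRP)**, with a
complete-pooling comparator and a split-sample cross-validation harness
that scores both estimators against held-out data.

## The problem and who this is for

Health surveillance surveys (the motivating case is VIGITEL, the Brazilian
telephone survey sampled per state capital) record whether each respondent
reaches 150 minutes per week of leisure-time physical activity, along with
gender, age group, and geographic unit. Estimating the share of active
people in a *subpopulation* — one capital, or one gender × age × capital
cell — from subgroup respondents alone is noisy, and a single-level
("complete pooling") regression determines its many geographic contrasts
poorly at small sample sizes. This package is for survey methodologists
and epidemiologists who want the MRP alternative with everything testable:
synthetic data with known ground truth, both competing models, census
weighting, and the cross-validation that adjudicates between them.

## The method

1. **Multilevel regression.** A Bayesian logistic model for the binary
   outcome y_i:

   Pr(y_i = 1) = logit⁻¹(β₀ + β_gender[j(i)] + β_age[k(i)] + α_unit[l(i)]),
   α_unit[l] ~ N(0, σ²_unit)

   with normal(0, 10) priors on population-level effects and an
   exponential(1) prior on σ_unit. The partially pooled unit intercepts
   shrink small-sample units toward the national mean. The comparator is
   the same model with unit as dummy-coded fixed contrasts (no variance
   component).

2. **Poststratification.** Per posterior draw, cell predictions θ_c over
   the 2 × 7 × 27 gender × age × capital grid are averaged with census
   weights: y_s = Σ_{c∈s} N_c θ_c / Σ_{c∈s} N_c. Draw-wise aggregation
   gives means and 90% credible intervals for any grouping.

3. **Cross-validation.** Half the survey (disaggregated per-unit
   proportions) is the estimation target; from the other half, Q random
   subsamples at several fractions are fitted with both models and scored
   by mean absolute error per unit and overall.

Posterior sampling is MCMC via JAGS (rjags) using its `glm` block
samplers; reference settings are 3 chains × 500 iterations with 250
warmup (750 retained draws).

## Worked example

```r
library(mrpstrat)
spec   <- vigitel_spec()                                  # 2 x 7 x 27 levels
census <- make_census(spec, seed = 1)                   # synthetic census counts
truth  <- draw_true_params(spec, unit_sd = 0.3, seed = 2)
survey <- simulate_survey(truth, census, n = 10000, seed = 3)

fit <- mrp_fit(survey, spec, control = mrp_control("reference", seed = 4))
fit
#> Bayesian multilevel logistic fit (MRP regression stage)
#>   10000 respondents; 750 retained draws (3 chain(s) x 250 post-warmup)
#>   max split-R-hat: 1.059  [CONVERGENCE FLAGGED]

poststratify(fit, census, by = "unit")[1:4, ]
#> Poststratified subpopulation estimates (90% credible intervals)
#>       unit   mean  lower  upper population
#>  capital01 0.3408 0.3029 0.3830     218237
#>  capital02 0.4505 0.4076 0.4925     214706
#>  capital03 0.3912 0.3519 0.4321     186562
#>  capital04 0.4700 0.4333 0.5056     268493

cv <- run_cv(survey, census, cv_design("test", seed = 5))
cv
#> Split-sample cross-validation: MRP vs single-level regression
#>   25 replicates x 2 fraction(s); 27 scored units
#>        method MAE @ 2.5% MAE @ 10%
#>           MRP    0.07812   0.06338
#>  single_level    0.18476   0.09780
```

Reading the output: each per-capital row is the census-weighted posterior
proportion of active adults with its 90% interval and the capital's
population. The cross-validation table shows the headline result — at a
2.5% subsample (~125 respondents) MRP's overall mean absolute error
(0.078) is less than half the single-level model's (0.185), and both
improve as the subsample grows. The split-R-hat flag on the fit is the
convergence gate being conservative at 250 retained draws per chain;
doubling `iterations` clears it without changing the estimates
appreciably.

A command-line wrapper covering simulate / fit / estimate / crossval is
installed at `system.file("cli", "mrp", package = "mrpstrat")`; see
`?mrp_cli`.

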