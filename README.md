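# beehab

Phylogenetic comparative analysis linking relative brain size to habitat
occupancy in bees.

Some bee species thrive in cities while most avoid them. The *cognitive
buffer hypothesis* proposes that a relatively large brain confers the
behavioural plasticity needed to exploit novel environments. `beehab`
provides the full analysis chain needed to test this idea on a species-level
comparative dataset — a phylogeny, brain and body measurements, and
georeferenced occurrence records over a natural/agricultural/urban land-cover
classification — together with a synthetic-data generator so every stage can
be exercised end to end without any download.

## The methods

**Relative brain size.** Brain mass scales allometrically with body size, so
the informative quantity is the residual of the log–log allometry. `pgls_fit()`
fits, by maximum likelihood,

    log(brain) = b0 + b1 * log(body) + e,   e ~ MVN(0, s^2 * V(lambda))

where `V(lambda)` is the phylogenetic (Brownian) covariance with off-diagonals
scaled by Pagel's lambda, profiled over [0, 1]. `relative_brain_size()` returns
the residuals: positive values mean a larger brain than the allometry predicts.

**Degree of habitat occupancy.** From filtered occurrence records
(`filter_records()`: years 1990–2022, at least two coordinate decimals;
`apply_min_records()`: at least 50 records per species), `build_matrix()`
tabulates species x habitat counts. `occupancy_percentiles()` draws randomized
matrices with the same row and column totals (Patefield's algorithm, the
`r2dtable` method) and scores, per cell, the percentage of simulated counts
below the observed one. Above the 80th percentile is *high* occupancy, below
the 20th is *low*, the boundaries themselves are intermediate.

**The association.** `phylo_logit()` regresses high (1) vs low (0) occupancy
per habitat on relative brain size with the phylogenetic covariance as a
random effect,

    logit P(y = 1) = beta0 + beta1 * x + u,   u ~ MVN(0, sigma^2 * C)

fitted by Laplace-approximated maximum likelihood (penalized IRLS for the
joint mode, bounded search over `sigma^2`). `phylo_signal()` gives Pagel's
lambda with a likelihood-ratio test, and `rank_sum_test()` covers the diet
specialization check.

## Worked example

```r
library(beehab)

cfg <- pipeline_config(scenario = scenario_config(seed = 1),
                       n_sim = 1000, seed = 1)
report <- run_pipeline(cfg)
report
```

```
beehab pipeline report
  species analysed: 150 
  allometry: slope = 2.359  lambda = 0.364  R2 = 0.891 
  occupancy classes (species per habitat):
               low intermediate high
  natural       75           12   63
  agricultural  84            9   57
  urban         90            9   51
  occupancy ~ relative brain size (beta1 per habitat):
    natural       beta1 =   -0.629 (se 0.825, sigma2 0.000)
    agricultural  beta1 =   -1.153 (se 0.906, sigma2 0.322)
    urban         beta1 =    3.403 (se 0.986, sigma2 0.000)
```

The default scenario couples each species' allometric residual to its urban
log-odds with strength `gamma = 1.5`, so the fitted urban slope is positive
(species with relatively larger brains occupy urban habitat more than the
fixed-margin null expects) while the natural and agricultural slopes are
negative — the same qualitative contrast the method is designed to detect.
The allometric slope and R² recover the generator's allometry
(`slope = 2.5`, strong fit), and `lambda` is the estimated phylogenetic
signal of the residuals.

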