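# sdsnet

Contact networks and Bayesian dyadic models for proximity-sensor
experiments.

`sdsnet` is for researchers who test behavioral interventions on physical
distancing by instrumenting visitors of an event with wearable
ultra-wideband sensors. Every time two sensors come within 1.5 m a
violation is logged — by *both* devices, so each contact reaches the
database twice. The package takes the raw directed logs, the sensor handout
registry and the experimental condition schedule, and produces:

1. **clean unordered-pair contacts** per condition (window filtering,
   sensor-to-visitor linkage, removal of unregistered-sensor, self and
   household-pair records, collapse of the double-logged records);
2. **undirected binary contact networks** over the full visitor roster —
   zero-contact visitors are re-added as isolates — with degree-distribution
   descriptives (range, mean ± SD, median, IQR);
3. **b2 model fits** comparing two conditions, reported as posterior-mean
   odds ratios with 95% credible intervals.

## The b2 model

For dyad (i, j) in network k, with Y_kij = 1 if the visitors ever came
within 1.5 m:

    P(Y_kij = 1) = exp(mu_kij) / (1 + exp(mu_kij))
    mu_kij = m + Xa_kij * beta_a + A_ki + A_kj
    A_ki ~ N(0, sigma_A^2)

This is the undirected reduction of the multilevel p2 model: reciprocity,
dyadic predictors and network-level random effects are omitted, and sender
and receiver effects are identical (`A`). The actor-level dummy `x` is 0 in
the reference condition and 1 in the comparison condition; under the
default actor-additive coding `Xa_kij = x_i + x_j`, so `exp(beta_a)` is the
per-actor odds ratio of contact formation (a dyad-indicator coding is
available as a config switch). Estimation is adaptive
Metropolis-within-Gibbs MCMC with a conjugate scaled inverse-chi-squared
update for `sigma_A^2`; priors are weakly informative normals (variance
100) on `m` and `beta_a` and scaled inverse-chi-squared (nu0 = 1, s0^2 = 1)
on `sigma_A^2`.

A synthetic-data generator emulates the sensor-log format *and its
measurement artifacts* (double logging, stray records from sensors never
handed out, suppressed household pairs, zero-contact visitors absent from
the log) so the whole pipeline is testable end to end without any deposited
data.

## Worked example

Generate a synthetic six-condition study, preprocess it, and compare the
unidirectional-walking buzzer condition (5) with the free-walking buzzer
condition (6):

```r
library(sdsnet)
dir <- file.path(tempdir(), "demo")
make_study_fixture(dir, seed = 42)

cfg <- default_config(dir, file.path(dir, "out"))
cfg$sampler <- list(n_chains = 2, n_iter = 8000, burn_in = 2000,
                    thin = 4, seed = 42)

pre <- run_preprocess(cfg)
run_describe(cfg, pre)
#>   condition duration_min   n min max  mean   sd median q1 q3
#> 1         1          120 130   0  35  8.34 5.89      7  4 11
#> 2         2          120 137   0  54  8.63 6.65      7  4 11
#> 3         3          120 122   1  31 11.31 6.71      9  6 16
#> 4         4          120 147   0  56 11.13 8.67      9  5 15
#> 5         5          120 137   0  31  6.64 5.62      5  3  8
#> 6         6          120 123   1  56 13.74 9.09     12  7 17

run_compare(cfg, list(label = "unidirectional_vs_no_direction",
                      reference = "5", comparison = "6"), preprocess = pre)
#> b2 comparison: unidirectional_vs_no_direction (condition 5 vs 6)
#>   OR = 1.677, 95% CI [1.392, 2.011]  (actor_additive coding)
#>   260 actors, 16819 dyads
#>   chains 2 x 8000 (burn-in 2000, thin 4), seed 42
#>   max split-Rhat 1.0266, min ESS 71
#>   config 30274ab17f623b1a12c012946e975b3a, sdsnet 0.1.0
```

Each descriptives row summarises one condition's degree distribution
(number of unique <1.5 m contacts per visitor, isolates included). The
comparison report says the odds of forming a contact are about 1.7 times
higher per actor without walking directions than with unidirectional ones —
the generator planted a per-actor OR of 1.66 for this contrast, so the CI
covering it is exactly what a sound fit should produce. The report embeds
seed, config hash and package version; rerunning with the same config and
seed reproduces it bit for bit.

A thin command-line wrapper with `simulate`, `preprocess`, `describe`,
`compare` and `all` subcommands lives at `inst/cli/sdsnet.R`.

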