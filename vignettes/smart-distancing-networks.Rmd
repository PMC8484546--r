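---
title: "From raw proximity-sensor logs to dyadic network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw proximity-sensor logs to dyadic network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdsnet)
options(sdsnet.verbose = FALSE)
```

## The measurement problem

Wearable ultra-wideband sensors make physical-distancing behavior directly
observable: whenever two sensors come within 1.5 m, both devices count a
violation and report it to an access point, so every contact is written to
the central database **twice** — once per reporting sensor. The raw log is
therefore a stream of *directed* records (reporting ID, opposing ID,
violation count, registration time) that must be cleaned before any
network can be built:

* records outside an experimental condition's time window are discarded.
  Windows are **half-open**, `[start, end)`, so a record at the exact
  boundary between back-to-back conditions is counted once, in the later
  condition;
* a record is kept only if **both** sensors can be linked to a visitor via
  the handout registry for that condition. Unlinkable sensors occur in
  practice (a sensor auto-activates when lifted off its charger without
  being handed out), so they are a *drop reason*, counted in the cleaning
  report, not an error. Self-records and records between two sensors
  registered to the same household (the hardware pairs those sensors so
  they should never log each other, but the pipeline must tolerate dirty
  logs) are dropped likewise;
* the surviving directed records are collapsed per unordered visitor pair.
  The two directions may carry different counts if one sensor synced late,
  and no reconciliation rule is documented for the original system, so
  `symmetrize()` **sums** the counts; nothing downstream depends on the
  choice because the analyzed networks are binary (an edge needs only
  `total_events >= 1`);
* visitors whose sensors logged nothing never appear in the output, so the
  roster is rebuilt from the registry and zero-contact visitors re-enter
  the network as isolates. Degree-0 actors are part of the degree
  distribution, not missing data.

Condition membership is taken from the registry's condition label; handout
and return times are carried along as metadata but do not truncate roster
membership (no rule for mid-condition returns is documented for the
original system, and inventing one would silently change degree-0 counts).

Cleaning is idempotent — re-running `link_and_clean()` on its own output
removes nothing — and the package treats a visitor who stayed for several
conditions as a distinct actor in each condition's network, consistent
with fitting per-condition networks (the residual dependence this induces
is a limitation, discussed below).

## Degree descriptives

Contacts are collapsed over time: within a two-hour condition only primary
transmissions are possible, so the epidemiologically relevant quantity is
the number of *unique* contacts per visitor, i.e. the degree distribution
of the binary undirected network. `degree_summary()` reports n, range,
mean ± SD, median and quartiles over the full roster.

Published tables in this area give integer IQR bounds without naming the
quantile estimator. `degree_summary()` defaults to the linear-interpolation
estimator (`stats::quantile()` type 7, R's default) and exposes the
nearest-rank estimator (type 1) via `quantile_method` in the pipeline
config; replicating someone else's integer quartiles may require toggling.

## The b2 model

For dyad $(i, j)$ in network $k$:

$$\Pr(Y_{kij} = 1) = \frac{\exp(\mu_{kij})}{1 + \exp(\mu_{kij})}, \qquad
\mu_{kij} = m + Xa_{kij}\,\beta_a + A_{ki} + A_{kj}, \qquad
A_{ki} \sim N(0, \sigma_A^2).$$

This is the undirected ("bidirectional") reduction of the multilevel p2
model for directed networks: reciprocity parameters, dyadic predictors and
network-level random effects are omitted, and the sender and receiver
effects are constrained to be identical, leaving a single heterogeneity
term per actor. The actor random effects are what distinguish the model
from an ordinary logistic regression on dyads: a few gregarious visitors
generate many edges, and ignoring that overdispersion understates the
uncertainty of the condition effect.

### Covariate coding

Both members of a within-network dyad share the same condition, so the
actor dummy ($x = 0$ reference, $1$ comparison) enters the dyad either as

* `actor_additive` (default): $Xa = x_i + x_j \in \{0, 2\}$, making
  $\exp(\beta_a)$ the **per-actor** odds ratio — the factor by which one
  visitor's odds of forming any given contact change under the
  intervention; or
* `dyad_indicator`: $Xa \in \{0, 1\}$, making $\exp(\beta_a)$ the
  **per-dyad** odds ratio, the square of the former.

The two codings are collinear here (they differ by a factor 2 on
$\beta_a$), so the choice is one of reporting scale. The default follows
the "probability of visitors forming contacts" reading; when validating
against externally published odds ratios, check both scales, since a
report rarely states which one was used.

### Priors

Exact prior choices for this model family are conventionally weakly
informative on the logit scale, and that is what `b2_priors()` defaults
to: $m, \beta_a \sim N(0, 100)$ and $\sigma_A^2 \sim$ scaled
inverse-$\chi^2(\nu_0 = 1, s_0^2 = 1)$. On the logit scale an SD of 10 is
far flatter than any plausible contact propensity, and the
inverse-$\chi^2$ scale 1 keeps the heterogeneity prior proper while
placing its mass over the 0.1–2 range typical of actor variances in p2-type
fits. All are configurable; `b2_priors(flat = TRUE)` gives the improper
flat configuration used to check the sampler against maximum-likelihood
limits.

### Sampler

`fit_b2_mcmc()` runs Metropolis-within-Gibbs:

* scalar random-walk Metropolis updates for $m$, each $\beta_a$ and each
  $A_{ki}$ (only the incident dyads are touched, so an actor update costs
  its degree, not the full dyad count);
* a conjugate Gibbs draw for $\sigma_A^2$ from its scaled
  inverse-$\chi^2(\nu_0 + N, (\nu_0 s_0^2 + \sum A^2)/(\nu_0 + N))$ full
  conditional;
* a **joint translation move**: propose $c \sim N(0, s_c)$ and move
  $A \to A - c$, $m \to m + 2c$. Every linear predictor is unchanged, so
  the move is accepted on the prior ratio alone. This is the device that
  breaks the strong posterior correlation between $m$ and the mean of the
  random effects. A deterministic re-centering (subtracting
  $\bar A$ each sweep) would look similar but is a singular projection
  that changes the sampled distribution; the translation *move* achieves
  the same decorrelation while leaving the posterior exactly invariant,
  which matters because the test suite compares the sampler against exact
  quadrature;
* proposal scales adapt in batches of 50 towards 44% acceptance during
  burn-in **only** and are frozen afterwards, so the post-burn-in kernel
  satisfies detailed balance.

Initialization: $m$ at the logit of the pooled density (clamped away from
0/1), $\beta_a = 0$, $A = 0$, $\sigma_A^2 = 0.5$; chains after the first
jitter their start by $N(0, 0.25)$. A non-finite log-posterior at the
start aborts with an explicit error. The Bernoulli log-likelihood is
evaluated as $y\mu - \log(1+e^{\mu})$ in `log1p` form on the appropriate
branch, finite for $|\mu|$ into the hundreds. Defaults are 2 chains of
40,000 iterations, 10,000 burn-in, thin 10. Given `seed`, the entire fit
is bit-reproducible.

The reported effect is the posterior **mean of** $\exp(\beta_a)$ with an
equal-tailed 95% credible interval from the empirical 2.5/97.5 percentiles
of the $\exp(\beta_a)$ draws. Convergence is monitored with split-$\hat R$
(threshold 1.1) and a variogram-based effective sample size; pipeline
reports carry both, and `run_compare()` flags any scalar parameter above
threshold. `sigma_A2` mixes the slowest of the scalars; its ESS is the one
to watch in short runs.

## What the synthetic generator does and does not emulate

`simulate_b2_network()` draws networks exactly from the b2 model;
`simulate_sds_log()` then manufactures the raw measurement layer:

* each true edge emits $1 + \mathrm{Geometric}(0.5)$ violation events
  (configurable); real per-pair event counts are unknown, and a
  heavy-ish-tailed count with minimum 1 is the simplest shape consistent
  with "logged at least once, often several times";
* each event is written as **two** directed records with
  `violation_count = 1` and independent timestamps uniform in the window
  (the framework collapses time, so no movement model is attempted). This
  makes the double-logging invariant exact: directed records = 2 × events
  over non-household edges;
* household pairs are registered, and their records are suppressed *at
  source*, as the paired hardware does; if a censored pair had a true
  edge, that edge is recorded in the emitted ground truth so round-trip
  tests can condition on it;
* a configurable number of records from sensors absent from the registry
  is injected, and isolates arise naturally as degree-0 actors.

`make_study_fixture()` assembles a full six-condition study: rosters of
130/137/122/147/137/123 sensors, 120-minute windows over three days with
walking direction varying across days and the supplementary intervention
within days, $\sigma_A^2 = 0.5$, and per-condition baseline logits placed
so that the five standard pairwise contrasts have known per-actor odds
ratios (1.05, 1.66, 0.99, 1.24, 1.43). The baseline logit of −2.955 was
solved numerically so that the *marginal* density — after integrating the
actor effects out of the logistic — gives a mean degree near 10 at
n = 137, the scale seen in instrumented indoor events; with
$\sigma_A^2 = 0.5$ the resulting degree SDs are of the same order as the
means, i.e. realistically overdispersed.

Not emulated: spatial movement and venue layout (timestamps are
exchangeable within a window), time-of-day effects, visitors returning in
later conditions (every condition gets fresh actors), sensor dropout and
clock skew, and count heterogeneity between the two directions of a
record. Passing the round-trip tests therefore shows the *pipeline logic*
is lossless and the *sampler* is calibrated under the model's own
data-generating process — it cannot show that the b2 model is adequate for
any particular real deployment.

## Verification strategy and problem sizes

The test suite checks the sampler against independent routes, at sizes
chosen to keep a full run in a few minutes on one core:

* exact quadrature of the posterior of $m$ on a 4-actor network
  ($\sigma_A^2$ fixed; grid 0.1 over $m$, 0.5 over each $A$) versus the
  MCMC mean, within 3 Monte-Carlo SEs;
* with heterogeneity disabled and flat priors, the posterior mode from
  `b2_map()` versus `glm()` on the dyad table;
* the analytic value $-d \log 2$ at all-zero parameters;
* null calibration: 200 replicates at 60 actors/network, $\beta_a = 0$,
  single reduced chains — the 95% CI for the OR must cover 1 at the
  nominal rate (±4 points);
* effect recovery: 20 replicates at 130 actors/network,
  $\beta_a = \log 1.5$, $\sigma_A^2 = 0.5$ — the mean posterior-mean OR
  must land within 15% of 1.5;
* full ingest round trips on seeded fixtures, including injected
  unregistered-sensor, self and household records, all of which must be
  removed and counted.

`scripts/acceptance.R` runs the study-scale pipeline (six conditions,
102–147 actors each, five comparisons at the default 2 × 40,000-iteration
chains) and writes every computed headline quantity as JSON.

## Known limitations

* Repeat visitors are independent actors per condition; if many visitors
  span conditions, the two compared networks are not independent and the
  credible intervals are mildly optimistic.
* Only two-network contrasts with a single dummy are first-class;
  `beta_a` is a vector internally, but multi-network (>2) designs are out
  of scope.
* No reciprocity, dyadic covariates or network-level effects — by design,
  this is the reduced undirected model.
* The quantile convention behind externally published integer IQRs is
  ambiguous; both estimators are provided but the default may not match a
  given publication.
* MCMC cost grows with the dyad count, i.e. quadratically in the roster;
  at a few hundred actors per network the defaults run in minutes, but
  much larger venues would want shorter chains or a sparser design.
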