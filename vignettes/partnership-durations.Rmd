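---
title: "Estimating partnership durations and homophily from categorical survey counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating partnership durations and homophily from categorical survey counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmnet)
```

## The problem

Dynamic network models of sexually transmitted infections among men who
have sex with men (MSM) need two kinds of social parameters that surveys do
not measure directly: how long partnerships of different kinds last, and
how strongly high-activity (HA) and low-activity (LA) men mix within their
own group (homophily). Behavioural surveys such as EMIS-2017 report the
number of partners in the last 12 months only as censored categories
(steady partners: 0, 1, ..., 9, "10+"; casual partners: 0, ..., 10,
"11-20", "21-30", "31-40", "41-50", ">50") and say nothing about durations.

`msmnet` estimates durations and homophily indirectly: reconstruct integer
partner counts from the categorical responses, summarise them as
calibration targets, and tune a daily three-layer partnership network
simulator until its simulated cumulative 12-month partner distributions
match those targets. The estimation is likelihood-free (adaptive ABC-SMC).
Because the survey microdata are access-restricted, the package ships a
synthetic survey generator with known ground truth, so every stage is
testable end to end.

## Activity groups

Three alternative HA definitions are supported, with population shares
34.6%, 30.41% and 27.90%:

* **PrEP eligibility**: HIV-negative adult with at least one of -- two or
  more condomless anal partners in 6 months, two or more STIs in 12
  months, two or more PEP courses in 12 months, or chemsex. The source
  criteria say "multiple" STIs/PEP uses; we read *multiple* as a count of
  at least 2, a single documented knob.
* **> 15 total partners / 12 months** on the reconstructed counts
  (a count of exactly 15 is LA -- the boundary is strict).
* **> 15 casual partners / 12 months**, likewise.

## Count reconstruction

`assign_integer_counts()` turns categorical responses into integers whose
summary statistics match published targets (`category_targets()`): overall
mean 15.8, SD 36.60, median 5, IQR 2-15, and per-category means/SDs for the
interval categories (16.4/3.30, 27.8/2.80, 38.6/2.40, 49.6/1.50,
128.2/98.10). Each iteration:

1. respondents reporting "10+" steady partners are reassigned uniformly to
   10, 11 or 12 (steady counts are capped at 12/year);
2. casual counts reported exactly (<= 10) give exact totals;
3. interval casual categories define a feasible total range
   `[steady + lo, steady + hi]`; if it spans two grid categories one is
   picked with probability proportional to the integer overlap
   (`resolve_total_category()`); an integer total is then drawn from a
   discretised normal on the feasible window with the assigned category's
   target mean and SD;
4. the absolute error sum -- |overall mean error| + |overall median error|
   + the sum of per-category mean errors -- is evaluated, and iteration
   stops below 1.5 (the algorithm keeps the best draw seen).

Numerical choices worth recording:

* **Error-sum composition.** The source method states the threshold (1.5)
  but not the error composition; we sum the overall mean and median errors
  with the per-category mean errors, the statistics the target table
  actually reports. Per-category statistics are computed over respondents
  whose totals were *drawn*, grouped by assigned total category; exact
  totals (casual <= 10) cannot be adjusted by the algorithm and enter the
  overall statistics only.
* **Moment-matched truncated draws.** Truncating a normal to a category
  window shifts its mean, so the location parameter is re-solved so the
  truncated mean equals the target (`dtnorm_pmf()`). Windows narrowed by a
  large steady count (e.g. totals 21-22 for a respondent bumped from
  "11-20" into "21-30") may make the target unattainable; the draw targets
  for the remaining, unclamped windows are then adjusted so the category's
  expected mean stays on target.
* **">50" cap.** The open-ended category is capped at 300 partners/year
  (configurable); the printed target (mean 128.2, SD 98.1) needs wide
  support, and a cap keeps it finite.
* **Rounding and quantiles.** `split_casual()` rounds half to even (base R
  `round()`); all quantiles, for targets and simulated summaries alike,
  use the linear-interpolation definition (R type 7).

One-off partners are `round(casual x one-off fraction)` per respondent,
the remainder persistent casual. The group x type medians and IQRs of the
reconstructed steady / persistent-casual / one-off counts
(`target_summaries()`) are the calibration targets.

## The synthetic survey generator

`generate_survey()` emulates the survey the reconstruction was designed
for; it is a stand-in for restricted microdata, with latent integer counts
retained as ground truth. Latent casual counts follow a two-component
negative-binomial mixture -- a low-activity bulk and a heavy tail. Three
quantities are solved at configuration time (deterministically, from the
declared targets, not fitted to any test outcome):

* the tail weight, so that the expected HA share under the configured
  scenario -- measured on *reconstructed* counts, the way classification is
  defined -- equals the scenario target;
* the tail mean, so that the expected overall reconstructed mean is 15.8;
* the bulk mean, so that the overall median sits at 5 with
  `P(total <= 4)` centred half the mass of {5} below one half, making
  both median-flip directions equally unlikely in a finite sample.

Steady counts use a fixed thin-tailed distribution (most respondents 0 or
1 steady partners/year). PrEP-rule fields are generated consistently with
a latent eligibility status whose probability increases with total partner
count and whose intercept is solved so the expected eligible share equals
34.6%; rule-based classification therefore recovers the latent status
exactly for HIV-negative adults. HIV-positive respondents (7%) and minors
(1.5%) exercise the negative clauses of the rule.

What the generator does **not** emulate: recruitment bias of dating-app
sampling, survey weighting, item non-response, country heterogeneity, and
any real dependence structure beyond a configurable Gaussian-copula
coupling between ongoing steady and casual status (default independent)
-- the joint distributions the original survey would supply are not
published, so these defaults are synthetic stand-ins (notably the one-off
fraction of 0.5). Passing tests therefore demonstrate the *machinery* on a
population consistent with the published marginals, not fidelity to the
restricted microdata.

## The network model

`simulate_network()` advances three overlapping partnership layers --
steady, persistent casual, one-off -- in daily steps over a two-group
population (`population()`, HA share per scenario).

**Formation is target-driven.** The source framework fits separable
temporal ERGMs whose role is to hold network statistics constant over
time; the published quantities are those statistics, not ERGM
coefficients. We therefore replace likelihood-based STERGM estimation with
a stochastic formation algorithm that holds the same statistics at target
in expectation: per-layer edge counts, group-pair composition (HA-HA,
LA-LA, HA-LA) implied by the two homophily rates (`pair_mix()`),
concurrency (share of nodes with 0/1/>1 partners in the layer, enforced
by rejecting candidate pairs that would push the distribution more than 2
percentage points past target), and cross-layer status mix (formation
weights by the candidate's degree class in the other layer; neutral by
default since the source's tables for them are unpublished). Dissolved
edges are replaced so that counts are stationary -- the expected number of
new edges per day equals target x hazard, the birth-death equilibrium
identity.

**Dissolution is memoryless.** Steady and casual partnerships end each day
with probability 1/duration (`duration_to_hazard()`); lifetimes are
geometric with the configured mean. The steady hazard is global; the
casual hazard is keyed on the unordered group pair {HA,HA}, {LA,LA},
{HA,LA}. One-off partnerships last exactly one day.

**Initialisation is stationary.** Layers start at their target counts and
composition with edge ages drawn from the geometric stationary age
distribution (by memorylessness, age and residual lifetime are
independent), so a 12-month measurement window can start immediately;
whether the source burned in its networks is unstated, and this is our
choice.

**Sex acts.** Each surviving partnership has a daily Bernoulli sex act
with a layer x group-pair probability; acts are assigned one of the
combinations of six sex types (oral, oro-anal, anal; insertive/receptive)
from a frequency table. The default probabilities and frequencies are
synthetic stand-ins (the source's tables are unpublished) and the whole
stage can be disabled; it does not feed the calibration summaries.

`measure_cumulative_partners()` counts distinct partners per node, layer
and window (a re-formed partnership with the same partner counts once) and
summarises them per group with the shared quantile convention.

## Homophily balance

With homophily operationalised as the share of a group's partnerships that
are within-group, cross-group partnership conservation -- every HA-LA
partnership is one HA person's LA-partnership and one LA person's
HA-partnership -- ties the two rates together:

h_LA = 1 - (n_HA d_HA / (n_LA d_LA)) (1 - h_HA).

`la_homophily()` implements this and treats a negative result as an error:
the requested HA rate is infeasible for the given sizes and degrees. The
degrees may be momentary mean degrees (our default use) or cumulative
12-month counts -- the algebra is identical, and both interpretations are
supported by simply passing the corresponding degrees. Only the HA rates
are calibrated; the LA rates are derived, per particle, through this
identity.

## Calibration

`abc_smc()` implements an adaptive ABC population Monte Carlo scheme: an
initial generation of `n/alpha` prior draws, of which the best `n` (by
distance) survive; each later generation perturbs weighted ancestors with
a component-wise normal kernel (variance twice the weighted empirical
variance, truncated to the prior box by resampling), re-simulates, merges
and keeps the best `n`; sampling stops when the share of new particles
beating the previous distance threshold drops below `p_acc_min`. Choices:

* **Distance**: normalised L1 over the group x type x {median, q1, q3}
  cells, `sum(|sim - target| / max(target, 1))` -- scale-balances steady
  counts (medians of 0-1) against one-off counts (tens).
* **Defaults**: alpha = 0.5, `p_acc_min` = 0.05, 100 particles, 2 network
  replicates averaged per particle -- desk-scale values in the spirit of
  the defaults of common ABC-SMC implementations. A generation cap bounds
  the run when the acceptance proportion plateaus above `p_acc_min`
  (replicate noise keeps it there): 10 generations for the recovery
  experiment, 5 in the pipeline profile.
* **Weights**: importance weights of the whole retained set are recomputed
  against the previous generation's perturbation mixture each generation
  (uniform priors make the numerator constant). Recomputing all weights,
  rather than carrying old weights forward, keeps the weight scales of old
  and new particles comparable.
* **Infeasible mixing**: parameter vectors whose HA homophily implies a
  negative LA rate return an infinite distance rather than an error --
  such mixings cannot exist in a closed population, so they receive zero
  posterior support. This matters in practice: with strongly skewed
  one-off activity the balance identity rules out low one-off homophily,
  and this truncation is the main information the data carry about it.
* **Priors** (`prior_spec()`): uniform, per scenario -- steady duration
  U(800, 2000) days; casual HA-HA U(4, 15) (PrEP) or U(3, 100); casual
  LA-LA U(15, 500); casual mixed U(10, 30) (PrEP) or U(5, 100); homophily
  steady U(0.55, 1), casual U(0.45, 1) (U(0.60, 1) under >15-total),
  one-off U(0.45, 1).

### What is and is not identified

The calibration summaries are per-group quantiles of cumulative partner
counts, so parameters are informed only through turnover and group
composition. Casual durations and casual homophily are strongly
identified (pair-type turnover differs by an order of magnitude). The
steady duration and steady homophily are weakly identified: yearly steady
counts are small integers and the steady hazard is pair-independent, so
their posteriors remain close to the prior. One-off homophily does not
affect per-group one-off counts at all (all one-off pair types last one
day); it is only set-identified through the feasibility truncation above.
The recovery experiment (`recovery_experiment()`, stage 5 of the analysis)
checks recovery in exactly these terms: at least 6 of the 7 posterior
means within 25% of truth and at least 6 of 7 credible intervals covering
it -- allowing one miss for a boundary or set-identified parameter --
rather than demanding sharp recovery of parameters the summaries cannot
sharply inform.

## Problem sizes

Desk-scale defaults keep every stage runnable on one CPU in minutes: 2763
synthetic respondents (the survey's size), 1000-node networks over 365
days, 100 particles, 2 replicates (roughly 1200-2400 network simulations
per calibration). The published analyses use 10,000 nodes; the population size
is a configuration switch (`run_config(n_nodes = 10000)`), and all
formation targets scale linearly with it.

## Limitations

* The generator's unpublished joint distributions (partnership-status
  combinations, sex-type frequencies, one-off fraction) are synthetic
  defaults, clearly marked; conclusions about the restricted microdata
  require the microdata.
* The target-driven formation holds statistics at target in expectation
  but is not an ERGM: higher-order network structure (clustering, degree
  correlations beyond the controlled classes) is emergent, not matched.
* STI transmission, condom use and risk perception are out of scope.
* The concurrency band (2 percentage points) is enforced approximately
  within a day's formation batch.
* Posterior CIs for boundary truths (a duration at its prior bound) cannot
  cover them from one side; the recovery criterion allows for this.
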