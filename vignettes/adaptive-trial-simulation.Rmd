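---
title: "Simulating operating characteristics of an event-triggered adaptive trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating operating characteristics of an event-triggered adaptive trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(adaptsim)
```

## The design problem

Before running an adaptive trial, its frequentist operating
characteristics — type I error, power, the probability of stopping early,
the expected sample size, and the probability of a misleading early stop —
must be established under the planned adaptation rules. For all but the
simplest designs these have no convenient closed form, so they are
estimated by Monte-Carlo simulation: generate many complete trials under a
known truth, apply the planned analysis and decision rules to each, and
average the indicators of interest.

`adaptsim` implements this for a two-arm, parallel-group trial with a
binary primary outcome and a single *event-triggered* interim analysis:
the interim look happens when a pre-specified cumulative number of
outcome events has accrued, not at a calendar date. The worked example
throughout is the PIMS trial of intravenous fluid composition in
children, whose primary outcome is hyponatraemia (serum sodium
< 135 mmol/L with a fall of ≥ 3 mmol/L) by 72 hours, re-designed with one
interim analysis.

## The simulated trial, block by block

A single simulated trial is built from five composable pieces, each an
exported function:

1. **Randomisation** (`simulate_randomisation`): permuted-block
   randomisation. Whole blocks of `block_size` containing the per-arm
   `allocation` counts are permuted uniformly at random, so arm totals
   are exactly balanced at the end of every complete block. The
   permutation is implemented by ordering uniform random keys within each
   block, which is distributionally identical to any correct shuffle.
   When `n` is not a multiple of the block size, the tail is a freshly
   permuted block truncated to length — a choice the balanced worked
   example never exercises, made explicit here.
2. **Accrual** (`simulate_accrual`): recruitment is uniform over
   `recruit_period` days; the accrual times are the order statistics of
   `n` independent Uniform(0, `recruit_period`) draws. Real recruitment
   ramps up and down and varies by site; a `generator` hook accepts any
   replacement accrual law, but only the uniform generator ships.
3. **Outcomes** (`simulate_trial_data`): each participant's event is an
   independent Bernoulli draw with probability `p0` (control) or `p1`
   (treatment), available immediately at accrual — zero outcome lag.
   Loss to follow-up and missing outcomes are deliberately not modelled.
4. **Interim selection** (`select_interim`): the running event total is
   computed over participants in accrual order; the participant at whom
   the `events_at_interim`-th event accrues closes the interim dataset
   (that participant included). With zero outcome lag, interim outcomes
   equal final outcomes for everyone in the interim dataset. If a
   simulated trial never accumulates enough events the interim is
   skipped: interim statistics are recorded as missing and only the
   final analysis can stop the trial. Under the default scenarios at
   least 20 events are all but certain, so this branch is a guard, not a
   behaviour the defaults exercise.
5. **Analysis and decisions** (`fit_binary_logistic`,
   `evaluate_decisions`, `analyse_trial`): the treatment effect is the
   odds ratio from a logistic regression of outcome on the treatment
   indicator. With a single binary covariate the maximum-likelihood fit
   is closed-form in the 2×2 table —
   log OR = log(ad/bc), SE = √(1/a + 1/b + 1/c + 1/d) — and the Wald
   z gives the two-sided p-value and the confidence interval, identically
   to a `glm` summary but orders of magnitude faster across thousands of
   replications (the test suite holds the two routes to 1e-6 agreement).
   Efficacy is declared if the p-value falls **strictly below** the
   threshold: `alpha_interim` (0.005) at the interim, `alpha_final`
   (0.045) at the final analysis. We note the source design description
   is ambiguous between strict and non-strict comparison at the final
   analysis; with continuous p-values the boundary event has probability
   zero, so the operating characteristics are unaffected either way.

Both analyses are always computed, even for trials that would have
stopped at the interim. Early stopping is applied in post-processing,
which is what makes the *flip-flop* probability — interim threshold met
but final threshold not met on the complete data — measurable for every
trial.

### Degenerate analyses

A 2×2 table with a zero cell corresponds to a separated logistic fit: the
Wald statistic degenerates and an IRLS fit would report an enormous
standard error and p ≈ 1. The closed form makes that explicit: the
estimate is flagged `degenerate`, the p-value set to 1, and no finite
odds ratio or interval is reported. A degenerate analysis therefore never
stops a trial, and degenerate odds ratios are excluded (with a reported
count) from summary means. A fully empty arm is an error instead — no
comparative analysis exists.

## Reproducible replication

`run_trial(design, scenario, seed)` is a pure function of its arguments:
the seed initialises the stream, and the three random components are
consumed in a fixed, documented order (allocation, accrual, outcomes).
`simulate_trials()` derives one seed per trial from the master seed via a
single seeded `sample.int()` draw, so any trial of a run can be replayed
in isolation from its recorded seed, and the results are independent of
the order (or chunking) in which trials are executed.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n` | 584 | maximum sample size (292 per arm), from the analytic calculation below |
| `recruit_period` | 928 days | uniform recruitment window |
| `block_size`, `allocation` | 4, (2, 2) | permuted blocks, 1:1 allocation |
| `events_at_interim` | 20 | event count triggering the interim (about half the expected events) |
| `alpha_interim` | 0.005 | interim efficacy threshold |
| `alpha_final` | 0.045 | final efficacy threshold |
| `ci_level` | 0.95 | confidence level for interval estimates |

The thresholds split the overall alpha between the two looks
(0.005 + 0.045, a simple fixed spending scheme); the final threshold
matches the significance level of the fixed-design sample-size
calculation. The confidence level is fixed at 95% by convention — the
source tables report 95% intervals without stating the level.

The default scenarios fix `p0 = 0.10` and vary the treatment arm:

```{r}
do.call(rbind, lapply(pims_scenarios(), as.data.frame))
```

## The analytic design calculation

The maximum sample size comes from the pooled-variance ("chi-square")
two-proportion formula

$$ n/\text{arm} = \left\lceil \frac{\left(z_{1-\alpha/2}\sqrt{2\bar p\bar q}
 + z_{1-\beta}\sqrt{p_0q_0 + p_1q_1}\right)^2}{(p_0-p_1)^2}\right\rceil,
 \qquad \bar p = \tfrac{p_0+p_1}{2},$$

which gives 292 per arm (584 total) at
(p₀ = 0.10, p₁ = 0.04, α = 0.045 two-sided, 80% power) — a 6% absolute
risk difference, odds ratio 0.375. The pooled-variance form is used
because it corresponds to the Pearson chi-square test;
`stats::power.prop.test()` uses an unpooled variance and lands slightly
elsewhere. The Fleiss continuity correction is available
(`continuity_correction = TRUE`); applied to the real-valued solution
before the ceiling it yields 316 per arm at a two-sided α of 0.05, which
the test suite cross-checks against an exact enumeration of the
continuity-corrected chi-square test's power. Commercial software that
applies its own rounding conventions to the corrected formula can give
nearby but not identical values; no attempt is made to be bit-compatible
with any of them.

```{r}
two_proportion_n(0.10, 0.04, alpha = 0.045, power = 0.80)
odds_ratio_from_props(0.10, 0.04)
```

## A complete run

```{r}
sims <- simulate_trials(pims_design(), pims_scenarios()[["As powered"]],
                        n_sims = 200, seed = 1, log_every = 0)
sims
```

`summary(sims)` adds the six-number summary (minimum, quartiles, median,
mean, maximum) of every per-trial result variable; `extract_oc(sims)`
returns the operating characteristics as one row, and `scenario_grid()`
stacks one such row per scenario from independently seeded runs. The
mean of `stop` estimates the type I error under the null scenario and
the power elsewhere; the mean of `sample_size` (interim index for trials
that stopped early, `n` otherwise) estimates the expected sample size.

This vignette keeps `n_sims` small so it renders quickly; the package's
acceptance script and test suite run the full 5,000 replications per
scenario used for the reference results, which take well under a minute
per scenario. Monte-Carlo standard errors scale as
$\sqrt{p(1-p)/n_\text{sims}}$ — at 5,000 replications a proportion near
0.05 carries an SE of about 0.003.

## Numerical and design choices

* **Quartiles** use linear interpolation of order statistics
  (`quantile()` type 7). Implementations differ in quantile conventions;
  the differences are O(1/n_sims) and immaterial at 5,000 replications.
* **Indicator variables** (`interim_stop`, `stop`, `flipflop`) are
  summarised with all six statistics, although only their mean is
  interpretable, to keep one fixed table schema.
* **Missing values** (interim statistics of trials whose trigger was
  never reached; degenerate odds ratios) are excluded from summaries
  with an explicit exclusion count, never silently dropped.
* **Allocation is expressed as per-block counts**, not a ratio, so
  non-1:1 designs are representable without changing the block logic.
* **Ties in accrual times** have probability zero under continuous
  sampling; if a custom generator produces them, order among tied values
  follows draw order.
* **Extension points, not features**: outcome lag, multiple interims,
  calendar- or accrual-count-triggered interims, futility rules and
  non-uniform accrual are documented hooks or straightforward
  modifications, deliberately left out of scope, as are stratified
  randomisation and covariate-adjusted analyses.

## What the simulations do and do not show

The generator emulates the idealised design: constant accrual,
immediately observed outcomes, no loss to follow-up, no stratification,
independent Bernoulli outcomes with arm-specific constant probabilities.
Passing the reproduction tests shows the machinery is faithful to that
model — not that a real trial will behave this way. Real recruitment is
lumpy, outcomes lag, event probabilities drift, and data are incomplete;
operating characteristics under those violations require extending the
generator, which the block structure is designed to make easy.
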