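---
title: "Personalized trigger rules for a social-support JITAI: models, engine and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized trigger rules for a social-support JITAI: models, engine and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jitaisim)
library(dplyr)
```

## The problem

Just-in-time adaptive interventions (JITAIs) deliver brief mobile
interventions at algorithmically chosen moments. For a social-support JITAI
the decision problem is: given a stream of ecological momentary assessment
(EMA) reports — here six prompts per day over 21 days, each with four
distress items (negative affect, stress, loneliness, rumination, all on a
1–7 Likert scale) and a trinary momentary support-need item — when should
the phone prompt the person to activate their support network?

`jitaisim` implements the computational core of a microrandomized
feasibility design around this question: at every completed EMA in the
intervention phase the person is randomized to one of four triggering
conditions, the condition's criterion is evaluated in real time, and a
delivery happens only if the criterion is met and fewer than two
interventions were already delivered that day. The three active rules are

* **fixed cutoff** — any distress item $\geq 5$ (disjunctive, non-strict);
* **SPC** — any distress item strictly above its personalized upper control
  limit (below);
* **support need** — the person answered *yes* to "would it help you right
  now to talk to someone?".

The fourth condition delivers nothing; when a no-intervention assignment
coincides with at least one satisfied criterion the moment is logged as an
*omitted control*, the comparison stratum for the proximal-outcome
analyses.

## The personalized control chart

For each person $i$ and distress item, the Shewhart individuals chart is
built from the baseline (phase-1) observations $x_{ij}$:

$$MR_{ij} = |x_{ij} - x_{i,j-1}|, \qquad
  \hat\sigma_i = \overline{MR}_i / d_2, \qquad
  UCL_i = \bar x_i + L\,\hat\sigma_i,$$

with $d_2 = 1.128$ (the expected range of a standard-normal pair,
$2/\sqrt\pi$, so that the mean moving range is an unbiased SD estimate) and
$L = 2$, a one-sided Gaussian tail of about 2.28% per observation. Moving
ranges are taken between successive *completed* observations, ignoring
missed prompts and overnight gaps. The chart is a growing window from day 1
through day 7, frozen afterwards; the intervention phase starts on day 4
once at least 7 baseline observations were completed. An exceedance is
strict (`value > UCL`); a value exactly at the limit does not signal. There
is no lower limit — only elevated distress is actionable here.

Two timing choices were genuinely open and are resolved as follows. First,
during days 4–7 an observation is always evaluated against the chart fitted
on *strictly prior* observations (pre-update), never against a limit that
already includes it. Second, baseline estimation includes all completed
day-1–7 observations, including those following delivered interventions;
excluding post-intervention observations is a plausible alternative
(intervention contamination) and is available through `fit_chart()`'s
`as_of` argument, but inclusion is the default because the delivery
schedule makes exclusion windows ambiguous and the contamination, at the
configured effect sizes, is small relative to within-person noise.

```{r}
rec <- tibble::tibble(person_id = "p1", day = rep(1:2, each = 4),
                      slot = rep(1:4, 2), completed = TRUE,
                      stress = c(2, 5, 3, 6, 2, 5, 3, 4))
fit_chart(rec, "stress", L = 2)
```

On autocorrelated series the moving-range estimator understates the
marginal SD by roughly $\sqrt{1-\rho}$, so personalized limits are tighter
— and SPC alarms more frequent — than the nominal 2.28% for persons with
strong serial dependence. This is a property of the published estimator on
EMA-like data, not a defect of the implementation; the false-alarm
calibration below therefore uses independent draws.

## The synthetic cohort

No participant-level data are redistributable, so the package generates
cohorts with the statistical structure the analyses assume. Per person:

* **Distress dynamics.** Each item follows a stationary AR(1) process,
  $x_t = \mu + \phi(x_{t-1} - \mu) + \varepsilon_t$, discretized by
  round-half-up and clipping to 1–7. AR(1) is the minimal process with the
  within-person serial dependence EMA analyses presuppose. Population
  defaults: person means $\mu \sim N(3, 0.8^2)$ (truncated to the scale),
  within-person SD log-normal with mean 1.0, $\phi \sim N(0.4, 0.15^2)$
  clipped to $[0, 0.95]$ — values a daily-diary analyst would call typical
  for distress items in a help-seeking sample.
* **Compliance.** Independent Bernoulli completion per prompt with a
  person-specific probability drawn from a Beta with mean 0.85 and SD 0.16,
  matching the observed compliance level and spread of such designs. The
  mechanism is missing-completely-at-random because only marginal
  compliance is reported for the design being emulated.
* **Support need.** The trinary item is driven by the momentary mean
  latent distress $m$: "no worries" when $m$ falls below a threshold
  (default 2.5), otherwise *yes* with probability
  $\mathrm{logit}^{-1}(-4 + 0.8\,m)$. The true link in real data is
  unknown; both slope and threshold are configuration, and a zero slope
  decouples support need from distress entirely.
* **Data quality.** The attention check is shown with probability 1/7 at
  completed prompts and answered 5 unless a careless event (default rate
  1.5%) replaces it with a uniform draw from the other scale points.
* **Intervention response.** At each delivery, adoption (actually seeking
  support) is Bernoulli with a condition-specific probability (defaults
  0.23 / 0.22 / 0.43 for fixed cutoff / SPC / support need, the levels
  reported for such conditions). When adopted, the next completed same-day
  prompt has its latent distress reduced by `effect_delta` (default 0.2)
  and its latent support-seeking rating raised by `support_seek_shift`
  before re-discretization. The two post-intervention items attach to the
  next completed prompt even across missed ones, and an evening
  helpfulness rating is generated for each day with a delivery.

One master seed drives everything; per-person child streams are derived
deterministically, so any subset of a cohort is reproducible and the whole
bundle is byte-identical across reruns.

What the generator does *not* emulate: time-of-day and weekday structure,
mood-dependent missingness, response styles other than the careless check,
floor effects beyond clipping, and feedback from deliveries to later
compliance. Passing tests therefore demonstrate that the engine and the
analyses are correct and calibrated *under the stated model*, not that the
trigger rules are effective in real populations.

### Two-pass effect injection

The engine decides all deliveries on the pre-effect records, and
`apply_intervention_effects()` then modifies post-delivery records. A live
system has feedback (a reduced T+1 report can change the T+1 decision);
the two-pass design was chosen because it keeps decision logic and outcome
generation separable and testable, and at the configured effect sizes
(latent shifts of 0.2–0.5 within-person SDs affecting at most the next
same-day prompt) the feedback term is far smaller than prompt-to-prompt
noise.

## The trigger engine

`run_trial()` processes prompts chronologically per person: all three
criteria are evaluated at every completed intervention-phase prompt
(needed for omitted-control and overlap accounting), the condition is
randomized (default ¼ each; the assignment probabilities of the emulated
design are not published, and the delivered-count split it reports reflects
criterion base rates rather than assignment weights), and the daily cap
admits at most two deliveries per person-day. Only *delivered*
interventions count toward the cap; randomize-then-cap ordering is used, so
cap-suppressed assignments are still logged under their assigned condition.
Missing prompts produce placeholder decisions. The decision log is a tidy
table (`tidy()` on the trial), with `glance()` and `trigger_accounting()`
for the totals.

```{r}
run <- run_pipeline(jitai_config(n_persons = 8), seed = 1)
glance(run$trial)
trigger_accounting(run$trial)
```

## The analyses

* `compliance_summary()` — per-person completed/scheduled with the
  double-70% feasibility rule (at least 70% of persons at or above 70%).
* `careless_rate()` — share of shown attention checks not answered 5, with
  the 5% quality bound.
* `descriptives()` — grand mean, person means, between-person SD (SD of
  person means) and mean within-person SD (mean of per-person SDs), the
  standard decomposition for intensive longitudinal data.
* `welch_contrast()` — two-tailed Welch t with Satterthwaite df and a
  pooled-SD, $(n-1)$-weighted Cohen's $d$ (no variant was prescribed;
  the pooled two-sample form is the common default). Binary adoption is
  contrasted as 0/1 means without continuity correction, and p-values are
  reported unadjusted.
* `change_scores()` — for each intervention-phase prompt T with a completed
  same-day follow-up, $\Delta = x_{T+1} - x_T$ per distress item, so
  negative values are reductions. The wording of change-score construction
  in feasibility reports is sometimes the reverse subtraction; the sign
  convention here follows the results convention (negative = reduction).
  T+1 is the next *completed* same-day prompt, not the next scheduled slot,
  and overnight lags are excluded. Strata: `delivered`,
  `omitted_control`, and `not_triggered` (no criterion met anywhere);
  moments where a criterion was met but no delivery or omitted-control
  applied (cap-suppressed, or criterion/assignment mismatch) fit none of
  the three strata and are excluded with a reported count.
* `condition_outcome_contrasts()` — pairwise condition contrasts of
  appropriate timing, behavior adoption, and helpfulness (the latter
  restricted to days with exactly one delivery so the evening rating is
  attributable), and delivered vs omitted contrasts of support seeking at
  T+1 and the distress change scores.

## Calibration designs

Two pre-specified configurations back the package's self-checks.

**Null calibration** (`null_calibration_config()`). Delivered and
omitted-control moments condition on different momentary-state
distributions when several criteria are active (a delivered fixed-cutoff
moment implies high distress; an omitted control only implies *some*
criterion), and AR regression-to-the-mean then differs between groups even
with no intervention effect — a selection feature of this class of designs
worth knowing about when interpreting delivered-vs-omitted contrasts. The
type-I calibration therefore isolates a single active criterion (support
need) at 50/50 randomization against no-intervention, disables the other
two rules and the daily cap, and injects zero effects: the two groups are
then an exact random split and the Welch contrast's rejection rate at
$\alpha = .05$ must be nominal. One thousand replicates of 12-person
cohorts are used (per-replicate group sizes of roughly 60–110 change
scores), a size at which the full replicate loop stays inside a couple of
minutes while the 99% binomial band around 0.05 is ±0.018.

**Effect recovery** (`seek_effect_config()`). Adoption is set to 1 and the
latent support-seeking shift to $0.24\,\sigma_{\text{seek}}$, so the
delivered vs omitted contrast at T+1 carries a standardized effect of 0.24
(slightly attenuated by discretization and clipping, well inside the ±0.1
recovery band at 500 persons). Support seeking is generated independently
of distress, so the selection asymmetry above does not bias this contrast
and the full mixed-criteria design is exercised.

## Numerical and degenerate-input choices

* Discretization is round-half-up (`floor(x + 0.5)`) then clip — monotone
  and exactly testable, avoiding banker's rounding surprises at .5.
* A constant baseline gives $\hat\sigma = 0$ and $UCL = \bar x$; strict
  exceedance then triggers on any value above the mean, and never on the
  mean itself.
* Chart fitting requires ≥ 2 completed baseline observations (else an
  insufficient-data error); the *engine* additionally requires ≥ 7 before
  the SPC rule is evaluable, recording `insufficient_baseline` when the
  SPC condition is assigned earlier.
* UCLs are recomputable from stored components to 1e-12; chart fitting and
  Welch results match independent brute-force implementations to 1e-10 in
  the test suite.
* Contrast cells with fewer than two observations or fully degenerate
  variance are flagged `estimable = FALSE` rather than erroring inside
  result tables; the standalone `welch_contrast()` errors instead, since a
  direct call signals the user expected a result.

## Problem sizes used in the checks

The packaged checks run 500-person cohorts for parameter recovery (three
standard errors for compliance; ±0.1 for the injected effect; ±0.05 for
the adoption difference), 200,000 draws for the known-parameter
false-alarm rate, 100,000 draws for randomization calibration, 1,000
replicates for the null type-I rate, and 1,000 random instances for each
brute-force oracle comparison — sizes chosen so each band is dominated by
the property under test rather than Monte-Carlo noise.

## Known limitations

* The generator's missingness is MCAR and its support-need link is
  logistic in mean latent distress; both are configuration, not claims
  about real data.
* The moving-range sigma is biased low under serial dependence (see
  above), so SPC trigger rates exceed the nominal tail for autocorrelated
  persons — faithful to the published chart, but worth remembering when
  comparing conditions.
* Delivered-vs-omitted contrasts in the mixed-criteria design carry the
  regression-to-the-mean selection asymmetry described under the null
  calibration; the package reports them (as the emulated analyses do) but
  the calibration guarantees apply to the single-criterion design.
* Multilevel models of the intensive longitudinal structure are out of
  scope; all contrasts are observation-level Welch tests.
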