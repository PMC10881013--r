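---
title: "Estimating canine odor detection thresholds from adaptive staircase sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating canine odor detection thresholds from adaptive staircase sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(odorthresh)
```

## The measurement problem

Detection dogs are asked to find a target odor at concentrations far below
human-instrument convenience, and their detection limit moves with the
environment they work in. `odorthresh` implements a complete pipeline for
measuring that limit with an automated olfactometer line-up: a dog faces
three odor ports, exactly one of which carries the target (a
three-alternative forced choice, 3-AFC), and an adaptive staircase walks the
delivered concentration down as the dog succeeds and back up when it fails.
The package covers the dilution model of the olfactometer, the staircase
engine and its stopping rules, the threshold statistic, the behavioral
covariates logged alongside, the mixed-model analysis of condition and
acclimatization effects, and a synthetic observer so every stage can be
validated end to end without animals.

## Air dilution and the concentration ladder

Stimulus intensity is an air dilution: a regulated odor line (cc/min)
displaces vial headspace into a manifold where a clean line (L/min) dilutes
it. The delivered fraction is

$$c = \frac{q_{\text{odor}}}{q_{\text{odor}} + 1000\, q_{\text{clean}}},$$

the factor 1000 reconciling the two flowmeters' units. The standard ladder
has five steps with nominal fractions 0.80, 0.50, 0.25, 0.12, 0.03:

```{r}
default_ladder()
```

All threshold arithmetic uses the nominal fractions: the imputation rules
are stated nominally (0.03 at the floor, 0.80 on failure), and the nominal
and flow-derived values agree to half a percent. Delivered flux (total flow)
is not modelled; the 80% step requires a lower total flow than the others,
and whether flux matters to the animal is outside the model.

## The 3-down-1-up staircase

After three consecutive correct trials the concentration drops one step;
after any error it rises one step. A *reversal* is any change in the
direction of realized movement, recorded at the fraction presented on the
trial that triggered the change — a convention symmetric in up- and
down-turns (the alternative, recording the post-change level, can be had by
shifting the recorded index; the engine exposes the trajectory so either can
be derived). Conventions the engine fixes:

* the consecutive-correct counter resets on every step change and on every
  error, so partial credit never crosses a step;
* an error at the top step clamps without movement, and non-movement never
  records a reversal;
* the first realized movement sets the direction and is never itself a
  reversal;
* refusing to search moves nothing, leaves the counter intact, and feeds the
  welfare streak; a searched trial resets that streak.

A session stops, in priority order, by **welfare** (five consecutive
no-search trials, or one under flagged heat stress), **floor** (three
consecutive correct at the lowest step), **reversals complete** (7 in the
environmental-condition design, 4 in the acclimatization design), or
**time cap** (40 minutes). Floor is checked before reversal completion when
both fire on one trial, because floor terminations carry their own
imputation rule.

## The threshold statistic

The session threshold is the geometric mean of its reversal concentrations,
analysed on the log10 scale. Incomplete sessions are padded to the required
reversal count: floor stops with the lowest fraction (0.03, so a dog that
beats the olfactometer scores $\log_{10} 0.03 = -1.523$), welfare stops with
0.80 (task failure, $-0.097$). Time-capped sessions are padded like welfare
stops; that rule is a package decision — the source procedure defines
imputation only for floor and welfare stops — so it is configurable and the
provenance column records which rule fired. A non-imputed variant uses the
observed reversals only, as the acclimatization analysis requires. Failure
imputation can only raise, and floor imputation only lower, the non-imputed
estimate, so the two variants bracket it.

## The synthetic observer

The simulated dog answers correctly with probability

$$P(\text{correct} \mid x) = \gamma + (1 - \gamma - \lambda)\,
F\!\left(\frac{\log_{10} x - \alpha}{\beta}\right),$$

with guess rate $\gamma = 1/3$, lapse $\lambda$, logistic $F$, midpoint
$\alpha$ (log10 fraction) and spread $\beta$ (log10 units). A logistic core
was chosen over a Weibull because its closed-form midpoint anchors the unit
tests; the staircase only needs a monotone sigmoid. Transformed up-down
theory says a 3-down-1-up rule equilibrates where descent and ascent balance,
$p^3 = 1/2$, i.e. at $p^\ast = 0.5^{1/3} \approx 0.794$.

Two regime caveats matter on this ladder and are verified by the test suite:

* **Tracking regime.** The theory assumes steps small relative to the
  psychometric spread. The fixed ladder's steps are 0.2–0.6 log10 wide, so
  the tracking check uses an observer with $\beta = 0.3$ log10 centered at
  the ladder's log-midpoint ($\alpha = -0.8$); observers much steeper than a
  step quantize onto the ladder and the 79.4% point is undefined between
  steps.
* **Measurable band.** The estimator's response to a planted shift in
  $\alpha$ has slope about 1 mid-ladder but censors toward $-1.52$ and
  $-0.10$ at the ends. Parameter-recovery studies therefore plant effects at
  an interior baseline ($-1.05$) with session spread small enough
  ($\sigma_{\text{dog}} = 0.10$, $\sigma_e = 0.08$) that both condition
  locations stay inside the band — the same floor/ceiling caution the
  underlying assay needs for its hardest and easiest odorants.

## The generated study designs

`simulate_experiment1()` reproduces the environmental-condition design: 8
dogs (two breeds, two blocked condition orders), 4 explosive odorants (AN,
C4, SP, TNT run to completion in that order), 5 chamber conditions (21°C/50%
standard; 40°C at 70% and 40% RH; 0°C at 90% and 50% RH), every cell once,
seven-reversal rules — 160 sessions. `simulate_experiment2()` reproduces the
acclimatization design: the same dogs split 4/4 into control and
acclimatization groups, daily C4 sessions with four-reversal rules over a
22-day schedule that ramps the acclimatization group from standard to
40°C/70% over six days, with both groups tested at 40°C/70% on days 11
and 22.

The generating model for a session's true log threshold is
$\alpha = \alpha_{\text{odor}} + \delta(\text{odor}, \text{condition}) +
b_{\text{dog}} + \varepsilon$, with $b_{\text{dog}} \sim N(0,
\sigma_{\text{dog}}^2)$ and $\varepsilon \sim N(0, \sigma_e^2)$. Defaults
(`effect_spec()`): per-odor baselines at the standard-condition cell means
the assay is built around (C4 $-1.40$, AN $-0.73$, TNT $-0.79$, SP $-1.70$ —
deliberately below the ladder floor, since smokeless powder saturates the
dilution range), condition shifts of the observed magnitudes (C4 + 0.47
under hot-humid, +0.38 under hot-dry), $\sigma_{\text{dog}} = 0.15$,
$\sigma_e = 0.10$, $\beta = 0.15$. Heat load raises the lapse rate, the
no-search probability, and the latency / inter-box-interval locations
(lognormal, additionally shifted by how far the session's true threshold
sits above its odor baseline), so the covariate regressions have signal.
Subcutaneous temperature follows an exponential approach toward a
condition-dependent asymptote (hot-humid > hot-dry > standard), sampled
every 5 minutes with reading noise; cold-chamber series are flagged invalid,
as the real chip readings were. The default temperature coupling of
threshold is zero because the condition shifts already carry the
between-condition differences; the covariate-recovery study plants a
0.21 log10/°C slope with $\delta \equiv 0$ instead, so the pathway is tested
without double-counting.

One master seed drives everything; per-session child seeds are derived
deterministically so any single session reproduces in isolation.

What the generator does *not* emulate: trial-level learning or fatigue
within a session, odor-plume physics, correlated errors between ports,
handler effects, or real chip-failure modes. Passing recovery tests
therefore show the *analysis* is faithful to its own model, not that the
model exhausts real dogs.

## The inferential layer

Estimation mirrors the standard mixed-model workflow for this design
(lme4 REML fits; car Type-II Wald chi-square per fixed term; emmeans
contrasts):

* `fit_threshold_model()`: log10 threshold ~ breed + condition × odor +
  (1 | dog), standard condition as reference.
* `posthoc_condition_vs_standard()`: condition − standard within each odor;
  positive = poorer detection. P-values are emitted unadjusted and with a
  Dunnett-style adjustment, because both conventions appear in reports of
  this design and the choice is not settled.
* `fit_covariate_model()`: threshold ~ covariate × odor + (1 | dog) for mean
  subcutaneous temperature (restricted to the three valid-chip conditions),
  mean searched-trial latency, or mean inter-box interval. Session-mean
  latency averages searched trials only; no-search trials carry no latency.
* `fit_acclimation_model()`: response ~ group + (1 | dog) on the two test
  days, for the threshold (imputed or not) and the behavioral companions.
* `fit_voc_threshold()`: per-odor ordinary regression of threshold on
  condition-mean total VOC, standard condition excluded (no VOC sampling
  there) and condition itself omitted as collinear with VOC. Slopes are
  reported per 100 ppm so they are order 0.1; the scale is printed in the
  output because it is a reporting convention, not a finding.

Asymptotic Wald inference is deliberate — it matches the chi-square-per-term
reporting style of the assay's own analysis — but it is anticonservative in
very small designs: the test suite's null-calibration study (400 simulated
experiments at 4 dogs × 2 odors × 3 conditions) measures rejection near 8%
at nominal 5%, and most of that excess persists even with ideal Gaussian
responses, where the Wald chi-square ignores the ~18 residual degrees of
freedom. Users with few subjects who need exact sizes should prefer
Kenward–Roger or parametric-bootstrap references; the package reports the
Wald statistics that the workflow defines.

## Problem sizes and numerical choices

The test suite validates the staircase against an independent replay oracle
exhaustively over all correct/incorrect sequences up to length 12, checks
tracking over 500 sessions, null calibration over 400 scaled experiments,
and parameter recovery over 30 replicates of 12-dog designs — sizes chosen
so the full suite runs in a few minutes while keeping Monte-Carlo error
well inside the asserted tolerances. Geometric means are computed as means
of log10 fractions (exact for the constant cases); thresholds are bounded by
the ladder whenever all reversals are ladder fractions. Degenerate inputs
(single odor, constant covariate, empty group, zero observed reversals
without imputation) drop terms, error, or flag missing values explicitly
rather than silently fitting.

## Limitations

Thresholds are censored by the five-step ladder: odorants whose true limits
sit below 3% (smokeless powder) or near 80% read as floor or ceiling values,
and planted effects that push sessions against either end recover
attenuated. The reversal-recording convention (pre-change level) is one of
two defensible choices. The treatment-group analysis inherits the
small-sample caveats above at n = 4 per group. And synthetic validation,
however complete, is a statement about the pipeline — real-data conclusions
still require the real logs.
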