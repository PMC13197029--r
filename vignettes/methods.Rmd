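---
title: "Compositional multilevel analysis of the 24-hour day and daily stress: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional multilevel analysis of the 24-hour day and daily stress: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ambulatory-assessment studies record, for each participant and day, how the
24 hours were split across four exhaustive behaviors — sleep, sedentary
behavior (SB), light physical activity (LPA) and moderate-to-vigorous
physical activity (MVPA) — together with repeated momentary ratings of
self-perceived stress and coping self-efficacy (CSE) on a 1–5 Likert scale.
The scientific question is how the *composition* of the day relates to the
daily mean of each rating, both between persons and from day to day within
a person, and what outcome change is predicted when time moves from one
behavior to another.

Durations of a closed day are not free to vary independently: they sum to
1440 minutes, carry only relative information, and entering them jointly in
a regression produces built-in collinearity. `stresscomp` therefore works
in Aitchison geometry: every day is mapped to isometric log-ratio (ilr)
coordinates before modelling.

## Pivot coordinates and the four rotations

For an ordered 4-part composition $(x_1, x_2, x_3, x_4)$ the pivot
(sequential binary partition) coordinates are

$$z_1 = \sqrt{\tfrac34}\,\ln\frac{x_1}{\sqrt[3]{x_2 x_3 x_4}},\qquad
  z_2 = \sqrt{\tfrac23}\,\ln\frac{x_2}{\sqrt{x_3 x_4}},\qquad
  z_3 = \sqrt{\tfrac12}\,\ln\frac{x_3}{x_4}.$$

The first coordinate isolates the first listed behavior against the
geometric mean of the rest. Fitting the same model under four named
rotations (`H1`–`H4`, see `ilr_orderings`) lets every balance of interest
appear once as a leading or trailing coordinate — e.g. rotation `H4` ends
with the sleep-to-SB balance $z_3 = \sqrt{1/2}\ln(\text{sleep}/\text{SB})$.
The four rotations are orthogonal reparameterizations of the same geometry:
total ilr variance and, for a fixed random structure, the mixed-model
likelihood are rotation invariant, which the test suite checks to
numerical precision. The basis is hard-coded for $D = 4$; no general-$D$
machinery is provided because none is needed here.

## Zero replacement

Log-ratios require strictly positive parts, but accelerometer pipelines
occasionally record 0 minutes of MVPA when activity stayed below the
detection limit. `replace_zeros()` defaults to multiplicative replacement:
a zero cell becomes $\delta = 0.65\,d$ with detection limit $d = 1$ minute,
and the observed cells are rescaled by $(1440 - \delta)/1440$, preserving
their pairwise ratios exactly. An expectation-maximization variant on the
additive log-ratio scale (`method = "lrEM"`, tolerance $10^{-6}$, at most
50 iterations, imputations kept below the detection limit) is provided for
users who prefer model-based imputation. With the handful of zero cells
such cohorts contain, the two methods are numerically indistinguishable
downstream; the multiplicative rule is the default because it has an exact
closed form that tests can pin down. The 1-minute detection limit is an
assumption of this package, chosen as the natural resolution of
minute-aggregated classification.

## Screening

A participant-day is valid when wear time is at least 20 hours, at least
one walking period was detected, and sleep is non-zero; participants need
at least three valid days. Momentary ratings are averaged per day
(arithmetic mean of the non-missing 1–5 ratings); days with no rating of
either outcome are dropped, and a day missing only one outcome is kept and
simply drops out of that outcome's model (listwise per model). Days are
calendar midnight-to-midnight, so time in bed before midnight counts
toward the following day — a known distortion of sleep timing that this
package inherits deliberately. `screen_cohort()` reports every exclusion
bucket and the counts reconcile exactly: input days = days of excluded
participants + wear-invalid days + rating-free days + retained days.
Morning sleep quality refers to the night preceding the day it is attached
to; the evening exercise flag refers to the same day.

## The two-level models

With daily outcome $Y_{ij}$ (day $i$ in participant $j$), the hypothesis
models are

$$Y_{ij} = \gamma_{00} + \gamma_{01}\,\text{sex}_j + \gamma_{02}\,\text{age}_j
 + \gamma_{03}\,\text{BMI}_j \;[+\; \gamma_{10}\,\text{CSE}_{ij}]
 + \gamma_{20} z^{(c)}_{1,ij} + \gamma_{30} z^{(c)}_{2,ij}
 + \gamma_{40} z^{(c)}_{3,ij} + u_{0j} \;[+\; u_{1j} z^{(c)}_{k,ij}] + r_{ij},$$

fitted by REML via `lme4`, with the ilr predictors centered within person
($z^{(c)}_{ij} = z_{ij} - \bar z_{\cdot j}$, unweighted arithmetic means
over the participant's retained days), so the composition coefficients are
within-person effects. On the ilr scale this centering equals compositional
perturbation by the inverse of the person's geometric-mean day. Sex is
coded female = 0. The CSE covariate appears only in stress models; it
enters grand-mean centered by default (`cse_centering = "grand"`), which
leaves its slope untouched but keeps the intercept on the outcome scale —
the raw covariate is available as a sensitivity toggle. Person-mean
centering of CSE is deliberately not the default, so its coefficient blends
within- and between-person association as in the emulated design.

Random-slope selection (`select_random_slope()`) tests each candidate ilr
slope one at a time against the intercept-only model by a REML likelihood
ratio, using the boundary-corrected $0.5\chi^2_1 + 0.5\chi^2_2$ mixture
null; at most one slope is retained (smallest $p < .05$, ties broken by
ilr index), with an unstructured 2×2 random covariance. Testing all three
coordinates is the package's choice; a study may prefer theory-chosen
candidates, and the candidate set is an argument.

Fixed-effect inference uses the residual degree-of-freedom convention
$df = n_{\text{obs}} - n_{\text{fixed}}$ — consistent with the large
printed $t$-statistics degrees of freedom such studies report —
rather than Satterthwaite adjustment; with ~2000 observation-level degrees
of freedom the difference is immaterial. Standardized coefficients use
$\beta_{std} = B \cdot SD(x)/SD(y)$ over all retained participant-days;
this is a documented convention, since "established procedures" for
standardization differ in how they treat multilevel variances. Intraclass
correlations come from unconditional models:
$\rho_I = \tau_0^2 / (\tau_0^2 + \sigma^2)$, within-person share
$= 100(1 - \rho_I)$, an exact identity of the fitted variance components.
Diagnostics (`model_diagnostics()`) report VIFs of the fixed design,
Shapiro–Wilk and QQ data for level-1 residuals, and a Spearman test of
$|r_{ij}|$ against fitted values — flags only, never automatic refitting;
non-convergence is reported, not silently worked around.

## Reallocation (isotemporal substitution)

`reallocate()` moves $t \in \{0, 20, 40, 60\}$ minutes from one behavior
to another, holding the rest fixed. The predicted outcome change is

$$\Delta(t) = \sum_k \gamma_{k}\,\bigl(z_k(\text{reallocated}) - z_k(\text{base})\bigr),$$

summed over the three composition fixed effects; covariates and random
effects cancel because they are held fixed. $\Delta$ is exactly
antisymmetric under reversing the move from the moved-to composition. The
base composition defaults to the sample's arithmetic mean day closed to
1440 minutes, with an explicit override: published starting points are not
always derivable from the same sample's tables (the emulated study prints
a 490/649/227/74-minute base that matches neither its arithmetic nor its
geometric means), so reproduction runs should pass the printed base
explicitly.

Confidence intervals come from a cluster bootstrap: whole participants are
resampled with replacement (days kept intact, duplicated participants
treated as distinct clusters), the model is refitted per resample with the
random structure fixed to the full-data choice (re-selecting slopes inside
the bootstrap would add selection noise to the interval), and the 2.5/97.5
percentiles of the $\Delta$ draws are reported; 1000 replicates by
default. The resampling unit is the package's choice — resampling level-2
units is the standard way to respect two-level dependence. Replicates that
fail to converge are dropped; more than 20% failures aborts with
diagnostics.

## The synthetic cohort generator

No deposited data accompany the design this package emulates, so the
generator is a first-class, tested module that produces the three study
tables with the between/within structure the analysis assumes. Defaults
describe a cohort of 198 university employees over 15 scheduled working
days.

* **Compositions** are logistic-normal on the ilr scale: person means
  $\mu_j \sim \mathcal N(\mu, \Sigma_B)$, days
  $z_{ij} \sim \mathcal N(\mu_j, \Sigma_W)$ (reference rotation `H1`),
  mapped back through the inverse ilr and closed to 1440 minutes. A
  Dirichlet alternative was rejected because the logistic-normal makes the
  between/within variance partition exact in the geometry the models use.
  $\mu$ is set so the population geometric-mean day is 8.1 h sleep /
  10.8 h SB / 3.8 h LPA / 1.2 h MVPA. $\Sigma_B$ projects independent
  log-part variances onto the pivot basis with coefficients of variation
  (sleep .151, SB .113, LPA .272, MVPA .333) calibrated so person-level
  hour SDs match the descriptive table of the emulated cohort; a diagonal
  ilr covariance cannot do this because sleep and MVPA load the final
  pivot coordinate symmetrically. $\Sigma_W = \mathrm{diag}(0.23, 0.34,
  0.32)^2$ was chosen so fixed-effect standard errors at study scale come
  out in the printed range. Between- vs within-person splits of real
  compositions are not published, so these are calibration choices, not
  study facts.
* **Outcomes.** Each day carries latent means for CSE and stress generated
  from the two-level models above, with fixed effects, random-effect SDs
  and residual SDs set to the reference reported estimates
  (`default_outcome_params()`); ilr effects act on the true within-person
  deviations; the stress equation couples to the day's latent CSE
  ($\gamma = -0.57$) anchored at its expected value. The random intercepts
  of the two outcomes correlate at 0.20, calibrated so the unconditional
  stress ICC, SD and mean land at the emulated 0.483 / 0.87 / 2.36 after
  Likert clamping compresses the tails.
* **Prompts.** Per day a Poisson(4.9) count capped at 6 (capped mean ≈ 4.4
  answered prompts); with probability 0.07 the day has no ratings. Each
  prompt adds $\mathcal N(0, 0.3)$ measurement noise to the daily latent,
  rounds to the Likert grid and clamps to 1–5 — the daily latent is
  per-day by design, prompt noise is pure measurement error, matching an
  analysis that aggregates to daily means.
* **Imperfections.** 15% of days wear < 20 h, 1% lack detected walking,
  and MVPA below the 1-minute detection limit — or an injected detection
  failure at rate 0.0013 per day, about three days per cohort — is
  recorded as 0 with the minutes absorbed into SB, feeding the
  zero-replacement stage. Morning sleep quality (0–100, 10% missing) and
  the evening exercise flag (30% missing) support the exploratory models;
  their effect sizes are illustrative, not calibrated.
* **Covariates.** Age and BMI are truncated normals whose *realized*
  mean/SD equal the printed descriptives (parent parameters
  moment-matched; plain truncation of a normal at the printed mean/SD
  would shift the realized mean upward by more than a year); sex is
  Bernoulli(0.548 female).
* **Seeding.** One master seed spawns one stream per participant and
  stage, so enlarging the cohort never perturbs earlier participants, and
  identical configurations are bit-identical.

What the generator does **not** emulate: raw acceleration or posture
classification, weekday/weekend structure, prompt-level autocorrelation
within a day, systematic (non-random) missingness, floor/ceiling
asymmetries beyond Likert clamping, or any intervention arm. Passing tests
therefore demonstrate that the *pipeline* recovers what it assumes, not
that real behavior satisfies those assumptions.

## Parameter recovery and verification strategy

Because the emulated study's human data are not deposited, its headline
coefficients cannot be reproduced from raw input. Verification instead
has two arms:

1. **Printed arithmetic identities** the pipeline's own formulas must
   reproduce exactly (ICC-to-share conversion, percentage-to-hours of the
   geometric-mean day, count proportions).
2. **Parameter recovery**: `simulate_model_data()` generates daily-level
   cohorts (198 × 12 by default) from the reference sleep-vs-SB model
   values (`h4_stress_params()`: ilr3 effect −0.10, intercept SD 0.61,
   residual SD 0.55) with the calibrated ilr variability, and
   `recover_parameters()` refits the model across replicates, reporting
   mean estimates with Monte-Carlo standard errors. Recovery simulates at
   the daily level (no prompt noise) and defines the generating ilr
   effects on deviations from *observed* person means, so the refit is
   unbiased by construction and deviations flag implementation defects
   rather than design artifacts.

Problem sizes used by the shipped tests: 100 recovery replicates at
198 × 12; bootstrap-coverage simulation with 100 outer replicates of
50 participants × 6 days and 100 bootstrap draws (nominal 95% interval,
accepted range 90–99%). Percentile cluster bootstraps are known to
undercover when clusters are few — the same code measured 88% coverage at
30 clusters — so 50 clusters is about the smallest cohort for which the
default intervals should be trusted at face value. Slope-selection power
is exercised at 80 participants × 30 days (many days
per person make a random-slope variance identifiable — at 198 × 12 with
slope SD 0.3 the restricted LRT has only ~50% power, which is worth
knowing when interpreting retained and non-retained slopes in real data
of that shape).

## Numerical choices and limitations

* Optimizer: `lme4` defaults with deterministic initialization; REML
  throughout; bootstrap refits disable derivative checks for speed.
* Ties in slope selection break by smallest p then ilr index; LR
  statistics are floored at 0.
* Compositions are validated to close to 1440 ± 1e-6; ilr requires all
  parts > 0 and refuses otherwise rather than imputing silently.
* The package fits no prompt-level (3-level) models, no Bayesian
  estimation, no crossed random effects, and no reallocations beyond
  equal-time pairwise swaps within the 60-minute window.
* Likert clamping makes the generator's observed outcome moments differ
  slightly from the latent generating values (the stress mean rises by
  ~0.05 and between-person variance compresses); the calibration above
  absorbs this at the defaults, but users changing outcome parameters
  should re-check marginal moments.
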