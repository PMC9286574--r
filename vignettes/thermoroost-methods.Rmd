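---
title: "Methods: torpor detection, the duration model, and the energetics simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: torpor detection, the duration model, and the energetics simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoroost)
```

thermoroost studies a question in thermal ecology: when a small heterothermic
bat can drop into daily torpor at will, how much does the temperature of its
diurnal roost actually matter to its energy budget, and does roost
temperature then predict which roosts it uses? The package implements the
full chain of analyses as testable code: bout delineation from
skin-temperature telemetry, a hierarchical regression of daily torpor
duration on ambient temperature, a minute-by-minute energy-expenditure
simulator contrasting heterothermy with forced homeothermy, and a
used-versus-available roost selection analysis. A seeded synthetic-data
module generates datasets with known ground truth so that every stage can be
validated end-to-end without field data.

This vignette records the modelling choices, their rationale, and the limits
of what the synthetic validation demonstrates.

## Clock-time conventions

All of the field rules are clock-time rules, so times are local clock time
in minutes since midnight (0-based) and dates are ISO-8601. The analysis
window is 4:45 AM to 9:00 PM (minutes 285 to 1260, 975 min) — typical roost
entry and exit times — and window membership is half-open, `[start, end)`,
so the window holds exactly 975 one-minute samples. Roost thermal summaries
are restricted to 28 July–30 September. (Configuration inherited a
"31 September" end date from the source conventions; since that date does
not exist it is read as 30 September.)

## Torpor-bout delineation

Torpor is taken to begin when skin temperature drops below the lowest skin
temperature observed during homeothermy, and to end when skin temperature
begins a steep sustained rise (re-entry into homeothermy, or departure from
the roost). Two parameters operationalise "steep rise": a warming rate
(default 0.5 °C/min) that must hold on average over a sustain period
(default 5 min). Two refinements matter in practice:

* the close is placed where the rise *starts*, so in addition to the
  window-average criterion the immediate next step must also warm at the
  threshold rate — otherwise a look-ahead average closes bouts several
  samples before arousal actually begins;
* after a close, scanning is suspended until the steep rise slackens (below
  half the threshold rate) or skin temperature re-crosses the onset
  threshold, so an arousal ramp cannot re-open the bout it just ended. If an
  aborted arousal sags back into torpid temperatures, a new bout opens,
  which is the intended reading of "a rise that *leads to* homeothermy".

A bout still open at the trace end closes there (the bat left the roost
while torpid). Bouts shorter than one sampling interval are discarded. The
onset threshold is estimated per day from a homeothermic reference window
(default: the first 30 min after the window start), either pooled across the
bats present that day (default, matching the pooling of "bats maintaining
homeothermy during a day") or per bat-day; an explicit scalar override is
accepted, and is the right choice for traces in which bats are already
torpid at first light. Single missing samples are linearly interpolable;
traces with longer gaps are dropped from the daily records, so only full
days enter the model.

## The hierarchical torpor-duration model

Daily torpor minutes are modelled as

$$y_{ij} = \alpha + a_i + \beta_T\,\bar{T}_{ij} + \beta_M\,m_i +
\varepsilon_{ij}, \qquad a_i \sim N(0, \sigma_{ind}^2), \quad
\varepsilon_{ij} \sim N(0, \sigma_{res}^2),$$

with $\bar{T}_{ij}$ the daily mean ambient temperature over the analysis
window (°C) and $m_i$ body mass at capture (g). Covariates enter on the raw
scale so $\beta_T$ reads directly as minutes of torpor lost per additional
degree.

The sampler is a blocked Gibbs sampler written for exactness and
testability; every full conditional is conjugate, so there are no tuning
parameters and chains are deterministic given a seed. Priors are
Normal(0, 10^4) on the coefficients — placed on the slopes and on the
intercept of the internally mean-centered design, the convention of standard
hierarchical-regression software, so the intercept prior refers to the
response at average covariates — and half-Student-t(3, 100 min) on both
standard deviations, implemented exactly through their inverse-gamma
parameter expansion to keep the variance blocks conjugate. Two numerical
choices deserve note:

* the coefficient block is *collapsed*: random intercepts are integrated
  out of the coefficient update (per-bat covariance handled analytically
  through group sums). Body mass is constant within bat, so the
  uncollapsed sampler walks a ridge between $\beta_M$ and the $a_i$ and
  mixes poorly; collapsing removes the ridge at no cost in correctness;
* records are sorted by bat and date before sampling, so posterior
  summaries are invariant to input row order.

Defaults follow the study protocol: 3 chains × 12,000 iterations with 2,000
warm-up. Convergence is assessed with split-chain Gelman–Rubin $\hat{R}$ and
an autocorrelation-based effective sample size using Geyer's initial
positive monotone sequence truncation; runs missing $\hat{R} < 1.01$ or
ESS > 10,000 warn rather than fail. With a single individual the model is
unidentifiable in $\sigma_{ind}$; the fit proceeds with a warning and the
random-intercept SD held at its prior.

## The energy-expenditure simulator

Metabolic rates follow the classic Scholander form. In homeothermy the
mass-specific rate is flat at the basal rate within the thermoneutral zone
and rises linearly below the lower critical temperature $T_{lc}$:
$\mathrm{MR}_h(T_a) = \mathrm{BMR} + k_h \max(T_{lc} - T_a, 0)$. In torpor
the rate follows a Q10 curve anchored at a reference measurement,
$\mathrm{MR}_t(T_a) = \mathrm{TMR}_{ref}\,Q_{10}^{(T_a - T_{ref})/10}$,
capped at the homeothermic rate so torpor can never cost more than
homeothermy at the same temperature. Whole-animal J/min is the per-gram rate
× mass × 20.1 J/mL O~2~ / 60.

The default constants — $T_{lc}$ 33 °C, BMR 1.5 mL O~2~ g^-1^ h^-1^,
conductance slope 0.18 mL O~2~ g^-1^ h^-1^ °C^-1^, torpid rate 0.05 at
20 °C, Q10 2.5, mass 8 g — are **calibration placeholders** in the right
range for a small vespertilionid. They are deliberately user-settable;
species-specific laboratory measurements should replace them, and the
package's validated claims about the simulator are structural (dominance of
heterothermy, monotone homeotherm cost, flatness of the heterotherm trend)
plus hand-evaluated arithmetic of the configured formulas, not absolute kJ
values.

A simulated day anchors to observation: the baseline "average" roost
(window-mean temperature $\bar{T}$, by default the mean over used
roost-days) receives the observed mean torpor duration $\bar{D}$; any other
roost-day shifts that duration along a slope draw,
$D = \mathrm{clamp}(\bar{D} + \beta_T (T - \bar{T}),\, 0,\, 975)$.
Clamping is applied before the bout split. Torpor is laid out with the
observed decision rules: bats enter torpor immediately at roost entry, so
the morning bout starts at the window start and takes 86.9% of $D$; the
evening bout takes 13.1% unless it would be shorter than 30 min, in which
case all torpor is morning torpor. The evening bout is anchored to *end* at
the window end, matching pre-departure torpor. Segment boundaries stay
fractional, so scheduled torpor equals $D$ exactly; energy is then
integrated minute-by-minute on a 1-minute grid (logger traces are linearly
interpolated to that grid, and a roost-day missing more than 10% of window
minutes is an error rather than a silent extrapolation). Arousal costs are
not modelled — transitions are instantaneous state switches — because the
simulated decision rules carry no transition physiology; this
underestimates heterotherm costs slightly and uniformly.

Posterior uncertainty is propagated by drawing an independent $\beta_T$ from
the fitted posterior for every roost-day (draws taken up front in sorted
roost-day order, so the simulation is seed-deterministic).

## Roost thermal summaries and the selection model

Per roost and day: the window mean, the clock time of the daily maximum
(earliest sample attaining it, as decimal hours — the window is
daytime-only, so an arithmetic mean of hours needs no circular treatment),
and the population (divide-by-*n*) SD; daily values are averaged across
complete days (≥ 90% of expected window samples) in the date range.

Selection is a Bayesian logistic regression of used (1) versus available
(0) on the three summaries, rock and tree roosts pooled. Predictors are
standardized internally for sampler stability; coefficients are reported on
both scales. Priors are Normal(0, 5²) on the standardized scale. The sampler
is random-walk Metropolis within Gibbs with per-coordinate proposal scales
adapted toward 44% acceptance during warm-up only, so the kept draws come
from a valid fixed-kernel chain. Complete separation warns and is handled by
the priors. Predictive performance is the rank-sum AUC (ties counted half)
of the posterior-mean linear predictor; the companion regression of
used-roost temperature on daily ambient temperature is ordinary least
squares with the two-sided slope test on $n-2$ df.

## What the synthetic data emulate — and what they do not

The generators reproduce the statistical structure every stage assumes:
diurnal sinusoid-plus-AR(1) roost traces (window means spanning
16.9–23.6 °C, peak near 14:30, 10-min resolution) — parameterised by the
*window-mean* temperature, i.e. the sinusoid is centred on the analysis
window, because the window is not a whole period and an uncentred sinusoid
would shift every window mean by a constant ≈ 0.36 × amplitude; skin traces
(1-min resolution) alternating a 35 °C homeothermic level with torpor
tracking ambient + 2 °C, exponential entry (most of the drop inside a
minute, complete within 15), 1 °C/min arousal, and jitter truncated at
3 SD so the homeothermic floor is a hard bound; torpor durations linear in
daily temperature with per-bat intercepts (balanced shared-day designs
optional); and used/available labels from a logistic model on standardized
summaries, with the default intercept −0.9 matching the ≈ 40:97
used:available regime.

They deliberately omit: day-to-day weather (roost means are fixed per
roost, so the ambient-vs-used regression sees almost no ambient variance —
its null result on synthetic data validates plumbing, not weather
independence), microclimate heat waves, logger dropouts beyond simple gaps,
transmitter detachment artefacts, sex or reproductive-condition effects,
and any spatial structure among roosts. Passing tests therefore demonstrate
that the estimators recover the generating process they assume, not that
field data satisfy those assumptions. Body mass is drawn from N(8 g,
0.5 g), a documented placeholder.

## Problem sizes and seeds

Validation runs use desk-scale sizes chosen to keep Monte-Carlo error well
inside the asserted tolerances: 500-record balanced datasets for the
OLS-equivalence check (a balanced panel makes the GLS-weighted posterior
mean coincide with OLS, so the comparison is exact rather than approximate);
40 bats × 10 days with 20 seeded replicates for slope recovery; 137-roost
selection datasets with 20 replicates for coverage; 100 seeded traces for
detection round trips; chains of 1,500–4,000 iterations where the conjugate
sampler's effective sample sizes already reach the thousands. Every
stochastic step takes an explicit integer seed, and all generators are pure
functions of (truth, seed).

## Known limitations

* The metabolic constants are placeholders (above); absolute kJ outputs are
  illustrative until calibrated.
* The onset-threshold rule assumes some homeothermic reference exists; for
  days on which a bat is torpid from first observation, the threshold must
  be supplied explicitly.
* The selection model is an unpaired binomial fit even though available
  roosts were sampled partly as pairs of used roosts; no weighting is
  applied, and paired designs would call for a conditional-logistic
  variant that is out of scope here.
* ESS is truncated at the total draw count, so antithetic chains are
  reported conservatively.
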