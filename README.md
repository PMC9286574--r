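# thermoroost

Daily torpor, roost microclimates, and the energy budget of a heterothermic
bat.

Small insectivorous bats spend their days inactive in rock crevices and
tree cavities whose temperatures usually sit well below the thermoneutral
zone. A strict homeotherm pays for that: metabolic rate rises linearly as
ambient temperature falls below the lower critical temperature, so cool
roosts are expensive and warm roosts should be strongly preferred. A
heterotherm, though, can drop into daily torpor, letting body temperature
track ambient and cutting metabolic rate by an order of magnitude — and it
can use *more* torpor on cooler days. thermoroost implements, end to end,
the analysis chain for asking whether that compensation is strong enough to
flatten daily energy expenditure across roost temperatures, and whether
roost temperature then predicts roost selection at all:

1. **Torpor detection** (`delineate_bouts()`, `detect_torpor_days()`):
   delineates torpor bouts in skin-temperature telemetry — onset when skin
   temperature drops below the lowest homeothermic skin temperature of the
   day, offset at the first sustained steep rise — and builds daily records
   of torpor minutes, daily mean ambient temperature, and body mass.
2. **Duration model** (`fit_torpor_model()`): a Bayesian hierarchical
   regression, `torpor_min = alpha + a_i + beta_T * T_day + beta_M * mass +
   eps` with per-bat random intercepts, fitted by an exact blocked Gibbs
   sampler (collapsed coefficient update; half-t priors on SDs via their
   inverse-gamma expansion), with split-chain R-hat, effective sample size,
   and equal-tailed credible intervals (`rhat()`, `ess()`,
   `credible_interval()`).
3. **Energetics simulation** (`simulate_study()`): minute-by-minute daily
   energy expenditure in each roost under a Scholander/Q10 metabolic model,
   contrasting the observed heterothermic strategy (torpor duration keyed to
   roost temperature through the fitted slope, a fresh posterior draw per
   roost-day, 86.9%/13.1% morning/evening bout split with a 30-min minimum
   evening bout) against a forced homeotherm.
4. **Microhabitat selection** (`thermal_summaries()`,
   `fit_selection_model()`, `auc()`, `ambient_vs_used_regression()`):
   windowed thermal summaries per roost, a Bayesian binomial
   used-vs-available model on mean temperature, peak timing, and daily SD,
   ROC/AUC, and the regression of used-roost temperature on daily ambient
   temperature.
5. **Synthetic data** (`gen_study()` and friends): seeded generators with
   known ground truth for every stage, so the whole pipeline is testable
   with no field data.

## Worked example

The `analysis/` scripts run the pipeline on a synthetic study (7 bats × 4
telemetry days; 40 used and 97 available roost loggers spanning
16.9–23.6 °C window means; ground-truth torpor slope −37.3 min/°C):

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_detect_torpor.R
Rscript analysis/03_fit_torpor_model.R
Rscript analysis/04_simulate_energetics.R
Rscript analysis/05_microhabitat_selection.R
```

which prints (tables land under `results/`):

```
detected 55 bouts over 28 bat-days (0 dropped for gaps)
mean |detected - programmed| torpor: 2.0 min (max 2.8)

torpor-duration slope: -38.3 min/degC (95% CI -49.3 to -26.9)
worst R-hat 1.0079, smallest ESS 1174

simulated 400 roost-days; baseline 385 min torpor at 20.7 degC
mean daily cost: heterotherm 5.33 kJ vs forced homeotherm 9.69 kJ
EE-vs-temperature slope: homeotherm -0.470 kJ/degC, heterotherm 0.097 kJ/degC (79% shallower)

137 roosts summarized (40 used, 97 available)
mean temp: used 20.7 degC vs available 20.1 degC; AUC 0.615
ambient vs used-roost temperature: slope 0.690, R^2 = 0.000, p = 0.963
```

Reading those numbers: detection recovers programmed bouts to within a
couple of minutes; the hierarchical model's credible interval covers the
generating slope (bats drop ~37 min of torpor per extra °C of daily mean
temperature); a forced homeotherm saves almost half a kJ per day for every
degree of roost warmth, while the heterotherm's budget is ~79% flatter
because longer torpor in cool roosts offsets the higher cost of
homeothermy there; and with selection coefficients this weak the model
barely beats a coin flip (AUC 0.615), with no sign that bats chase warm
roosts on warm days.

The metabolic constants (`metabolic_config()`) are documented calibration
placeholders for a small vespertilionid; replace them with species-specific
measurements for absolute (rather than structural) energy estimates.

## Layout

```
R/                  package code: detection, model, simulator, selection, generators
analysis/           numbered drivers running the pipeline on synthetic data
tests/testthat/     unit, property, and acceptance tests
scripts/acceptance.R  headline-quantity recomputation (JSON out)
vignettes/          methods vignette: models, priors, numerical choices, limits
```
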