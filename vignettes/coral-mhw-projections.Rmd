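---
title: "Projecting coral responses to marine heatwaves under ocean acidification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting coral responses to marine heatwaves under ocean acidification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralMHW)
```

## The problem

Marine heatwaves (MHWs) — runs of days on which sea surface temperature
exceeds a high percentile of a baseline distribution — are the proximate
trigger of mass coral bleaching, and they intensify in step with greenhouse
gas emissions while ocean acidification (OA) progresses in parallel.
coralMHW implements a projection pipeline that turns a corpus of published
warming and CO~2~ experiments on reef-building corals into quantitative
statements of the form "at the MHW intensity expected under RCP8.5 late this
century, coral survival is expected to decline by X% (95% CI ...)".

The pipeline has five stages, each usable on its own:

1. **Effect sizes** per experiment (`effect_sizes()`),
2. **Interaction classification** for full-factorial warming x CO~2~
   experiments (`interaction_effects()`),
3. **Multilevel random-effects meta-analysis** pooling the effect sizes
   (`coral_meta()`),
4. **Back-transformation** of pooled effects to percent change under
   warming/CO~2~ scenarios, with a threshold-sensitivity search
   (`percent_change_temp()`, `min_significant_delta()`, `project_all()`),
5. **MHW detection** in daily SST series (`mhw_threshold()`,
   `mhw_events()`, `mhw_annual_stats()`, `mhw_envelope()`).

A sixth component, the synthetic-data generators (`sim_experiments()`,
`sim_factorial()`, `sim_sst()`), produces every input with known ground
truth so that the whole chain can be validated end to end.

## Effect sizes

### Activation energy for warming contrasts

A warming experiment reports a control mean $V_o$ at temperature $T_o$ and a
treatment mean $V_i$ at $T_i > T_o$. Assuming the contrast conforms to an
Arrhenius model, the temperature sensitivity is summarised by the activation
energy (in eV)

$$E \;=\; \frac{\ln(V_o/V_i)}{\dfrac{1}{kT_o} - \dfrac{1}{kT_i}},$$

with $k = 8.617\times10^{-5}$ eV/K and temperatures in Kelvin
($T_K = T_C + 273.15$, exactly). The sign convention is that a rate which
*declines* under warming yields $E > 0$. Expressing the effect per unit of
$1/kT$ rather than per degree is what lets experiments with very different
warming increments (+0.5 to +13 °C in the envelope emulated here) be pooled
on a common scale: $E$ is a log response ratio standardised by the thermal
energy difference.

### Log response ratio for CO~2~ contrasts

CO~2~ contrasts do not presuppose an Arrhenius form; they are summarised by
the log response ratio per +100 µatm,

$$\mathrm{LnRR}_{\Delta 100} \;=\;
  \frac{\ln \bar{x}_{exp} - \ln \bar{x}_{cont}}
       {p\mathrm{CO}_{2,exp} - p\mathrm{CO}_{2,cont}} \times 100,$$

negative when the attribute declines as pCO~2~ rises.

### Sampling variances

The meta-analysis weights each effect size by the inverse of its sampling
variance, which the source literature leaves unspecified. coralMHW uses the
standard two-group delta-method variance of a log ratio,

$$v_{\ln} = \frac{SD_{t}^2}{n_t \bar{x}_t^2} + \frac{SD_c^2}{n_c \bar{x}_c^2},$$

rescaled to the effect scale ($v_E = v_{\ln}/\Delta(1/kT)^2$;
$v_{\mathrm{LnRR}} = v_{\ln}\,(100/\Delta p\mathrm{CO}_2)^2$). When both arm
SDs are zero (occasionally reported for survival counts) the variance
degenerates; a configurable floor (`variance_floor`, default $10^{-8}$ on
the final effect scale) is substituted with a warning rather than producing
an infinite weight. Records with non-positive means cannot enter a log
ratio; they are excluded at validation, with an optional continuity
correction (`continuity = TRUE`, substituting $0.5/n$) for zero survival
proportions, off by default because its use in the source analyses is
unknown.

## Interaction classification

Full-factorial experiments carry four arms (control, warming, CO~2~, both).
The interaction strength is the standardized log-mean contrast

$$\mathrm{LnRR}_{inter} \;=\;
 \frac{\ln\bar{x}_B - \ln\bar{x}_W - \ln\bar{x}_C + \ln\bar{x}_{Cont}}{2s},$$

with $s$ the pooled SD over the four arms. The grouping of the numerator is
chosen so that a *multiplicative* null
($\bar{x}_B = \bar{x}_W \bar{x}_C / \bar{x}_{Cont}$) gives exactly zero —
the only reading consistent with the multiplicative rationale of the
log-ratio effect sizes, and the one `interaction_effects()` implements.
Individual effects are $(\ln\bar{x}_W - \ln\bar{x}_{Cont})/s$ and
$(\ln\bar{x}_C - \ln\bar{x}_{Cont})/s$.

Classification: **additive** when the 95% CI of
$\mathrm{LnRR}_{inter}$ includes zero; otherwise **synergistic** when the
interaction is negative (the combination is worse than the multiplicative
expectation) and **antagonistic** when positive, given individual effects
that are both negative or of mixed sign. When both individual effects are
positive the reading inverts (a positive interaction then amplifies the
increases); such rows are flagged `sign_inverted` because that convention is
adopted from the factorial meta-analysis literature rather than implied by
the decision rule itself.

### Two variance modes

The factorial meta-analysis variance formula transcribed from the source
literature,

$$s^2_N = \frac{1}{n_W} + \frac{1}{n_C} + \frac{1}{n_B} + \frac{1}{n_{Cont}}
 + \frac{\mathrm{LnRR}_{inter}^2}{2(n_W+n_C+n_B+n_{Cont})},$$

is implemented verbatim as the default (`variance = "as_published"`). Its
leading terms are not scaled by the pooled SD, which makes the implied CI
very wide for standardized log ratios: under a simulated multiplicative
null with $n = 4$ per arm the additive classification rate is essentially
100%, i.e. the rule is strongly conservative. A calibrated alternative
(`variance = "delta"`) uses the delta-method variance of the log-mean
contrast, $\sum_a SD_a^2/(n_a\bar{x}_a^2) / (2s)^2$, whose CI covers a true
null at close to the nominal 95%; the type-I validation in the test suite
runs in this mode and additionally pins the conservatism of the as-published
mode. Both modes are exposed so users can reproduce the published behaviour
or work with the calibrated one.

## The meta-analysis model

Effect sizes are pooled per attribute x kind x driver context under

$$y_j = \mu + u_{study(j)} + w_{genus(j)} + e_j,\qquad
 e_j \sim N(0, v_j),\; u \sim N(0,\sigma^2_{study}),\;
 w \sim N(0,\sigma^2_{genus}),$$

with $v_j$ known and study and genus entering as *crossed* random
intercepts — they are parallel sources of dependence (a study contributes
several contrasts; a genus appears in many studies), not nested levels. A
nested variant (`structure = "nested"`) is available for comparison.
Variance components are estimated by REML with non-negativity constraints
and $\mu$ by generalized least squares at the REML variances; inference is
Wald-type ($z$), with significance meaning the 95% CI excludes zero. The
fitting engine is `metafor::rma.mv()`, the standard tool for this model
class; `coral_meta()` wraps it in a compact S3 modelling object with
`print`, `summary`, `coef`, `confint`, `predict` and `plot` methods.

Numerical safeguards:

* a random factor observed at fewer than two levels is dropped with a
  message (its component is unidentifiable), so a single-genus data set
  automatically reduces to the single-factor model;
* `fixed_sigma2 = c(0, 0)` forces the closed-form inverse-variance
  fixed-effect mean, used as an oracle in the tests;
* `reml_loglik()` evaluates the restricted likelihood independently of the
  optimizer (direct Cholesky algebra), so the test suite can verify on a
  grid that the returned components are a REML optimum rather than trusting
  the fitting library.

Publication-bias support follows the usual practice:
`leave_one_study_out()` reruns the fit without each study and flags verdict
changes, and `funnel_data()` exports funnel coordinates with an
inside-95%-funnel flag using total variance $v_j + \sigma^2_{study} +
\sigma^2_{genus}$.

## Back-transformation and scenarios

A pooled activation energy maps to an expected percent change at a warming
of $\Delta T$ °C through

$$\text{change(\%)} = 100\,(e^{-E\,\Delta(1/kT)} - 1),$$

so positive $E$ gives a negative change (a decline), bounded below by
−100%. The CO~2~ analogue is
$100\,(e^{\mathrm{LnRR}\,\Delta p\mathrm{CO}_2/100} - 1)$. CI bounds are
back-transformed from the Wald bounds of the pooled effect; the exponential
is monotone, so the bounds keep their order. Note the sign conventions: the
transform is written here so that the direction of every projected response
matches the direction of the underlying effect size.

The degrees-to-$\Delta(1/kT)$ mapping (`fit_arrhenius_map()`) is either
*analytic* at a baseline control temperature — the default baseline of
27 °C is the midpoint of the 24–30 °C control envelope of tropical coral
experiments — or an OLS fit of observed $\Delta(1/kT)$ on $\Delta T$ across
a record table, which is how a heterogeneous data set with controls at many
temperatures defines the mapping. The analytic map is exact but curved in
$\Delta T$; a linear fit through data spanning several degrees deviates from
it by order $10^{-3}$ eV$^{-1}$, which propagates to well under a tenth of a
percentage point in projected change.

`min_significant_delta()` scans driver increments (defaults: 0.01 °C and
1 µatm steps, capped at 13 °C / 800 µatm — the envelope of the emulated
data set) for the smallest increment whose back-transformed CI excludes
zero. Because the back-transform is monotone, under the strict rule
(`precision_rule = "exact"`) the answer is degenerate: it is the first
scanned step whenever the pooled effect itself is significant, and does not
exist otherwise. Finite, informative thresholds arise only when CI exclusion
interacts with reporting precision, so a `"rounded"` rule (exclusion after
rounding the percent bounds to `digits` decimals) is provided as well.
Neither rule is claimed to be the one behind any previously reported
threshold — the exact procedure is not recoverable from published
descriptions — which is why both are exposed and the default is the strict
one.

`project_all()` crosses fitted strata with a scenario table (RCP x period
with `delta_T_C` and/or `delta_pco2_uatm`); scenario warming levels are
configuration inputs, not quantities the package derives from climate model
archives. The end-of-century CO~2~ increments (+63, +173, +276, +490 µatm
for RCP2.6/4.5/6.0/8.5) ship as `rcp_co2_scenarios()`.

## MHW detection

`mhw_threshold()` computes an empirical percentile (the linear-interpolation
estimator, `quantile type 7`) of all baseline days — thresholding against
the full pre-industrial distribution rather than a day-of-year climatology,
so any exceedance of historically extreme temperatures counts regardless of
season. A day-of-year climatology mode (11-day window) is available for
comparison. `mhw_events()` finds maximal runs of days above threshold with
no gap-joining (the simplest rule; configurable via `min_duration`, default
1 day so every exceedance day is counted; the conventional 5-day rule is one
argument away). Annual statistics attribute event-level quantities to the
start year and day counts to the year of each constituent day;
`mhw_envelope()` reduces several models' annual series to per-year
mean/min/max. Reproducing published multi-model ensemble trajectories is
out of scope — that requires the CMIP5 archive — but the detector and
statistics are exactly the algorithm those trajectories are built from, and
they are validated on synthetic series instead.

## What the generators emulate — and what they do not

`sim_experiments()` draws studies (default 40), each contributing a few
contrasts (default 3) on one genus from a pool (default 15), with conditions
inside the envelopes of the emulated corpus (controls 24–30 °C and 297–486
µatm; increments +0.5–13 °C and +100–800 µatm). Latent effects carry
normal between-study and between-genus deviations (defaults
$\sigma^2_{study} = 0.05$, $\sigma^2_{genus} = 0.02$ on the effect scale),
and each arm reports the sample mean/SD/n of lognormal replicates with CV
0.2 and $n$ of 4–8 — giving log-ratio sampling variances around 0.01–0.02,
typical of small physiology experiments. Defaults were set once, from the
descriptive statistics of the corpus being emulated, and are the conditions
under which the recovery suite runs: 200 replicates at a true $E$ of 1.0 eV
must cover the truth in at least 90% of fits with mean absolute error below
0.05 eV.

`sim_factorial()` perturbs multiplicative-null (or deliberately interacting)
quads with lognormal *mean-level* noise matched to the sampling noise of an
$n$-replicate mean, and reports the known replicate-level SD; under this
construction the delta-method CI of the interaction is calibrated, which is
exactly what the type-I test needs to interpret a 95% additive rate.
`sim_sst()` composes mean + seasonal sine + linear trend + AR(1) noise +
rectangular injected events on a 365-day model calendar.

What the generators do *not* emulate: the taxonomic composition of the real
corpus (87 species with strong *Acropora* dominance), correlations between
attribute responses within an experiment, non-lognormal outcome noise,
reporting and publication bias, and any spatial structure in SST. Passing
tests therefore demonstrate that the machinery is correct and calibrated
under the stated generating model — not that the real literature satisfies
that model.

## Numerical choices and degenerate inputs

* Kelvin conversion uses 273.15 exactly; $k = 8.617\times10^{-5}$ eV/K.
* $z = 1.96$ is fixed for the interaction CI; meta-analysis CIs use the
  exact normal quantile for the configured `alpha`.
* Effect-size computation refuses degenerate contrasts ($\Delta T = 0$,
  $\Delta p\mathrm{CO}_2 \le 0$), non-positive means, and $n < 2$;
  validation reports offending row numbers and either drops (lenient) or
  aborts (strict), with identical results on the valid rows.
* REML starting values are metafor's defaults; the grid oracle in the test
  suite guards the optimum independently of the optimizer.
* All randomness flows from explicit integer seeds; `run_pipeline()` is
  byte-identical across runs at the same seed.

Problem sizes in the validation suite — 200 recovery replicates of 120
effects, 2,000 null quads, 100 random SST series — were chosen as the
smallest sizes at which Monte-Carlo error is materially below the tolerances
being asserted (3 Monte-Carlo standard errors for the 95% additive rate).

## A worked example

```{r example}
sim <- sim_experiments(arm_types = "warming", true_E = 1.0, seed = 42)
eff <- effect_sizes(sim$records)
fit <- coral_meta(eff)
fit
predict(fit, delta_T = c(0.97, 1.94, 4.32))
```

The pooled estimate recovers the generating value of 1.0 eV within its CI,
and the projections decline monotonically with warming.

## Limitations

The projections inherit every assumption above: Arrhenius-form temperature
dependence within each contrast, log-linear CO~2~ dependence, known
sampling variances, and normal random effects. They are pantropical
averages — regional downscaling would require regional experiments — and
they take no account of acclimatization or adaptation. The
threshold-sensitivity search is as much a statement about reporting
precision as about biology; treat its `"rounded"` mode as descriptive, not
inferential.
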