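# coralMHW

Projecting the performance and survival of reef-building corals under
intensifying marine heatwaves (MHWs) and ocean acidification (OA).

Marine heatwaves — runs of days on which sea surface temperature exceeds a
high percentile (90th or 99th) of a pre-industrial baseline — are the
proximate trigger of mass coral bleaching, and they intensify together with
rising CO₂. coralMHW is for quantitative ecologists and meta-analysts who
want to turn a corpus of published warming and CO₂ experiments on corals
into scenario projections: expected percent change of a coral attribute
(symbiont density, chlorophyll *a*, photochemical efficiency,
photosynthesis, respiration, calcification, growth, survival) at the MHW
intensities and CO₂ increments expected under RCP emissions scenarios.

## The model in brief

Per experiment, warming contrasts are summarised by an Arrhenius activation
energy (eV),

    E = ln(V_o / V_i) / (1/(k T_o) − 1/(k T_i)),   k = 8.617e-5 eV/K,

(positive E = decline under warming), and CO₂ contrasts by a log response
ratio per +100 µatm,

    LnRR = (ln x̄_exp − ln x̄_cont) / ΔpCO₂ × 100.

Full-factorial experiments are classified additive / synergistic /
antagonistic from the standardized interaction
`(ln x̄_B − ln x̄_W − ln x̄_C + ln x̄_Cont) / 2s` and its 95% CI. Effect
sizes are pooled per attribute and driver context with a multilevel
random-effects meta-analysis (crossed study and genus intercepts, REML via
`metafor::rma.mv`, inverse-variance weights, Wald inference). Pooled
effects back-transform to percent change at a driver increment,

    change(%) = 100 (e^{−E·Δ(1/kT)} − 1)    and    100 (e^{LnRR·ΔpCO₂/100} − 1),

with CI bounds mapped through the same monotone transform; a scan over
increments finds the minimum warming / pCO₂ increase producing a
significant change. An MHW module detects percentile-exceedance events in
daily SST series and computes annual intensity/duration statistics with
multi-model envelopes. Synthetic-data generators with known ground truth
(`sim_experiments()`, `sim_factorial()`, `sim_sst()`) support end-to-end
validation of every stage.

## Worked example

Simulate a 40-study corpus of warming experiments on coral survival with a
true activation energy of 1.0 eV, pool it, and project declines at three
MHW intensities:

```r
library(coralMHW)

sim <- sim_experiments(arm_types = "warming", true_E = 1.0, seed = 42)
eff <- effect_sizes(sim$records)
fit <- coral_meta(eff)
fit
#> Multilevel random-effects meta-analysis (REML)
#>   attribute: survival  context: single_driver
#>   k = 120 effect sizes
#>   pooled estimate: 1.0167 eV (SE 0.0522), 95% CI [0.9144, 1.1189]
#>   z = 19.4926, p = 1.27e-84 (*)
#>   variance components: sigma2_study_id = 0.1035, sigma2_genus = 0.0000

predict(fit, delta_T = c(0.97, 1.94, 4.32))
#>   attribute       context        kind delta_T_C delta_pco2_uatm percent_change
#> 1  survival single_driver arrhenius_E      0.97              NA      -11.89343
#> 2  survival single_driver arrhenius_E      1.94              NA      -22.30918
#> 3  survival single_driver arrhenius_E      4.32              NA      -42.74900
#>      ci_low   ci_high significant
#> 1 -13.00810 -10.76448        TRUE
#> 2 -24.25634 -20.31196        TRUE
#> 3 -45.87125 -39.44665        TRUE
```

The pooled estimate (1.02 ± 0.05 eV) recovers the generating truth within
its CI, and the projected declines (−11.9%, −22.3%, −42.7%) deepen
monotonically with the configured MHW warming. `run_pipeline()` executes
every stage — effect sizes, interaction classification, meta-analyses,
scenario projections, sensitivity scan, MHW statistics — and writes one
tidy CSV per stage plus a JSON manifest, deterministically for a given
seed. A thin command-line wrapper with `simulate` / `effects` /
`interactions` / `meta` / `project` / `mhw` / `report` subcommands is in
`inst/scripts/coralmhw-cli.R`.

See the vignette (`vignettes/coral-mhw-projections.Rmd`) for the full
account of the model, its assumptions, the variance modes of the
interaction classifier, and what the synthetic generators do and do not
emulate.

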