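# erythroflux

Erythrocytes are more than passive oxygen carriers: their glycolytic and
redox metabolism tunes hemoglobin's oxygen affinity (via 2,3-bisphosphoglycerate
from the Rapoport–Luebering shunt), defends against oxidative stress (via
NADPH from the pentose phosphate pathway), and responds dynamically to
exercise. `erythroflux` is an R toolkit for analyzing this biology in
exercise crossover studies. It is aimed at exercise physiologists and
red-cell biochemists who have (or want to simulate) lactate incubation
assays, blood-gas/effector panels, and near-infrared spectroscopy (NIRS)
muscle-oxygenation traces.

## What it computes

**Ex vivo glycolytic flux.** Flux is proxied by the rate of extracellular
lactate accumulation in a washed 50%-hematocrit erythrocyte suspension:
for lactate concentrations \(L(t)\) at incubation times \(t = 0, 30, 60,
90\) min, the flux is the OLS slope \(\hat\beta\) of \(L = \alpha + \beta t
+ \varepsilon\), in μM/min. Condition-by-timepoint summaries, fold changes,
and glucose / H₂O₂ dose–response tables build on these fits.

**Stoichiometric yield ledger.** Glucose carbon is partitioned between
glycolysis, a single maximal-efficiency pass of the pentose phosphate
pathway (per 6 G6P: 12 NADPH, 1 glucose fully oxidized, 4 F6P + 2 GAP
regenerated), and the Rapoport–Luebering shunt (one 2,3-BPG per diverted
triose, bypassing the phosphoglycerate-kinase ATP step). The ATP ledger is
−1/glucose (hexokinase), −1/F6P (phosphofructokinase), +1/non-shunt triose
(phosphoglycerate kinase), +1/triose (pyruvate kinase); every completing
triose ends as lactate, so NADH nets to zero. Three presets (`control`,
`oxidative_stress`, `exercise`) encode the rest, oxidative-stress and
acute-exercise flux partitions; carbon balance is audited to a zero
residual.

**Oxygen dissociation curve and p50.** Hemoglobin saturation is a Hill-type
curve with a pO₂-dependent cooperativity exponent, anchored at a p50 that
is the standard 26.8 mmHg plus closed-form polynomial corrections for
deviations of plasma pH (7.40), pCO₂ (40 mmHg), 2,3-BPG (4.65 mM) and
temperature (37 °C) — lower pH or higher pCO₂/2,3-BPG/temperature
right-shift the curve.

**NIRS reduction.** 10 Hz three-optode O₂Hb/HHb traces are averaged across
optodes and reduced to a last-30-s rest baseline, ten 10%-of-exercise-duration
bins (30 s trailing windows), minute-wise occlusion values for the
5/5/3-min vascular occlusion protocol, and recovery values at 60/90/120 s.

**Synthetic study generator.** A seeded generator emulates the 20-participant
two-condition crossover (flux ~21 μM/min at rest, ×1.4 under oxidative
stress, ×2.74 / ×1.67 after arm exercise with recovery by 30 min; blood-gas
and NIRS shifts to match), so the full pipeline is testable end to end with
known ground truth.

## Worked example

```r
library(erythroflux)

# stoichiometric yields at rest: per 60 glucose
glance(compute_yields(scenario_preset("control")))
#> # A tibble: 1 x 8
#>   atp_net nadph nadh_net bpg23 lactate   co2 f6p_retained gap_retained
#>     <dbl> <dbl>    <dbl> <dbl>   <dbl> <dbl>        <dbl>        <dbl>
#> 1      94    12        0    24     118     6            0            0

# a simulated crossover study, and flux recovery from its lactate series
study <- generate_study(study_design(n_participants = 20, seed = 1),
                        include_nirs = FALSE)
est <- estimate_fluxes(study$lactate,
                       .by = c("participant", "condition", "timepoint"))
summ <- summarize_timecourse(est,
    timepoint_levels = c("baseline", "pre", "post0", "post10", "post30"))
dplyr::filter(summ, timepoint == "post0")
#> # A tibble: 2 x 10
#>   condition        timepoint     n mean_flux sd_flux missing se_flux fold_vs_baseline fold_vs_pre pct_vs_pre
#>   <chr>            <chr>     <int>     <dbl>   <dbl> <lgl>     <dbl>            <dbl>       <dbl>      <dbl>
#> 1 control          post0        20      59.4    7.50 FALSE      1.68             2.74        2.73      173.
#> 2 oxidative_stress post0        20      50.6    6.27 FALSE      1.40             2.32        1.67       67.0
```

The post-exercise cells recover the generating multipliers (2.74 and 1.67;
+173% and +67% versus pre-exercise) from the noisy lactate tables alone.

```r
# oxygen dissociation: rest vs exercise blood-gas states
rest <- blood_gas_state()                                  # p50 26.8 mmHg
exer <- blood_gas_state(ph = 7.2, dpg = 4.65 * 1.14, temp = 38.5)
delta_p50(rest, exer)
#> # A tibble: 1 x 4
#>   p50_a p50_b delta_p50 shift
#>   <dbl> <dbl>     <dbl> <chr>
#> 1  26.8  35.1      8.31 right shift
autoplot(build_odc_curve(exer))
```

The exercise state (acidosis, raised 2,3-BPG, 38.5 °C) right-shifts the
curve by ~8 mmHg — the physiological facilitation of oxygen unloading to
working muscle.

`run_pipeline(seed = 1)` chains every stage (flux, stoichiometry presets,
p50 shifts, NIRS summaries, hemoglobin audits) into one deterministic
report; `write_report()` serializes it to JSON.

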