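---
title: "Methods: erythrocyte glycolytic flux, yield stoichiometry, p50, and NIRS reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: erythrocyte glycolytic flux, yield stoichiometry, p50, and NIRS reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erythroflux)
```

This vignette is the package's own account of its models: what each stage
assumes, which parameters matter and why their defaults were chosen, where
the design was genuinely open, and what the synthetic-data tests do and do
not establish about real data.

## Ex vivo glycolytic flux

Erythrocytes rely exclusively on glycolysis for ATP, and essentially all
glycolytic carbon leaves the cell as lactate. The flux assay therefore
incubates a washed 50%-hematocrit suspension (buffer supplemented with
10 mM glucose) and measures extracellular lactate at 0, 30, 60 and 90 min;
flux is the slope of the OLS regression of lactate (μM) on time (min).

Design choices:

* **Plain OLS, not robust regression.** With four points per series a
  robust fit is underdetermined; the assay's published convention is a
  linear regression slope. `estimate_flux()` wraps `stats::lm()`; the
  grouped fast path `estimate_fluxes()` uses `stats::lm.fit()` with the
  standard slope-variance formula (tests pin both to the closed-form
  normal-equation solution at 1e-9).
* **Units.** μM/min of the 50%-hematocrit suspension. No per-cell
  normalization is attempted; fold changes are unit-free.
* **QC, not exclusion.** Fits with R² < 0.9 are flagged
  (`qc = "low_r_squared"`) but never dropped — there is no principled
  exclusion rule for a 4-point assay, and flagging preserves the balanced
  design. For a constant series (zero total variation, zero residual) R² is
  defined as 1: the line fits exactly.
* **Degenerate inputs** (< 3 points, < 3 distinct times, non-finite
  values) error with class `erythroflux_degenerate_input` rather than
  returning unstable estimates.
* **Fold changes on cell means**, not means of per-sample ratios, matching
  how group percentages are conventionally reported. The timecourse
  summary reports fold changes against both the condition's baseline and
  its pre-exercise cell; empty cells warn and propagate `NA` instead of
  failing.
* **Dose grids** for the exogenous challenges are fixed to the assay
  design (glucose 3.9/5.6/7.2/10 mM; H₂O₂ 0/5/10/20/40 μM on 10 mM
  glucose); off-grid doses are validation errors naming the grid. The
  trend diagnostic is the sign of the Spearman correlation between dose
  and fitted flux — monotonicity only, no dose–response model is imposed.

## Stoichiometric yield ledger

The scenario model is bookkeeping, not kinetics: it counts molecules for a
fixed partition of a glucose pool. A `scenario_config()` fixes the pool
size, the glycolysis/PPP split, the number of trioses diverted through the
Rapoport–Luebering shunt (RLS), and the fate of the sugars regenerated by
the PPP.

The PPP operates at maximal NADPH efficiency: each G6P yields 2 NADPH and
1 CO₂ in the oxidative phase, and the non-oxidative phase converts every 6
pentoses to 4 F6P + 2 GAP — equivalently, of 6 G6P in, 5 hexose
equivalents come back and 1 glucose is fully oxidized. Counts are
real-valued so any pool size scales linearly (the model is homogeneous of
degree 1; a property test checks this).

The ATP ledger: −1 per fresh glucose (hexokinase), −1 per F6P passing
phosphofructokinase (fresh glycolytic glucose plus any returned F6P), +1
per non-shunt triose (phosphoglycerate kinase), +1 per triose (pyruvate
kinase). Shunted trioses pass GAPDH (so 1,3-BPG is available to the
shunt), skip the PGK step, and continue through pyruvate kinase to
lactate. Because every completing triose is reduced to lactate, GAPDH's
NADH is exactly consumed by lactate dehydrogenase and the NADH ledger nets
to zero. Carbon is audited: 6 C per glucose must reappear as lactate
(3 C), CO₂ (1 C), or retained F6P/GAP; `carbon_balance()` reports the
residual, which is zero for every feasible configuration (property-tested
over random scenarios).

Genuinely open choices, and how they were settled:

* **F6P return mode.** Whether PPP-regenerated F6P re-enters glycolysis
  (paying the PFK ATP) or is retained (poised for further PPP cycling) is
  not derivable from the partition alone; it is an explicit flag. The
  `control` preset returns F6P; `oxidative_stress` and `exercise` retain
  it, consistent with running the PPP for maximal NADPH under stress.
* **RLS load as a count, not a fraction.** The three presets use 24, 20
  and 39 shunted trioses directly. Expressing these as a common fraction
  of trioses is impossible (they imply 20.3%, 23.8% and 21.7%
  respectively), so a direct count is the only faithful parameterization.
  "20% of glucose" diverting through the shunt is interpreted as both
  trioses of those glucose molecules (12 glucose → 24 2,3-BPG in the
  control scenario).
* **The exercise ATP discrepancy.** Under the documented ledger the
  exercise preset (180 glucose, 50/50 split, 39 shunted trioses, F6P
  retained) yields 111 net ATP, with 180 NADPH and 39 2,3-BPG. The
  historically reported 108 ATP for this scenario is not reproduced by
  either F6P return mode (return mode gives 291). No accounting we could
  construct yields 108 together with 39 2,3-BPG and 180 NADPH, so the
  preset reports the ledger's 111 and attaches an explicit `discrepancy`
  attribute rather than silently matching a number the model cannot
  produce.

The cross-tissue arithmetic helpers (`atp_turnover_scale()`,
`relative_rate()`) are deliberately trivial — documented, exact products
and percentages used for the erythrocyte-versus-muscle energetic
comparison (e.g. 1.50 mM/h × 3 = 4.5 mM/h; 4.5/18 000 = 0.025%).

## Oxygen dissociation curve and p50

The saturation model is the revised closed-form parameterization of the
Dash–Bassingthwaighte family. p50 is computed directly from additive
polynomial corrections — no root finding — in the deviations from the
standard state (plasma pH 7.40, pCO₂ 40 mmHg, 2,3-BPG 4.65 mM, 37 °C;
standard p50 26.8 mmHg):

$$p_{50} = 26.8 + \Delta_{\mathrm{pH}} + \Delta_{\mathrm{CO_2}} +
\Delta_{\mathrm{DPG}} + \Delta_{T}$$

with cubic polynomials in ΔpH and ΔT and quadratics in ΔpCO₂ and Δ[2,3-BPG]
(concentration in mol/L). Saturation is Hill-type with the model's
pO₂-dependent cooperativity exponent \(n(p\mathrm{O}_2) = 2.82 - 1.20
\cdot 10^{-p\mathrm{O}_2/29.25}\):

$$S(p\mathrm{O}_2) = \frac{(p\mathrm{O}_2/p_{50})^{n}}{1 +
(p\mathrm{O}_2/p_{50})^{n}}.$$

Because saturation is parameterized by the adjusted p50 itself,
\(S(p_{50}) = 0.5\) holds by construction to machine precision, and the
standard state returns exactly 26.8 mmHg. The test suite verifies the
implementation against an independently transcribed second copy of the
polynomials on a 5⁴ effector grid (625 states, 1e-9), and checks the
physiological sign pattern by finite differences: p50 rises with pCO₂,
2,3-BPG and temperature and falls with pH (the Bohr effect).

Conventions and edge handling:

* 2,3-BPG is accepted in mM; converting from assay units (often
  μmol/g Hb) is the caller's responsibility and must be done before
  calling the model.
* States outside the validity box (pH 6.8–7.8, pCO₂ 5–120 mmHg, 2,3-BPG
  1–10 mM, 30–43 °C) produce a warning and an `out_of_range` attribute
  rather than an error: post-exercise states legitimately sit near the
  edge, and a hard failure would make the pre/post comparison impossible.
* Printed per-condition p50 values from any particular study cannot be
  re-derived without that study's per-state pH and 2,3-BPG measurements;
  the package therefore validates the model by its fixed points, its
  monotonicities, and oracle equivalence, not by matching published
  condition means.

## NIRS trace reduction

All reductions are means over explicit sample windows on the 10 Hz grid;
every reported value is reproducible by a brute-force loop over samples
(the tests do exactly that on randomized traces).

* **Optode averaging** precedes everything: the three optodes sample
  different depths and their pointwise arithmetic mean is the analysis
  signal. Mismatched optode lengths are an alignment error.
* **Baseline** is the mean of the final 30 s of the rest phase (300
  samples); a rest phase shorter than 30 s is an error.
* **Decile bins.** Exercise durations differ between participants, so the
  exercise phase is normalized to ten reporting points at 10%…100% of its
  duration. Each bin is the mean of the 30 s window *ending* at its
  reporting point. Whether the original 30 s bins were trailing or
  centered is not specified anywhere we could find; trailing was chosen to
  mirror the baseline's last-30-s convention, and centered windows are
  available via `windows = "centered"`. Windows are half-open
  `(end − 30, end]` — exactly 300 samples at 10 Hz — and are clipped at
  the phase start for reporting points earlier than 30 s.
* **Recovery** values at 60/90/120 s are 30 s trailing-window means
  measured from the end of the exercise/occlusion phase (cuff release /
  exhaustion), the physiologically standard origin.
* **Occlusion mode** enforces the 5/5/3-min protocol within a fractional
  tolerance (default 5%) and reports minute-wise values (windows ending at
  each of minutes 1–5 of occlusion) plus the same recovery points.
* tHb is derived as O₂Hb + HHb at every summary point, never smoothed
  separately, so the tHb consistency identity holds exactly.

## The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known ground truth without any external data. Its defaults are the study
conditions the analysis assumes, not tuning knobs:

* 20 participants, two conditions in crossover (each participant carries
  one resting flux draw shared by both conditions), five timepoints.
* Resting flux 21.1 μM/min with a between-participant SD of 3 μM/min
  (~14% CV, a typical between-subject spread for a cellular flux
  phenotype). Oxidative stress multiplies flux by 1.4 from the
  pre-exercise timepoint; acute exercise multiplies the pre level by 2.74
  (control) or 1.67 (oxidative stress) at post-0. Post-10 sits at the
  geometric mean of pre and post-0 (the recovery is only characterized
  qualitatively between those anchors), and post-30 returns to the pre
  level.
* Lactate series: intercept + flux·t with independent Normal(0, 50 μM)
  assay noise per point. The participant-level intercept is drawn from
  N(200, 20) μM — residual extracellular lactate in the washed
  suspension. The positive intercept is load-bearing: concentrations
  cannot be negative, and the generator resamples negative draws, so an
  intercept within a few noise SDs of zero would truncate the error
  distribution at t = 0 and attenuate every fitted slope. At 200 μM
  (4 SD) the constraint is inactive and the OLS assumptions hold; a test
  documents the attenuation that appears when the intercept is forced to
  zero.
* Blood-gas panels: pO₂ 100 / pCO₂ 40 mmHg throughout; plasma pH 7.40
  falling to 7.20 at post-0 (a typical maximal-exercise acidosis);
  2,3-BPG 4.65 mM rising 14% (control) or 22% (oxidative stress) at
  post-0; temperature 37 → 38.5 °C. Half-sized shifts at post-10, full
  return at post-30.
* NIRS: per participant-condition, one exercise trace with exhaustion
  drawn uniformly between 480 and 900 s (so the decile binning is
  exercised across variable durations), O₂Hb falling 10 μM and HHb rising
  12 μM monotonically to exhaustion (HHb amplitude scaled by 0.926 under
  oxidative stress, the −7.4% condition effect), exponential recovery
  with τ = 40 s (back within ~1% of baseline by 3 min), and independent
  Gaussian optode noise of 0.5 μM per sample.

Everything is driven by the single `study_design()$seed` through a
restorable RNG scope, so identical seeds give bit-identical tables and the
caller's RNG state is never disturbed.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no biomarker covariance structure beyond the
mean shifts; no within-participant drift, batch or order effects; no
heteroscedastic or proportional assay noise; no movement artifacts,
optode-coupling drift or adipose-thickness attenuation in NIRS; no
dynamometry or gas-exchange outcomes. Parameter-recovery results certify
the estimators under the generator's assumptions, not the assay's
real-world error structure.

## Problem sizes and numerical tolerances

The test suite fixes its own scales: OLS oracle equivalence at 1e-9 on
random 3–10-point series; the p50 oracle grid at 5⁴ = 625 states (1e-9);
carbon-balance property tests over 50–100 random scenarios; the
replicate-slope check at 1000 series; and Monte-Carlo parameter recovery
at 20 participants × 100 simulated studies (NIRS generation disabled
there, since only the lactate tables feed the flux estimators), compared
within two Monte-Carlo standard errors of the mean. Recovery uses ratios
of cell means — the same estimator the reporting uses; in the crossover
the shared participant draws cancel in the ratio, so its finite-sample
bias is orders of magnitude below the Monte-Carlo resolution.

## Known limitations

* The yield model is static bookkeeping: no kinetics, no thermodynamic or
  enzyme-capacity constraints, and no partial PPP recycling modes beyond
  the binary return/retain flag.
* The saturation model omits CO₂ binding (HbCO₂), carbon monoxide and
  ferryl/methemoglobin corrections; `functional_hb()` and
  `methb_percent()` audit the latter's magnitude separately rather than
  folding it into the curve.
* Flux is per suspension volume; converting to per-cell rates would
  require the suspension hematocrit to be trusted sample-by-sample, which
  the assay does not guarantee.
* The NIRS reduction deliberately stops at window means: no chromophore
  separation, no muscle oxygen-consumption slope from the occlusion test.
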