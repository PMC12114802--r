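---
title: "Model and methods: 5-FU exposure and toxicity thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: 5-FU exposure and toxicity thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fupbpk)
```

## The question the package answers

5-fluorouracil (5-FU) has a narrow therapeutic window, and its monitoring
convention is built on the area under the concentration–time curve (AUC).
But the AUC compresses very different exposure histories into one number: a
large dose pushed in over two hours and the same cumulative exposure spread
over a day have comparable AUCs and radically different peak
concentrations. `fupbpk` provides the machinery to ask which
pharmacokinetic summary — AUC, peak concentration `Cmax`, steady-state
concentration `Css`, or an early "dynamic" concentration `Cdyn` — best
predicts toxicity: a whole-body PK model to turn dosing records into
concentration histories, the exposure metrics themselves, and a minimal
classifier to compare them as toxicity predictors.

## The PBPK model

The model is a perfusion-limited (flow-limited) physiologically based
pharmacokinetic model with nine tissue compartments — fat, liver, brain,
kidney, muscle, skin, vessel-rich tissue, skeleton and red marrow — plus
arterial and venous blood. Each tissue obeys

$$V_T \frac{dC_T}{dt} = Q_T\left(C_A - \frac{C_T}{P_T}\right),$$

where $V_T$ is the tissue volume (L), $Q_T$ the blood flow through it
(L/h), $C_A$ the arterial concentration and $P_T$ the tissue:blood
partition coefficient, so the venous outflow leaves at $C_T / P_T$. The
liver is the single eliminating organ: 5-FU is cleared almost entirely by
hepatic dihydropyrimidine dehydrogenase, which the model represents as a
Michaelis–Menten sink driven by the liver's venous-equilibrium
concentration $C_V = C_{liver}/P_{liver}$ (the well-stirred reading),

$$RAM = \frac{V_{max}\, C_V}{K_m + C_V},
\qquad V_{max} = 1221.7\ \mathrm{mg/h},\quad K_m = 11.7\ \mathrm{mg/L}.$$

Venous blood collects all tissue outflows plus the intravenous input;
arterial blood receives the summed tissue flow at venous concentration,
with lungs and heart treated as a zero-volume pass-through. Saturability is
the scientific crux: an infusion rate above $V_{max}$ has no finite steady
state, so concentration grows for as long as the infusion runs — which is
why a 2-h infusion of a "daily" dose (rate 1526 mg/h against a capacity of
1221.7 mg/h) is qualitatively different from the same exposure over 24 h.

### Parameters and their provenance

Volumes, flows and partition coefficients sit in
`default_physiology()`/`default_substance()` and can be overridden
individually or from a YAML/JSON file (`load_model_config()`). Choices that
the reference tables leave open were fixed as follows:

* **Body-weight scaling.** Only muscle ($0.40 \times bw$) and skin
  ($0.0371 \times bw$) volumes are written as body-weight coefficients in
  the parameter table; everything else, including all flows, stays at the
  73-kg reference values regardless of `body_weight_kg`. This literal
  reading reproduces the package's 49-kg worked example.
* **Flow bookkeeping.** The nine tissue flows sum to 390.0 L/h while the
  quoted cardiac output is 401.7 L/h. The model routes the venous-to-
  arterial transfer at the tissue-flow sum, which keeps compartment-level
  mass balance exact without inventing a shunt; the cardiac-output field
  is retained as metadata and an upper bound (tissue flows may not exceed
  it by more than 5%).
* **Blood volumes.** Not listed in the parameter table; taken as 5.3 L
  total at 73 kg (ICRP-style reference), split 1/3 arterial and 2/3
  venous, scaled linearly with body weight. The simulated peak of the
  worked example moves by under 2% across any plausible blood volume
  (3.6–5.3 L), so this choice is not load-bearing.
* **$K_m$.** Two values circulate for the pooled Michaelis constant, 11.1
  and 11.7 mg/L; the default follows the parameter table of record
  (11.7), and `substance_parameters(km_mg_per_L = 11.1)` or a config file
  restores the alternative.
* **Observed concentration.** "Plasma concentration" is read as the venous
  blood compartment with a blood:plasma ratio of 1 (protein binding is
  8–12%, and no ratio is given). Venous and arterial differ only
  transiently; at steady state both equal $C_V + rate/Q_{liver}$.
* **Boluses.** An iv bolus is realized as a 1-minute constant-rate
  infusion into venous blood, which avoids discontinuous initial
  conditions while being indistinguishable from an instantaneous input at
  the 0.1-h timescale of interest.

### Numerics

The equations are integrated with `deSolve::lsoda` (stiff-capable), with
the right-hand side compiled in C for the standard 9-tissue layout and an
exported R implementation (`pbpk_derivatives()`) kept as the readable
reference; the two are tested to agree to solver precision. Integration is
segmented at every dosing-event boundary so the input rate is constant
within a segment, and output is returned on a fixed grid — 0.01 h during
dosing and 0.05 h afterwards by default — so trapezoidal AUCs are exactly
reproducible. Tolerances default to `rtol = 1e-8`, `atol = 1e-10` mg/L.
Every simulation closes its mass balance (dose = amount in body + amount
metabolized) and errors out beyond a relative error of $10^{-3}$; in
practice the error is at rounding level. Cohort-scale runs
(`simulate_cohort()`, the synthetic generator) default to a coarser grid
(0.05/0.1 h), which changes AUCs of these smooth profiles by well under
0.1% while making thousand-simulation analyses cheap.

The analytic steady state (`steady_state_analytic()`) inverts the
Michaelis–Menten balance in closed form and serves as the independent
oracle for the solver: a 48-h infusion at 100 mg/h — dozens of effective
half-lives, the terminal half-life being on the order of an hour — must
plateau within 0.5% of it, and does.

## Exposure metrics

`pk_auc()` integrates the venous curve by trapezoids; the full-profile AUC
runs until the concentration falls below 0.1% of `Cmax` (the integration
horizon is otherwise unstated in the monitoring literature), which
truncates under 0.1% of the area. `css_observed()` averages the final 10%
of a constant-rate infusion and flags windows still drifting by more than
1%/h as `no_plateau`. `css_from_auc()` is the monitoring convention
$C_{ss} = AUC/\text{infusion time}$; applied to a whole-course AUC it
slightly overstates the plateau because the rise is included, and no
correction is applied — that is how the source AUC studies used it.
`fraction_of_steady_state()` and `predict_css_from_cdyn()` formalize the
early-sampling idea: one hour into a standard 24-h infusion the model
puts the venous concentration at ~52% of the plateau, so doubling a 1-h
sample forecasts `Css`, and thresholds of 1.5 and 3 mg/L at 1 h map onto
plateau thresholds of 3 and 6 mg/L.

## Cohort analysis and the decision stump

`simulate_cohort()` turns dosing records into per-patient `(Css, AUC)`
pairs. Infusions of at least 5 h report the plateau mean; shorter
infusions and boluses have no steady state, so their `css` column carries
the peak concentration with `no_plateau = TRUE` — a convention this
package states explicitly because published exposure–toxicity scatters
plot a single "simulated Css" per patient without defining it for boluses.

`binned_fraction()` tabulates the fraction of patients with an effect in
right-open 1-mg/L concentration bins anchored at 0 (the bin convention
implied by phrases like "between 3 and 4 mg/L").

`fit_stump()` is an exhaustive CART-style depth-1 tree over the two
features: every midpoint between consecutive distinct sorted values of
`Css` and of `AUC` is scored by Gini impurity decrease (entropy available
via `criterion = "information"`), minimum leaf size 1, ties broken toward
the concentration feature and then the smaller threshold. Depth 1 is the
point, not a simplification: the fitted object *is* the answer to "which
single test on which parameter best separates life-threatening toxicity".
The implementation is tested against a naive brute-force oracle on
hundreds of random datasets and cross-checked against `rpart` (maxdepth 1,
minbucket 1, cp ~ 0).

## Synthetic cohorts: what they emulate and what they do not

The two individual-level datasets behind the exposure–toxicity analyses
are not public, so `make_ma_like_cohort()` and `make_auc_study_like()`
generate cohorts with their published *structure*, and every pipeline
stage is exercised on those.

* **Ma-like dosing cohort** (`n = 138`: 86 life-threatening, 52 not).
  Dose rate and infusion duration are drawn log-uniformly over 50–2000
  mg/h and 0.25–96 h. Log-uniform is this package's choice where the
  source gives only ranges: it spreads regimens across orders of magnitude
  (bolus-like to multi-day), yields both classes in comparable numbers
  around the 6 mg/L boundary, and decorrelates `Css` from `AUC`
  (short-high vs long-low regimens), which is precisely the contrast the
  stump analysis needs. Each candidate is simulated through the PBPK
  model, labelled life-threatening iff its modeled `Css`/peak exceeds the
  true threshold (default 6 mg/L), label-flipped with probability 0.02,
  and accepted until the 86/52 composition is met. Deterministic per seed.
* **AUC-study-like dataset** (`n = 321`: 94 with non-life-threatening
  toxicity, 227 without, all at 1000 mg/m² per 24 h). Group AUCs are
  truncated-normal draws: toxic group mean ± SD 82.2 ± 21.8 mg·h/L;
  no-toxicity group 58.3 ± 21.0, truncated to 9.5–126.3. The published
  no-toxicity SD (68.1) is internally inconsistent with the published
  range and interquartile span at `n = 227` — a normal that wide truncated
  to that range is near-uniform and contradicts the IQR — so the default
  SD is the value the IQR implies under normality (21.0), and the
  published figure remains available as an override. A truncated normal
  (rather than lognormal) is used because the toxic group's mean and
  median nearly coincide.

What passing tests on these cohorts show is that the *pipeline* recovers
the structure that was put in — composition, group moments, a
concentration threshold near 6 mg/L — under realistic noise. What they
cannot show is anything about the real patients: the true joint
distribution of doses and durations, covariates such as DPD activity, and
the single published outlier (a life-threatening case at `Css` 4.2 mg/L)
are not reproducible from summary statistics.

A note on threshold recovery under label noise: with 2% label flips,
roughly 3 labels flip per cohort of 138. When a flip lands adjacent (in
rank) to the 6 mg/L boundary, the Gini-optimal split — correctly following
the labels it is given — settles one observed value outside the noise-free
gap. This happens in roughly 5–10% of seeds, is a property of
minimum-leaf-size-1 stumps under boundary-adjacent noise rather than of
the solver or generator, and is why the feature choice (`css` over `auc`)
is a far more stable readout than the exact threshold placement.

## Problem sizes and determinism

All simulation-based checks run at the sizes the analyses are stated for:
the patient case on the default fine grid, cohort analyses at `n = 138`
on the cohort grid, threshold-recovery sweeps over 100 seeded cohorts,
and AUC-group recovery at tenfold group size (`n = 940`). Every stochastic
function takes an explicit seed through its spec object, and pipeline
outputs are stamped with the seed and a configuration hash; reruns are
bit-identical.

## Known limitations

* One eliminating organ, one compound: no DPD pharmacogenetics, no
  metabolites or prodrugs, no circadian enzyme rhythm, no tumor
  compartment. DPD-deficient patients are outside the model's population.
* Partition coefficients are taken as given (the skin and muscle values
  are surprising for a compound this hydrophilic); they are overridable
  but no attempt is made to recompute them from physicochemistry.
* The inter-subject variability banding (`vmax_scale`) is illustrative: a
  multiplicative factor on $V_{max}$, not a calibrated population model.
* `css_from_auc()` on whole-course AUCs inherits the small upward bias of
  the convention it implements.
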