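---
title: "Methods: fuzzy simulation, soft sensing and recurrent forecasting of wine fermentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy simulation, soft sensing and recurrent forecasting of wine fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fermentforge models yeast alcoholic fermentation of (white) wine as observed
by in-tank sensors: biomass (g/L), sugar (g/L), CO₂, pH, temperature (°C)
and alcohol (g/L), sampled on a uniform grid (typically every 5 minutes over
21 days). It provides four connected pieces: oenological unit conversions, a
fuzzy phase-blended simulator that acts as the package's synthetic-data
source, a Mamdani fuzzy soft sensor that infers alcohol from the other five
channels, and a variable-depth stacked LSTM forecaster of future
fermentation measurements. This vignette explains the models, their
assumptions, the tunable parameters, and the design decisions taken where
the design was genuinely open.

## Unit conversions

For a must heavier than water the hydrometric chain is
SG = 145/(145 − °Bé), °Bx ≈ 1.8 °Bé and sugar (g/L) = °Bx × SG × 10.
CO₂ head-space readings in ppm convert to gas-phase mass concentration with
the factor 1.964×10⁻⁶ g/L per ppm (stored as a constant; it corresponds to
a molar volume of 22.414 L/mol, which the conversion chain does not state
explicitly). The dissolved concentration follows Henry's law,
C = kH·P·M×10⁻⁶ per ppm, with kH = 1.65×10⁻² mol/(L·atm) for CO₂ in white
wine at 20 °C and M = 44.01 g/mol, giving 7.262×10⁻⁷ g/L per ppm; the
dissolved factor is *computed* from kH and M rather than hard-coded, and a
test pins the agreement to four significant figures. Their ratio, ≈ 0.37,
says the dissolved CO₂ mass concentration is about 37% of the gas-phase
one at equilibrium.

Ethanol vapour converts via C = ppm × M/Vm(T) × 1/α with M = 46.07 g/mol,
Vm(T) = 24.45 L/mol × T/298.15, and partition coefficient α ≈ 2.5×10⁻⁴.
Taken literally this formula yields liquid-equivalent values orders of
magnitude above what head-space traces of 100–1000 ppm (0.5–5 mg/L in gas
mass terms) would suggest; α is therefore exposed as a setting and the
formula is implemented as printed rather than silently corrected — the
calibration of this correction factor is device-specific. Percent alcohol
by volume is C/(ρ×1000)×100 with ρ = 0.789 g/mL.

## The fuzzy fermentation simulator

The simulator is the package's synthetic-data source; no public dense
fermentation dataset exists at 5-minute resolution, so all training and
evaluation material is generated. Fermentation is described by four
canonical phases with fuzzy time memberships:

* lag: `trimf(t; 0, 0, 20)` — yeast acclimatisation, first ~20 h;
* exponential: `trapmf(t; 15, 20, 70, 80)` — vigorous growth and sugar
  conversion;
* stationary: `trapmf(t; 70, 80, 150, 170)` — growth slows, flavours
  develop;
* death/decline: `smf(t; 150, 336)` — nutrient depletion to the end of the
  campaign.

Each attribute has a closed-form expression per phase (the "rule chain"):
biomass grows as `X0(1 − e^{−t/τ})` in lag, sigmoidally as
`X0 + Xmax/(1 + e^{−r(t−tm)})` in the exponential phase (midpoint tm = 45 h),
declines linearly in stationary and exponentially (rate 0.005 1/h, anchored
at t = 200 h) in death. Sugar holds at S0, decays as `S0·e^{−ke·t}`,
relaxes to `30 + 50·e^{−0.02(t−100)}` and settles at 20 g/L. pH holds at
4.5, drops sigmoidally to ~2.7–3.2 and recovers slightly toward 3.0–3.5.
CO₂ is slaved to biomass with Gaussian-in-time burst envelopes peaking in
the exponential phase; alcohol is proportional to biomass with mild
sinusoidal modulation (0.15·X in exponential, 0.9·X in stationary, 0.8·X in
death). Temperature is a controlled 15 °C setpoint throughout.

Per-fermentation variability enters through uniform draws
Xmax ~ U(3, 4) g/L, r ~ U(0.25, 0.35) 1/h, S0 ~ U(200, 220) g/L,
ke ~ U(0.01, 0.02) 1/h, drawn once per curve from a child seed of the
master seed, making datasets bit-reproducible.

Design decisions worth knowing:

* **Phase blending.** Where memberships overlap (15–20 h, 70–80 h,
  150–170 h) the per-phase values are combined by a normalised
  membership-weighted average — the natural Takagi–Sugeno reading of a
  phase rule chain. One visible consequence: the stationary sugar
  expression, anchored at t − 100, exceeds the exponential-phase decay
  throughout the 70–80 h hand-over, so blended sugar bumps upward there
  before resuming its decline. This is a property of the published closed
  forms, implemented literally; tests assert monotonicity within pure-phase
  spans only.
* **Noise.** Gaussian per-sample noise for biomass, sugar, pH and
  temperature with phase-specific standard deviations (e.g. sugar: 0.5, 1,
  0.8, 0.3 g/L across the four phases); exponential noise for CO₂. The
  exponential term E(λ) is read as exponential with *mean* λ (the numpy
  `exponential(scale)` convention); reading λ as a rate would add mean-10
  noise to a lag-phase CO₂ signal of ~0.03, which is physically absurd.
  Noise is sampled independently per time point and attribute (no
  autocorrelation), after phase blending, with the per-phase scales blended
  by the same memberships. A `noise_mult` multiplier supports
  noise-inflation studies.
* **Alcohol source.** By default the alcohol channel comes from the
  deterministic rule-chain expressions; when a trained soft sensor is
  supplied, alcohol is inferred from the other five channels instead, and
  the choice is recorded in the curve's metadata.
* **Rate equations as diagnostic only.** The growth/consumption pair
  dX/dt = μX, dS/dt = −(1/Y)μX is implemented as a residual report
  (`ode_consistency_check`) rather than an integrator: the closed forms are
  the generative model, and no maintenance coefficient or integration
  protocol is specified for the rate form. The specific growth rate μ is
  backed out of dX/dt, so the biomass residual is ~0 by construction and
  the sugar residual measures departure from strict yield-coupled
  consumption.
* **Units.** The CO₂ channel carries the rule chain's native model units
  (peaks ~40 when biomass ≈ 3.5 g/L). These are not reconcilable with the
  g/L-per-ppm conversion chain, so the simulator emits them as-is under the
  neutral column name `co2`; conversions are applied only explicitly via
  the conversions module.
* Temperature defaults to the 15 °C setpoint of the rule chain (a 25 °C
  variant appears in the coarser phase-rule table); it is configurable.

What the generator does *not* emulate: sensor drift and recalibration
jumps, autocorrelated disturbances, stuck fermentations, temperature
excursions, or between-vintage composition effects. Tests passing on this
material demonstrate that the pipeline recovers structure the generator
put in; they do not certify performance on real tank data.

## Gaussian partitions and the alcohol soft sensor

Each attribute is partitioned into three fuzzy classes (low, medium, high)
with Gaussian membership functions built from data: with mean μ, median m,
sample standard deviation σ (denominator n − 1), dispersion
κ = max(σ, 0.01) and skewness adjustment δ = (μ − m)/κ, the calibrated
layout places centers at (min, μ, max + kd·δ) with kd = 1 and shared width
w = σ/k, k = 3 by default (k ∈ 1…10). The universe of discourse is widened
by the calibrated range offsets (low end min − 2·min, high end
max + 0.2·max). An alternative formula-style convention with centers
(min, m, max − δ) is selectable (`convention = "centers_eq"`); the
calibrated layout is the default because it is the one described as tuned
for minimum inference error. Note that δ is dimensionless yet added to a
center in attribute units; this is implemented literally as specified.

The soft sensor is a Mamdani system: five antecedent partitions (sugar,
pH, CO₂, biomass, temperature) and one consequent (alcohol). Because no
rule base is published, rules are induced from training curves by
Wang–Mendel grid learning: each sample votes for the rule formed by its
argmax class per attribute with weight equal to the product of the winning
memberships; per antecedent combination the consequent with the largest
accumulated weight survives, carrying the largest single-sample product as
its weight. Inference uses min for antecedent combination, max aggregation
and centroid defuzzification over a 201-point discretisation of the
consequent universe, followed by Gaussian smoothing of the inferred series
(σ = 2 samples).

Two numerical choices matter:

* **Implication.** With classical clipping (truncation) implication, weak
  firing strengths — common under min-composition of five narrow Gaussians
  — let the consequent Gaussians' tails dominate the clipped sets, and the
  centroid drifts toward the universe middle regardless of which class won.
  The package therefore defaults to scaling (product/Larsen) implication,
  which makes the centroid invariant to a common rescaling of the firing
  strengths; clipping remains available (`implication = "clip"`).
* **Coverage floor.** If no rule fires above 10⁻⁶ the sensor returns the
  consequent-universe midpoint and warns; out-of-universe samples are
  clipped to the universe before membership evaluation.

**Known limitation.** Three consequent classes bound the resolution of the
inferred alcohol series: within-class variation (e.g. the slow decline
through the death phase) maps to a nearly constant output, and the
exponential phase contains attribute-class combinations that occur with
both low and high alcohol, which grid learning must resolve by majority.
On held-out synthetic curves (train on 24 of 25, evaluate the 25th) the
sensor reaches R² ≈ 0.2 at nominal noise and degrades as noise is
inflated; resubstitution on noise-free hourly curves reaches ≈ 0.45. The
much higher agreement reported for real tank campaigns elsewhere is not
reproducible here because that data is not public; the held-out synthetic
property is the substitute the tests pin.

Temperature is included as an antecedent although it is near-constant; in
noise-free data its dispersion hits the κ = 0.01 floor and every sample is
confidently "medium", which is the graceful degeneration intended.

## The variable-depth LSTM forecaster

The forecaster maps a history window of nt = 288 five-minute steps (24 h)
of all k = 6 attributes to a forecast of the next pl = 288 steps.
Windows are cut at a configurable stride and min-max normalized per
attribute with bounds fitted on the training curves (values outside the
fitted range extrapolate beyond [0, 1]; no clipping). The architecture is
l stacked LSTM layers of nc cells (all but the last return full
sequences), a dense layer mapping the last hidden state to k·nc units
(ReLU), a dense layer to pl·k outputs, a reshape to (pl, k), and
optionally batch-normalization over the k output channels. The loss is
RMSE on normalized labels. Because no deep-learning backend is available
to R here, the model — the package's core contribution — is implemented
from scratch in C++ (RcppArmadillo): full backpropagation through time,
Adam (β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁷), Glorot-uniform initialisation with
forget-gate bias 1, and a private Mersenne-Twister stream so that a seed
fixes initialisation and shuffling exactly.

Interpretation choices where the architecture description is ambiguous:
the first dense layer reads the *last* LSTM state (nc values), not the
flattened sequence; "reduction factor of 25%" is read as
new = 0.25 × old; and output batch-normalization uses batch statistics in
training and running statistics at inference. nt is 288 (= 12 × 24
five-minute steps in 24 h); an alternative printed value of 255 is
inconsistent with its own parenthetical arithmetic.

**Training protocol.** Adam starts at 10⁻⁴; on a validation plateau
(patience 1 epoch, min_delta 10⁻⁵) the rate is multiplied by 0.25 down to
10⁻¹⁰; early stopping (patience 5) restores the best validation weights;
batch 32; at most 100 epochs; 20% validation split. Chunked continual
training partitions the window set into ordered chunks and trains them
sequentially *without* reinitialising weights — the observed decline of
per-chunk epoch counts under early stopping is the signature of this
continual scheme and is asserted on a three-chunk miniature in the tests.

**Auto-tuning.** Cells first: 10 unique candidates on a 32-step grid in
[32, 512], each trained as a 1-layer model for 10 epochs, minimum
validation RMSE wins, ties to fewer cells. Then depth 1–10 with the chosen
cell count. A min-max weighted layer penalty — the product of the
min-max-normalized RMSE and the min-max-normalized layer count — is
reported per depth candidate as a diagnostic of what accuracy each added
layer buys; selection itself follows minimum RMSE (a minimum-penalty mode
is available). Tuning-stage validation RMSE is reported on the raw
attribute scale by default (`raw_scale = TRUE`), which is the only reading
that reconciles tuning-stage loss magnitudes of ~10 with final normalized
losses of ~0.16 in the protocol this package follows; the normalized-scale
variant is a flag away.

**Problem sizes used by the tests and the acceptance script.** The
full-scale protocol (1200 fermentations, 12 chunks of 100) is deliberately
not rerun; the package's own evaluation uses a reduced replication chosen
to be informative on a single CPU: 12 seeded 21-day fermentations at 5-min
sampling, windows nt = pl = 288 at stride 48 (~1,380 windows), a 64-cell
2-layer model trained at most 15 epochs with batch 32 and Adam 10⁻⁴, and a
disjoint 20% held-out window set. Output batch-normalization is disabled
in this reduced protocol: its affine output parameters move at most ~lr
per Adam step, so within a 15-epoch budget they cannot reach the label
statistics and would dominate the error; at full scale (tens of thousands
of steps) this is immaterial. Unit tests use hourly curves and 24-step
windows for speed. The held-out normalized RMSE of the reduced replication
(≈ 0.06–0.08) sits comfortably inside the full-scale benchmark band
(≈ 0.16), as expected for noise-light synthetic material evaluated at
smaller scale; the tests assert only the benchmark bound, not the
band itself.

## Metrics

RMSE and R² are the shared measures; over multi-attribute windows the RMSE
is taken over the flattened residuals, and `evaluate()` reports the mean
of per-window RMSEs. R² requires non-constant actuals (TSS > 0) and may be
negative. `relative_reduction()` expresses a loss against a baseline in
percent.

## Degenerate inputs and edge behaviour

Constant attributes: partition construction widens a degenerate range by
κ and warns; min-max fitting widens a constant attribute's bounds by 10⁻⁹
and warns. Curves shorter than nt + pl are skipped with a warning during
windowing. Empty chunks are skipped. A curve whose step does not divide
its duration is rejected. Gaussian smoothing truncates its kernel at
4σ lags, renormalises to unit mass, and pads boundaries with the nearest
value, so constants pass through unchanged.
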