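---
title: "Methods: coupled exposure, GUTS-RED survival and collembolan population dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled exposure, GUTS-RED survival and collembolan population dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collempop)
```

`collempop` simulates the fate of a *Folsomia candida* population exposed to
one or several soil-applied pesticides. Four model layers are chained: a
predicted-environmental-concentration (PEC) module, a
toxicokinetic–toxicodynamic (TKTD) survival module of the GUTS-RED family,
mixture rules for multi-substance scenarios, and an individual-based
population model in a vertical soil column. This vignette documents the
model equations, the assumptions behind every design decision that was
genuinely open, the tunable parameters and their defaults, and what the
package's tests do and do not demonstrate.

## 1. Soil exposure

A single application of `rate` kg active substance per hectare, mixed
homogeneously into the top `d` cm of soil of dry bulk density `rho` g/cm³,
yields the initial concentration

$$PEC_0 = \frac{100 \, A (1 - f_{int})}{d[\mathrm{m}] \cdot \rho[\mathrm{kg/m^3}]} \quad [\mathrm{mg\,a.s./kg\,dry\,soil}],$$

where $f_{int}$ is the fraction intercepted by the crop canopy. Decline
follows single first-order kinetics with rate constant

$$k(T) = \frac{\ln 2}{DT_{50} \cdot f_{red}} \cdot Q_{10}^{(T - 20)/10},$$

evaluated daily against the scenario's temperature series; degradation
stops in frozen soil ($T \le 0$ °C). Multiple applications of the same
substance superpose linearly. With the standard verification inputs
(0.6 kg/ha, $DT_{50}$ = 92.1 d, 1.3 g/cm³, constant 20 °C) the model
reproduces the reference PEC table for 5 cm and 20 cm mixing depths to all
four printed decimals; the test suite asserts this.

Design decisions worth spelling out:

* **Time convention.** The PEC series is indexed by integer day and
  evaluated at day start; the application day carries the full undegraded
  $PEC_0$.
* **Reduction factor.** `reduction_factor` *multiplies* $DT_{50}$
  (a factor 2 halves the rate constant). The term "reduction factor for
  the degradation rate" is ambiguous in common usage, so the convention is
  stated in the documentation of `substance_properties()`.
* **BBCH input.** The crop growth stage feeds a canopy-interception
  lookup, not a growth-dependent degradation correction. The shipped
  default intercepts nothing (bare soil) — conservative, and exactly what
  the verification scenario assumes. Users supply crop-specific tables via
  `interception_fraction()`.
* **Temperature correction.** $Q_{10} = 2.58$ (the FOCUS default,
  equivalent to an activation energy of 65.4 kJ/mol) with reference 20 °C.
  At a constant 20 °C the correction is the identity, so the verification
  table is unaffected by this choice.
* **Penetration depth.** Pesticide is assumed present down to the mixing
  depth and absent below it, overridable via `penetration_depth`.
  Within-layer concentration gradients, leaching and metabolites are out
  of scope.

## 2. GUTS-RED survival

Toxicokinetics use the one-compartment scaled-damage equation
$\mathrm{d}C_i^*/\mathrm{d}t = k_e (C_s(t) - C_i^*(t))$, where the scaled
internal concentration $C_i^*$ carries external-concentration units
(mg/kg soil) and $k_e$ is the dominant rate constant. Within each
simulated day the external concentration decays exponentially at the
substance's degradation rate, which makes the step analytically solvable:

$$C_i^*(t+\Delta) = C_i^*(t)e^{-k_e\Delta} + C_{s,0}\frac{k_e}{k_e-k}\left(e^{-k\Delta} - e^{-k_e\Delta}\right),$$

with the limit $C_{s,0} k_e \Delta e^{-k_e \Delta}$ when $k_e \to k$. The
test suite checks this step against a Richardson-extrapolated explicit
Euler integration at $10^{-4}$ d resolution to $10^{-6}$ relative error.

Toxicodynamics follow the two canonical GUTS-RED variants:

* **Stochastic death (SD).** Hazard
  $h_z = k_k \max(0, C_i^* - z) + h_b$, survival
  $S_{SD}(t) = e^{-\int_0^t h_z \mathrm{d}\tau}$. The cumulative hazard is
  integrated with the trapezoidal rule on a sub-daily grid (default 10
  sub-steps/day, `substeps`), with $C_i^*$ evaluated analytically at every
  sub-step. Doubling the sub-step count changes survival by well under
  $10^{-4}$ on smooth profiles; the only error source is the hazard kink
  at the threshold crossing.
* **Individual tolerance (IT).** Thresholds are log-logistic with median
  $\alpha$ and shape $\beta$:
  $S_{IT}(t) = \left(1 - \frac{1}{1 + (\max_{\tau \le t} C_i^*(\tau)/\alpha)^{-\beta}}\right)e^{-h_b t}$.
  The running damage maximum is tracked on the same sub-daily grid.
  Survival freezes once the damage has peaked — the characteristic IT
  plateau — at exactly the tolerance CDF of the realised maximum.

The background hazard $h_b$ defaults to zero everywhere: the population
model provides its own density-dependent background mortality, and a
non-zero $h_b$ would double-count natural deaths. Standalone library use
may set $h_b > 0$.

## 3. Mixture rules

* **Independent action (IA / Bliss).** Per-substance survival
  probabilities at matched times are multiplied; equivalently effects obey
  inclusion–exclusion. Each substance's survival is computed from that
  individual's own exposure history.
* **Concentration addition (CA / Loewe).** Implemented as damage addition
  in toxic units: each substance's scaled internal concentration is
  converted to reference-substance equivalents (potency $z_{ref}/z_i$
  under SD, $\alpha_{ref}/\alpha_i$ under IT), summed, and run through the
  reference substance's toxicodynamics ($k_k$, $\beta$ from the reference).
  This is the standard GUTS-mixture construction. A plain-language account
  of CA sometimes describes "summing effects", which would instead be IA;
  we implement canonical concentration/damage addition, and pin the
  semantics with the sham-combination axiom: a substance mixed with itself
  at doses $a$ and $b$ predicts exactly the single-substance outcome at
  dose $a+b$ (asserted to $10^{-12}$ relative).

With one substance both rules reduce exactly to plain GUTS-RED.

## 4. The individual-based population model

The soil column is horizontally homogeneous and vertically heterogeneous:
`n_layers` layers of `layer_thickness` cm (default 30 × 1 cm, covering
both the 5 cm and 20 cm mixing-depth scenarios), each with temperature,
moisture and food values. Habitat suitability is the product of
trapezoidal preference memberships (temperature, moisture) and a
saturating food term. The default profile keeps temperature and moisture
constant and lets food decay exponentially with depth — a simple stand-in
for the surface concentration of organic matter.

Individuals are eggs, juveniles or adults. The life cycle is rule-based:
eggs hatch after `egg_development_days` (10), juveniles mature after
`juvenile_maturation_days` (21), adults lay `clutch_size` (10) eggs every
`reproduction_interval_days` (3) in their current layer, and individuals
die at `max_age_days` (240). These magnitudes are order-of-magnitude
placeholders for *F. candida* at 20 °C, deliberately exposed as
configuration: every structural test in the package depends on the rules,
never on these numbers.

**Density regulation.** Mobile stages (juveniles + adults) suffer a daily
background mortality $p = c \max(0, n/K - 1)$, zero at or below the
carrying capacity $K$ (200) and clipped at 0.99. The slope default
$c = 0.7$ was chosen analytically, not fitted: setting the lifetime
reproductive success $R_0(p) = 1$ under the default fecundity and
maturation schedule gives an equilibrium mortality $p^* \approx 0.14$/day,
and $c = 0.7$ places the corresponding equilibrium abundance
$K(1 + p^*/c)$ close to the nominal capacity. A pesticide-free run settles
into fluctuations around $K$ (asserted within ±20 % over the second half
of a 250-day run).

**Movement.** Each mobile individual daily considers staying or moving one
layer up or down (clipped at the column boundaries) and picks a candidate
with probability proportional to the candidates' habitat suitability;
when all three are unsuitable the choice is uniform. Eggs never move. Two
consequences are worth knowing: (i) the stationary distribution is
proportional to suitability *times* the local candidate-sum, so for an
interior suitability peak the population mode coincides with the best
layer, while directly at the column surface the clipped candidate set
shifts the mode by about one layer; (ii) the ±1-layer/day step size is a
modelling choice, not a measured dispersal rate.

**Exposure and death.** Every day each mobile individual reads the PEC of
its layer (zero below the penetration depth), advances its per-substance
damage state, and recomputes its mixture survival $S(t)$ — a
non-increasing, individual-specific trajectory, because movement histories
differ. Death sampling is inverse-CDF: each individual receives one
persistent uniform fate draw at creation and dies of the toxicant on the
first day $1 - S(t)$ exceeds it. This realises exact marginal cohort
survival under SD and is the literal meaning of IT (the draw is the
individual's tolerance quantile). A daily-redraw variant
(`redraw_fate_daily`) is available for sensitivity analysis only — it
compounds daily mortality and is *not* the default semantics. Eggs are
exempt from toxicant death; juveniles are exempt when
`include_juvenile_mortality` is off; and the last remaining alive adult
never dies of the toxicant (refugium rule), so the toxicant alone cannot
extinguish the simulated population.

**Event order.** Within a day: exposure update → survival update →
toxicant deaths → life cycle (ageing, age death, density mortality,
hatching, maturation, reproduction) → movement → recording. The order is
fixed and documented; one consequence is that a day's exposure reflects
the layer chosen the previous evening.

**Seeding.** The master seed lives in the scenario; iteration $i$ uses the
child seed $(\text{master} + 104729\,i) \bmod 2147483629$, so enlarging
the iteration count never changes earlier iterations, and identical
scenarios reproduce results files byte for byte.

## 5. Calibration

`fit_guts()` estimates GUTS-RED parameters from standard constant-exposure
survival tests by maximum likelihood. The likelihood is the standard
conditional-binomial form: deaths in each observation interval are
binomial with probability $1 - S(t_j)/S(t_{j-1})$, with $S$ from the exact
constant-exposure closed forms (`guts_survival_constant()`). Optimisation
is multi-start Nelder–Mead over log-parameters from stratified
(Latin-hypercube-style) starting points inside documented bounds;
confidence intervals come from a nonparametric bootstrap that resamples
replicates. Point estimates are all the simulator consumes downstream, so
no posterior machinery is needed; fit quality is reported as the maximised
log-likelihood and bootstrap spread without an adequacy verdict.

The synthetic-data generator `simulate_survival_experiment()` draws
individual death times by inverse-CDF sampling from the model survival
curve — the same sampling semantics the population engine uses. The
recovery harness (4 concentrations × 3 replicates × 20 individuals ×
21 days, 20 seeds per assumption) checks that true parameters fall inside
90 % bootstrap intervals at close to the nominal rate and that the median
relative error on $k_e$ stays within 25 %.

## 6. What the tests show — and what they cannot

The verification chain demonstrates: exact reproduction of the reference
PEC table; agreement of the TK step with a brute-force integrator;
closed-form correctness of both toxicodynamic variants and their
qualitative signatures (SD decays to zero under sustained exposure, IT
plateaus); mixture-rule axioms; parameter recovery from synthetic data;
and the coupling property that, with movement disabled and everyone inside
the mixed layer, cohort mortality in the population model is statistically
indistinguishable from the standalone GUTS prediction, while with movement
enabled the mean mortality can only fall below it (individuals spend time
below the penetration depth) with the per-individual maximum still
approaching the fully-exposed prediction.

None of this validates the model *against field data*. The life-history
defaults are uncalibrated placeholders; the synthetic survival tests share
their generating model with the fitter (they test recovery, not realism);
and sublethal endpoints (fertility, avoidance), species interactions, and
horizontal spatial structure are out of scope. The intended use is
comparative — ranking spray sequences or mixture assumptions under
identical population assumptions — not absolute prediction of field
abundances.

## 7. Problem sizes and runtimes

The shipped demonstrations and the test suite use deliberately modest
sizes: 100-day exposure horizons, 60-day cohort envelopes with 200
individuals and 3 seeds, 250-day baseline runs, and 20-seed recovery
harnesses with 40 bootstrap replicates. A 365-day, multi-iteration
scenario runs in seconds; the full acceptance computation completes in a
few minutes on one CPU.
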