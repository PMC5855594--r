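---
title: "Kinetic models and fitting methods in sprkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models and fitting methods in sprkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprkin)
```

## The scientific problem

Galectin-3 (Gal-3) is a β-galactoside-binding lectin whose affinity for
poly-*N*-acetyllactosamine glycans makes it a target for cancer diagnostics
and inhibitor design. Multivalent neo-glycoproteins — bovine serum albumin
decorated with 16–21 synthetic glycans — bind immobilized Gal-3 with
picomolar equilibrium dissociation constants, measured by surface plasmon
resonance (SPR). `sprkin` packages the quantitative machinery such a study
needs: forward simulation of sensorgrams under four kinetic models, double
referencing, global nonlinear fitting with model comparison, ELISA
dose-response analysis with cluster-glycoside-effect metrics, and the
Linear Interaction Energy (LIE) end-point free-energy estimate.

An important boundary: the experimentally fitted rate constants published
for this system were obtained from instrument sensorgrams that are not
redistributable, so they **cannot be re-estimated** by this package — they
are not reproducible without the raw instrument data. They enter `sprkin`
in exactly two roles: as generator inputs for synthetic validation data
(`table_fixtures()`), and as the basis of derived-quantity checks
(KD = kd/ka, relative potencies, fold differences) that the test suite and
acceptance script recompute.

## Kinetic models

All units are fixed package-wide: time in s, concentration in M, response
in RU, ka in M⁻¹s⁻¹, kd in s⁻¹.

**1:1 Langmuir.** A + L ⇌ AL with dR/dt = k~a~C(R~max~ − R) − k~d~R. During
association the closed form is

$$R(t) = R_{eq}\left(1 - e^{-(k_aC + k_d)t}\right),\qquad
  R_{eq} = \frac{k_aC\,R_{max}}{k_aC + k_d},$$

and dissociation decays exponentially at rate k~d~ from the end-of-injection
response. KD = k~d~/k~a~.

**Heterogeneous ligand.** Two independent immobilized site classes; the
response is the sum of two 1:1 terms with their own (k~a~, k~d~, R~max~).
This is the model that describes the reversed experimental setup, in which
a multivalent glycoprotein surface is probed with the lectin in solution
and lectin oligomerization produces two apparent site classes.

**Bivalent analyte.** The literature names this model without printing
equations, so the package adopts the standard biosensor convention with
statistical factors of 2 for the first attachment and last detachment:

$$\frac{dR_1}{dt} = 2k_{a1}C\,F - k_{d1}R_1 - k_{a2}R_1F + 2k_{d2}R_2,\qquad
  \frac{dR_2}{dt} = k_{a2}R_1F - 2k_{d2}R_2,$$

with free capacity F = R~max~ − R₁ − R₂ and observed response R₁ + R₂. The
second-step association constant k~a2~ is expressed per response unit
(RU⁻¹s⁻¹).

**Heterogeneous analyte.** Two analyte species compete for one shared
capacity: dR~i~/dt = k~ai~C~i~(R~max~ − R₁ − R₂) − k~di~R~i~ — the simplest
competitive form consistent with the model's name.

The two closed-form models are evaluated analytically; the two coupled
models are integrated with `deSolve::lsoda` at rtol 1e-8 / atol 1e-10,
chosen to out-resolve the 1e-6 relative tolerance at which the test suite
compares closed forms against independent integration. Integration is
split at the injection end so the concentration step never crosses an
adaptive step.

## Referencing

Array-format SPR instruments correct sensorgrams twice: the *interspot*
signal (unmodified surface exposed only to analyte flow — bulk
refractive-index shifts plus drift) and a *blank* (zero-concentration)
injection are both subtracted. `double_reference()` applies
`raw − interspot − blank` in one pass; the composition order is a package
decision since the instrument literature states both corrections without
their order. Grids must match exactly — no resampling is attempted, so
kinetic information is never silently smoothed. `zero_baseline()` removes
the mean of a pre-injection window. The generator emits a blank channel
that is already interspot-corrected (pure noise around zero), matching how
instrument software exports it.

## Global fitting

`global_fit()` shares rate constants and capacities across all curves of a
series and minimizes the pooled squared residual. Design choices:

* **Log-parameterization.** Rate constants are fitted as log10 values
  (they span decades), capacities and optional per-curve offsets linearly.
  Results are invariant to concentration-unit rescaling.
* **Bounds.** ka ∈ [1e2, 1e9] M⁻¹s⁻¹, kd ∈ [1e-6, 1] s⁻¹, Rmax up to 10×
  the largest observed response — the physically plausible biosensor range.
* **Multistart.** One data-driven heuristic start (k~obs~ from regressing
  dR/dt on R per curve, then ka and kd from k~obs~ versus C; kd refined
  from the dissociation tail), expanded into a small family of plausible
  second-event variants for the two-event models, plus Latin-hypercube
  candidates screened by a single residual evaluation — only the
  best-ranked candidates are polished by bounded Levenberg-Marquardt
  (`minpack.lm`). The screen-then-polish stage is what makes the weakly
  convex two-event surfaces tractable. All draws are seed-controlled.
* **Standard errors** come from the Jacobian-based covariance at the
  optimum with σ² = RSS/dof, transformed back to natural units by the
  delta method; KD errors propagate as
  se(KD) = KD·sqrt((se~ka~/ka)² + (se~kd~/kd)²). Published ± values are
  conventionally produced this way, but whether they are fit errors or
  replicate spreads is not stated in the source literature; the package
  reports fit standard errors and labels them as such.
* **Weighting.** Unweighted least squares: SPR noise is
  response-independent to first order.
* **Model comparison** uses AICc on the pooled residuals; candidates
  within 2 units tie and resolve to the fewer-parameter model. The
  published model choice was made on qualitative "reasonable fits"; AICc
  is a declared quantitative substitute, not an inference of intent.

Non-convergence after all starts raises a condition that still carries the
best candidate, so a caller can inspect a fit that stopped on the
iteration cap — which legitimately happens when a nested data set makes a
second site unidentifiable.

## ELISA analysis

Saturation curves are fitted to one-site specific binding,
S(c) = bg + S~max~c/(K~d,app~ + c): a single carbohydrate-recognition
domain titrated against immobilized multivalent ligand in excess, which
preserves the half-saturation reading of an apparent K~d~. Inhibition
curves use the four-parameter logistic with the Hill coefficient free in
[0.3, 5], because multivalent inhibitors plausibly depart from hill = 1
and fixing it would be an unprintable assumption. Both constants are
fitted on a log10 scale and reported in the unit of the input
concentrations.

The cluster glycoside effect is quantified by `relative_potency()`:
rp = IC50(monovalent glycan)/IC50(neo-glycoprotein) after conversion to a
common unit, and rp/m divides by the mean number of glycans per carrier.
Values of rp/m above 1 indicate a greater-than-additive multivalency gain.

## Linear Interaction Energy

`lie_free_energy()` computes ΔG = α·Δ⟨V~LJ~⟩ + β·Δ⟨V~el~⟩ between bound
and free ligand states with default α = 0.181, β = 0.3. When per-frame
energy trajectories are supplied, `lie_from_series()` averages the final
10 ns window (configurable) before applying the scaling — whether the
published scaling was applied to raw or block-averaged energies is not
stated, and for time averages of this form the two are identical. Running
or parsing the molecular-dynamics simulations themselves is out of scope;
only the end-point arithmetic on supplied energies is implemented.

## What the synthetic generator emulates — and what it does not

`generate_sensorgram_series()` emulates a parallel multi-concentration
injection on one surface: model trace + linear drift + square-pulse bulk
offset during injection + i.i.d. Gaussian noise, with paired interspot
(drift + bulk + independent noise) and blank (independent noise) channels.
Defaults are chosen once as realistic study conditions:

* noise sd 0.5 RU (SPR) and 0.02 absorbance units (ELISA) — typical
  short-term instrument noise, large enough to make recovery nontrivial;
* schedule 120 s association, 600 s dissociation, dt 0.5 s — a
  dissociation window long enough to constrain kd ≈ 1e-4 s⁻¹;
* analyte ladders of 5 two-fold dilutions from 250 pM for the
  immobilized-lectin setup (the sub-nanomolar KD regime) and from 250 nM
  for the nanomolar positive-control regime, spanning the printed
  16–250 nM window;
* ELISA designs of 12 two-fold dilutions bracketing the true constant;
* drift and bulk default to 0 and are switched on explicitly in
  referencing tests.

The generator does **not** emulate mass-transport limitation,
regeneration-cycle carryover, spikes/air bubbles, plate-layout effects, or
instrument-specific binary formats. Passing tests therefore demonstrate
statistical correctness of the estimators under the declared noise model,
not robustness to every artifact of real instrument data.

## Validation problem sizes

The test suite closes the generator→fitter loop at these sizes, stated
here as the package's own validation design: noise-free recovery for all
four model kinds (closed-form kinds to 0.1%, integrated kinds to 1% on a
coarser 3-concentration, 3 s grid); ±3 SE coverage of ka and kd in 100
seeded noisy replicates per published rate-constant regime; AICc selection
of the generating model in 100 replicates each for 1:1 data and for
two-site data with KD1/KD2 = 100 and equal capacities; and ELISA
recovery over 200 replicates at the 30 nM K~d~ / 137 µM IC50 regimes.

## Known limitations

* Mass-transport-limited and conformational-change models are not
  implemented.
* Two-event model parameters are only weakly identified when the second
  event contributes little signal; the multistart reports the best
  candidate but the covariance can be near-singular (errors reported as
  NA).
* The heuristic start assumes approximately 1:1 shape; pathological
  multi-phasic data rely on the Latin-hypercube screen.
* Printed-table potency ratios can be recomputed only to the precision of
  the printed inputs; one-decimal columns limit agreement to their
  rounding half-ulp.
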