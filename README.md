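# sprkin

Binding kinetics of lectin–glycoconjugate interactions from SPR and ELISA
data.

## What it is for

Quantitative workers characterizing high-affinity protein–carbohydrate
interactions — such as galectin-3 binding multivalent poly-LacNAc
neo-glycoproteins — need to go from raw biosensor and plate-assay readouts
to rate constants, affinities and multivalency metrics. `sprkin` covers
that path:

* **Kinetic models.** Forward simulation of surface plasmon resonance
  (SPR) sensorgrams under four models: 1:1 Langmuir
  (A + L ⇌ AL, closed form `R(t) = Req·(1 − e^−(kaC+kd)t)` with
  `Req = kaC·Rmax/(kaC + kd)`), heterogeneous ligand (sum of two
  independent 1:1 sites), bivalent analyte and heterogeneous analyte
  (adaptive ODE integration). `KD = kd/ka` with first-order error
  propagation.
* **Referencing.** Interspot + blank double referencing
  (`corrected = raw − interspot − blank`) and pre-injection baseline
  zeroing, with strict grid checking and no resampling.
* **Global fitting.** Rate constants shared across a multi-concentration
  series; bounded Levenberg–Marquardt in log-parameter space with a
  data-driven heuristic start and a screened Latin-hypercube multistart;
  Jacobian-based standard errors; AICc model comparison.
* **ELISA.** One-site saturation fits (apparent Kd) and four-parameter
  logistic inhibition fits (IC50, free Hill coefficient), plus the cluster
  glycoside effect: relative potency
  `rp = IC50(glycan)/IC50(neo-glycoprotein)` and per-glycan potency
  `rp/m`.
* **Linear Interaction Energy.** `ΔG = α·Δ⟨V_LJ⟩ + β·Δ⟨V_el⟩`
  (defaults α = 0.181, β = 0.3), with tail-window averaging of energy
  trajectories.
* **Synthetic data.** A seeded generator emulating multi-concentration
  association/dissociation experiments with interspot/blank channels,
  drift, bulk offsets and Gaussian noise, and ELISA dose-response curves —
  the basis of every statistical validation in the test suite.

The published rate constants of the galectin-3/neo-glycoprotein system are
bundled as a provenance-annotated fixture table (`table_fixtures()`). They
were fitted from instrument sensorgrams that are not redistributable, so
the package uses them only as generator inputs and as the inputs of
derived-quantity checks — it cannot, and does not claim to, re-estimate
them from real data.

## Worked example

Simulate the strongest published ligand regime (ka = 5.9×10⁶ M⁻¹s⁻¹,
kd = 8.5×10⁻⁵ s⁻¹, five two-fold dilutions from 250 pM, 0.5 RU noise),
double-reference it, and refit:

```r
library(sprkin)

p <- kinetic_params("langmuir_1to1", ka1 = 5.9e6, kd1 = 8.5e-5, Rmax1 = 100)
set <- generate_sensorgram_series(p, serial_dilution(250e-12, 2, 5),
                                  phase_schedule(),
                                  noise_spec(sd = 0.5, seed = 20260926))
fit <- global_fit(reference_set(set), "langmuir_1to1",
                  fit_options(starts = 4, seed = 1))
fit
#> Global kinetic fit [langmuir_1to1]
#>   ka1    = 5.363e+06 (se 3.42e+05)
#>   kd1    = 7.816e-05 (se 7.13e-06)
#>   Rmax1  = 109.1 (se 6.52)
#>   KD  = 1.457e-11 M (se 1.62e-12)
#>   RSS = 5396.93 over 7205 observations (3 parameters)
```

The fitted KD of 1.46×10⁻¹¹ M recovers the generating value
(kd/ka = 1.44×10⁻¹¹ M, ~14 pM) well within one propagated standard error;
ka and kd individually sit within 2σ of truth, as expected for a single
noisy realization.

Multivalency metrics and the LIE estimate are one-liners:

```r
relative_potency(42, 2026, 17)   # IC50s: glycan 42 uM, neo-glycoprotein 2026 nM
#> Relative potency: IC50(glycan) = 42 uM, IC50(neo) = 2026 nM, m = 17
#>   rp = 20.73, rp/m = 1.219

lie_free_energy(-100, 0, -50, 0)
#> [1] -33.1
```

An `rp/m` near 1 means the 17 conjugated disaccharides contribute no more
than additively — no cluster glycoside effect — whereas values ≫ 1 (up to
~31 per glycan in this ligand series) mark strong multivalent enhancement.

A command-line wrapper with `simulate`, `fit`, `compare-models`,
`elisa-fit`, `potency`, `lie` and `fixtures` subcommands is installed at
`inst/scripts/sprkin` (see `?cli_run`).

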