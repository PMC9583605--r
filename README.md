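# mcpafate

Millimeter-scale aggregation of pesticide-degrading microbes controls how
fast the phenoxy herbicide MCPA disappears from soil, how long it stays
detectable at depth, and how much of it leaches below the topsoil.
`mcpafate` is a scenario-analysis package for quantifying these effects in
an unsaturated, layered soil column. It is aimed at environmental
microbiologists and soil modellers who want to explore how spatial
degrader heterogeneity (and its interaction with precipitation) propagates
to column-scale pesticide fate.

The model couples:

- **variably saturated flow** — the Richards equation with van
  Genuchten–Mualem soil hydraulics,
  `Se = (1 + (α|h|)^n)^(−m)`, `K = Ks·Se^l·(1 − (1 − Se^(1/m))^m)²`,
  in a three-layer Luvisol profile, free drainage at depth, and spin-up to
  steady state under the mean net infiltration rate (0.56 mm/d);
- **reactive transport of MCPA** — advection–dispersion with
  Millington–Quirk unsaturated diffusivity `Ds = Dm·θ^(10/3)/θs²`,
  equilibrium Freundlich sorption `C_S = K_F·C_L^nF`, and Monod
  biodegradation `R = μmax·ρb·B·C_L/(K_M + C_L)` by an immobile degrader
  field `B`;
- **stochastic degrader fields** — a log-Gaussian Cox process (exponential
  correlation, FFT circulant embedding, Poisson thinning to gene counts)
  calibrated so ensembles match observed spatial statistics: topsoil CV of
  16 % (LOW), 161 % (HIGH) or 400 % (EXTR) and a semivariogram practical
  range of 27 ± 2 mm;
- **scale-transition diagnostics** — the macroscopic degradation rate
  decomposed as `R̄ = MFA + COV + VAR + ΣHOT`, where the mean-field
  approximation (MFA) is the perfectly mixed rate and the covariance term
  COV quantifies the slowdown caused by substrate–degrader
  anticorrelation.

Scenarios cross four heterogeneity levels (HOM/LOW/HIGH/EXTR) with two
precipitation regimes (continuous light rain, CLR; heavy rain events,
HRE), after a single 2 kg/ha MCPA application.

## Worked example

A homogeneous full-depth column under the heavy-rain-events regime:

```r
library(mcpafate)

mesh <- preset_mesh("column")          # 0.3 m x 2 m, single-column (1D)
ws   <- spin_up(mesh, 0.56)            # steady state at 0.56 mm/d
topsoil_saturation(ws, mesh)
#> [1] 82.5

run <- simulate_scenario(mesh, hom_field(mesh$width, 0.9),
                         build_precip("HRE"), t_end = 40, initial = ws)
dis <- depth_interval_series(run, interval = 0.1)
detectability_duration(dis$times, dis$C_T[, 3], threshold = 3e-3)
#> [1] 22.6
dt50(run)
#> [1] 3.5
mass_balance_error(run)
#> [1] 4.8e-08
```

The spin-up settles the topsoil at 82.5 % saturation (≈ −0.005 MPa). The
two 40 mm/d rain events flush MCPA down to the 20–30 cm interval, where
it stays above the 3 µg/kg detection threshold for ~23 days; half of the
applied dose is degraded within 3.5 days; the solute mass ledger closes
to 5 × 10⁻⁸.

A stochastic extreme-heterogeneity field and its rate decomposition:

```r
f <- sample_field(default_lgcp("EXTR"), width = 0.3, depth = 0.3, seed = 1)
field_metrics(f)     # per-realization CV 444 %, CR 93.9 %, range 31.4 mm
```

For a field with substrate depleted at degrader hotspots, `decompose()`
reports (µmol C/m³/d) `R_bar = 3263`, `MFA = 10200`, `COV = -6560`,
`VAR = -94`, `HOT = -285` — the perfectly mixed rate overestimates the
macroscopic rate threefold, and almost all of the deficit is carried by
the negative substrate–biomass covariance.

## The analysis workflow

Numbered drivers under `analysis/` run the analysis stages and write
tables under `results/`:

1. `01_degrader_fields.R` — field ensembles and their CV/CR/range metrics;
2. `02_hydraulics.R` — spin-up profile and saturation dynamics under both
   precipitation regimes;
3. `03_scenarios.R` — desk-preset scenario ensembles: depth-resolved
   residual concentrations, detectability, leaching, DT50;
4. `04_scale_transition.R` — decomposition of the macroscopic topsoil
   rate into MFA/COV/VAR/HOT per scenario;
5. `05_full_scale.R` — the full-geometry, one-year, 100-realization
   configuration (long-running; run scenario by scenario).

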