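# pbrsim

Coupled light, flow and growth simulation for flat-panel photobioreactors,
with estimators that recover kinetic, optical and LED-calibration
parameters from light-staircase experiments.

## What it is for

Bench-scale flat-panel photobioreactors grow phototrophic cultures (here a
*Synechocystis*-like cyanobacterium) under LED illumination with
turbidostat control: the instrument dilutes the culture whenever OD730
leaves a narrow band (0.4 ± 2.5%) and reports the growth rate from the
ln(OD) slope between dilutions. The light a cell actually receives differs
from the software setpoint for two reasons: (i) the **LED calibration** —
whether the panel was tuned with the sensor on the panel (case 1) or 1 cm
away (cases 2–3, five-point averaged or central-only) — rescales the
emitted intensity; and (ii) the vessel itself — glass, medium, bubbles,
probes, steel and above all the biomass — absorbs and scatters the beam.
`pbrsim` models the whole chain so these effects can be quantified and the
kinetic constants inferred from an experiment can be interpreted on the
right irradiance scale. It is aimed at bioprocess modellers and
quantitative microbiologists who run (or re-analyse) staircase
photo-physiology experiments.

The package provides:

- **Radiative transfer**: an analytic two-flux solver for layered media
  (`solve_two_flux_1d()`, `panel_light_1d()`) and a 3-D discrete-ordinates
  solver over the vessel cavity with isotropic scattering and opaque
  internals (`solve_dom_grid()`), plus per-domain light budgets
  (`domain_light_budget()`). Biomass attenuation follows
  `kappa(X) = a X^b`, calibrated to 1.34 m⁻¹ at 0.1 gDCW/L and
  4 m⁻¹ at 2 gDCW/L.
- **Hydrodynamics**: an exactly divergence-free prescribed circulation
  (stream-function roll + stirrer vortex; `flow_field()`,
  `velocity_at()`, `divergence_check()`).
- **Lagrangian cell tracking** with Stokes drag, buoyancy and elastic
  pair forces, recording per-cell perceived/absorbed light
  (`trace_particles()`, `sample_light_history()`).
- **Growth & control**: the Haldane photo-growth law
  `mu(I) = mu_max I / (K_I_S + I + I²/K_I_i)`, a lumped dissolved-oxygen
  balance, turbidostat dilution, and the coupled staircase simulation
  (`simulate_culture()`).
- **Estimation**: multi-start fitters for the Haldane constants, the
  absorption power law and the calibration factors (`fit_haldane()`,
  `fit_absorption_law()`, `fit_calibration_factors()`), with broom-style
  `tidy()`/`glance()` methods.
- **Synthetic campaigns** with known ground truth
  (`campaign()`, `generate_campaign()`), photosynthetic-efficiency
  accounting (`efficiency_table()`), ggplot2 `autoplot()` methods, a YAML
  configuration layer and a CLI (`inst/cli/pbrsim`).

## Worked example

Simulate the seven-step staircase (50–1,200 µE, 24 h holds) under
calibration case 2 with the case-2 kinetic constants, then look at the
growth response and efficiency:

```r
library(pbrsim)

kin <- kinetic_params_case(2)     # mu_max 0.221 h^-1, K_I_S 43.32, K_I_i 114.9 W m^-2
sim <- simulate_culture(c(50, 100, 200, 300, 500, 950, 1200), kin,
                        calibration_case = 2)
dplyr::select(sim$results, setpoint_uE, I_eff_Wm2, mu_obs_h, dO2, I_out_mean_uE)
#>   setpoint_uE I_eff_Wm2 mu_obs_h   dO2 I_out_mean_uE
#> 1          50      10.7   0.0431  107.          53.5
#> 2         100      21.5   0.0689  111.         107.
#> 3         200      42.9   0.0927  115.         214.
#> 4         300      64.4   0.0990  116.         321.
#> 5         500     107.    0.0945  115.         535.
#> 6         950     204.    0.0740  112.        1017.
#> 7        1200     257.    0.0648  110.        1285.
```

Reading the table: `I_eff_Wm2` is the volume-averaged irradiance inside
the culture (well below the panel output because the biomass absorbs),
`mu_obs_h` is the growth rate re-estimated from the simulated OD slope —
it rises through photo-limitation, peaks near the Haldane optimum
(`sqrt(K_I_S·K_I_i) ≈ 70 W m⁻²` effective) and falls under
photo-inhibition; dissolved oxygen tracks the same shape. Efficiency
(gDCW per mol photons) decreases monotonically with setpoint and is higher
when only liquid-phase losses are counted:

```r
eff <- efficiency_table(sim)
tidyr::pivot_wider(eff[, c("setpoint_uE", "variant", "efficiency_g_mol")],
                   names_from = variant, values_from = efficiency_g_mol)
#>   setpoint_uE whole_reactor liquid_phase
#> 1          50         3.20         4.87
#> 2         100         2.56         3.89
#> 3         200         1.69         2.57
#> 4         300         1.24         1.89
#> 5         500         0.699        1.06
#> 6         950         0.292        0.443
#> 7        1200         0.202        0.307
```

Fit the Haldane constants back from noisy synthetic observations:

```r
I <- microE_to_wm2(c(50, 100, 200, 300, 500, 950, 1200))  # 636 nm
set.seed(42)
obs <- data.frame(I_Wm2 = rep(I, 3),
                  mu_h = rep(growth_rate(I, kin), 3) * exp(rnorm(21, 0, 0.02)))
fit <- fit_haldane(obs, seed = 1)
tidy(fit)
#>   term   estimate unit
#> 1 mu_max    0.214 h^-1
#> 2 K_I_S    40.9   W m^-2
#> 3 K_I_i   121.    W m^-2
```

With 2% noise a single dataset lands within a few percent of the
generating constants (0.221, 43.32, 114.9); medians over repeated datasets
converge tighter. `autoplot(fit)`, `autoplot(sim)` and
`plot_light_budget()` visualise each result type.

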