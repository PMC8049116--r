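---
title: "Modelling light, mixing and phototrophic growth in a flat-panel photobioreactor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling light, mixing and phototrophic growth in a flat-panel photobioreactor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbrsim)
```

## The system and the modelling problem

`pbrsim` simulates a bench-scale flat-panel photobioreactor (PBR): a thin
glass vessel (0.11 m wide, 24 mm deep along the light path, ~0.20 m tall,
380 ml working volume) illuminated from one face by an orange-red LED panel
(636 nm), sparged with gas, stirred by a small anchor bar at the bottom, and
run as a turbidostat that holds the optical density of a cyanobacterial
culture at OD730 = 0.4 ± 2.5%. The scientific question the package is built
around is a metrological one: the *calibration* of the LED panel — where the
light sensor sits when the panel is tuned to a software setpoint — changes
the light the cells actually receive, and therefore every "physiological
constant" inferred from the experiment. Three calibration cases are
modelled: the sensor on the panel (case 1), at 1 cm averaged over five
positions (case 2), and at 1 cm at the central position only (case 3).
Cases 2–3 force the panel to emit more to reach the same reading, so at an
identical setpoint the culture in case 1 sees less light.

The package couples four submodels, each exposed as ordinary functions on
data frames so the pieces can be used and tested separately:

1. **Radiative transfer.** A two-flux (forward/backward stream) solver for
   layered media, and a 3-D discrete-ordinates (DOM) solver over the vessel
   cavity with isotropic scattering, opaque internals (O2/pH probes,
   sparger) and a single glass-interface reflectance. The culture's
   absorption coefficient grows with biomass as a power law
   `kappa(X) = a X^b`, calibrated so that `kappa(0.1) = 1.34 m^-1` and
   `kappa(2) = 4 m^-1` (gDCW/L).
2. **Hydrodynamics.** A prescribed, exactly divergence-free circulation
   field: a stream-function roll in the width–height plane (the
   sparger-driven loop) plus a compactly supported azimuthal vortex around
   the stirrer axis. This is a deliberate surrogate for a CFD solution; it
   reproduces plausible circulation times (tens of seconds), not the true
   velocity field.
3. **Particle tracking.** Newtonian cell transport with Stokes drag,
   gravity/buoyancy and optional linear-elastic pair forces; each cell
   records the light it perceives (`I_p`, interpolated from the radiative
   field) and absorbs (`I_ab = alpha_cell I_p`).
4. **Growth and control.** A Haldane/Andrews photo-growth law, a lumped
   dissolved-oxygen balance, turbidostat dilution, and estimation of the
   growth rate from the ln(OD) slope between dilutions — the same estimator
   the instrument uses.

On top sit estimators (`fit_haldane()`, `fit_absorption_law()`,
`fit_calibration_factors()`) and a synthetic-campaign generator so that
every estimator can be validated against known ground truth.

## The growth law

Growth responds to irradiance `I` (W m^-2) through the Haldane/Andrews
substrate-inhibition form

$$\mu(I) = \frac{\mu_{max}\, I}{K_{I,S} + I + I^2/K_{I,i}},$$

which captures photo-limitation at low light, photo-saturation around the
optimum $I^* = \sqrt{K_{I,S} K_{I,i}}$ (where
$\mu = \mu_{max}/(1 + 2\sqrt{K_{I,S}/K_{I,i}})$), and photo-inhibition
beyond it. This algebraic form is a modelling choice: the three fitted
constants are named for exactly these three regimes, and the
substrate-inhibition literature the fitting approach derives from uses this
form, but other three-parameter photoinhibition laws exist. The packaged
parameter sets (`kinetic_params_case()`) are the constants apparent under
each calibration case — the same culture yields different constants because
each calibration implies a different irradiance scale:

```{r}
purrr::map_dfr(1:3, function(cs) {
  k <- kinetic_params_case(cs)
  tibble::tibble(case = cs, mu_max = k$mu_max, K_I_S = k$K_I_S,
                 K_I_i = k$K_I_i)
})
```

A subtle open point is *which* irradiance the constants refer to: the
incident setpoint, the volume-averaged internal field, or the light
perceived by moving cells. `simulate_culture()` makes this explicit and
configurable (`light_mode`): the default drives growth with the
liquid-volume mean of the internal field; `"particle"` mode uses the
ensemble mean of the light perceived by traced cells.

## Radiative transfer: choices and numerics

**Two-flux solver.** Each layer is solved analytically with the 2×2 matrix
exponential of the Schuster–Schwarzschild system; flux continuity couples
layers, and the backward stream vanishes at the outlet. With zero
scattering this reduces *exactly* to Beer–Lambert attenuation, which is the
oracle the tests use. Energy closure (absorbed + transmitted +
back-scattered = 1) is algebraic, to rounding error.

**Discrete ordinates.** The cavity (liquid + headspace) is discretised on a
uniform grid (default 2–4 mm); the angular domain uses the 26
face/edge/corner directions with equal weights and an isotropic phase
function (the ordinate count of the original study is not something the
package asserts; 6 ordinates are available for quick runs). Transport uses
the conservative upwind (step) finite-volume scheme swept in each ordinate
direction, with source iteration on the scattering term (tolerance 1e-12 on
the relative change of the scalar field; non-convergence raises an error
reporting the residual). The collimated LED beam is carried by the
axis-aligned +y ordinate, so it suffers no angular diffusion and the
scatter-free limit reproduces exponential attenuation to a few 0.1%. The
glass walls and the single interface reflectance are composed analytically
outside the grid — this keeps the grid uniform, and re-entrant reflections
between glass and cavity (second order, zero for non-scattering glass) are
lumped into the glass absorption so the budget still closes exactly.
Light exiting the lateral/top/bottom cavity boundaries is booked as
absorbed by the surrounding steel frame. Opaque internals are strongly
absorbing cells (kappa = 1e4 m^-1), which both blocks and books the energy.

**Bubbles** are a homogeneous scattering coefficient over the liquid
(default sigma = 1 m^-1); no individual bubbles are resolved. **Abiotic
medium absorption** defaults to kappa = 2.5 m^-1, chosen so that the
cell-free liquid-phase loss over the 24 mm path is small (order 6%); both
are configuration values intended to be re-fitted per instrument with
`fit_calibration_factors()` / `fit_absorption_law()` when measurements
exist.

**Outlet sensors.** The reported outlet intensity is the back-face flux at
the central position and the mean over the central plus four angular
positions, mirroring the measurement scheme; the two coincide in the 1-D
solver.

## The flow surrogate and its divergence check

The roll derives from `psi = A sin(pi x/W) sin(pi z/H_fill)` with `A` scaled
so the peak vertical speed equals `loop_speed` (default 0.02 m s^-1); the
stirrer vortex derives from a stream function that is solid-body out to the
stirrer radius, tapers linearly to zero *before* the nearest wall, and
decays vertically with a Gaussian. Because both components are curls of
stream functions, the field is exactly solenoidal and has zero wall-normal
velocity everywhere.

`divergence_check()` evaluates the velocities by centrally differencing the
same stream functions with the same step used for the divergence stencil.
The discrete difference operators then commute, so the reported divergence
is at rounding level (~1e-14 s^-1) rather than at the O(h^2) truncation
level (~1e-4) a naive check of the analytic velocities would show. This is
a deliberate numerical design: the check certifies that the *field object*
is a discrete curl, and a genuinely compressible field passed through the
same check is detected at its true divergence.

## Particle transport

The drag relaxation time of a 2 um cell is `1/F_d ≈ 0.23 us`, so over any
practical time step cells move with the fluid: the default "tracer" mode
sets the particle velocity to the local fluid velocity minus the terminal
settling speed (`~1e-7 m s^-1` — negligible but kept for correctness). The
full semi-implicit inertial integrator (drag implicit, so the stiff rate
does not limit stability) is retained and is the surface on which the force
model is tested against closed forms: terminal settling speed and
exponential velocity relaxation are reproduced to better than 1% with
`dt <= 0.005/F_d`. Elastic pair interactions use a uniform cell list with
cutoff `4 r_0`; a brute-force O(N^2) sum is kept in the test suite as the
oracle. Coincident particles would make the Hookean force singular, so the
pair is skipped and given a deterministic ±x kick of magnitude `k_EL r_0`.
Walls reflect specularly; the probe/sparger/stirrer internals are
transparent to particles (the surrogate flow cannot resolve their boundary
layers, so blocking them would create artificial dead zones).

Residence-zone statistics classify the perceived light as photo-limited
below `K_I,S`, photo-inhibited above the optimum
`sqrt(K_I,S K_I,i)`, and photo-saturated between — the regime names are
standard, the numeric boundaries are this package's convention.

## Turbidostat, oxygen and the coupled loop

The control loop mirrors the instrument: when OD730 exceeds
`0.4 × 1.025` the culture is diluted multiplicatively down to
`0.4 × 0.975`; biomass and OD scale together (OD is proportional to X
through a configurable 0.25 gDCW/L per OD unit). The reported growth rate
is *re-estimated* from the ln(OD) slope between dilutions over the trailing
half of each hold — a deliberate duplication of the instrument's estimator
so that simulation and experiment are compared on the same statistic; a
post-dilution sample always opens a fresh regression window so the OD drop
never contaminates a slope.

Dissolved oxygen uses one lumped balance,
`d(dO2)/dt = Y_O2 mu X - k_La (dO2 - 100)`, updated with the exact
exponential step. The defaults (`Y_O2 = 8000` % sat per gDCW/L per unit mu,
`k_La = 5 h^-1`) place steady values in a plausible 100–160% air-saturation
band across the observed growth range; they are reporting-scale choices,
not fitted constants. The kinetics/control step is 0.05 h and the radiative
field is refreshed every step (biomass changes slowly, and the 1-D solve is
cheap; the 3-D solver is available per step via `light_mode = "dom"`).

## Photosynthetic efficiency accounting

Efficiency is grams of biomass produced per mole of photons made available,
`(I_in - I_out) × area × dt`, with the illuminated area taken as the
light-facing liquid cross-section (width × fill height). Two variants are
reported: *whole-reactor* (panel input vs reactor outlet — all vessel
losses count) and *liquid-phase* (liquid inlet vs liquid outlet), the
latter necessarily at least as high. Production under turbidostat control
is accounted as the continuously removed stream `mu X V dt`; the batch
formula `X V (exp(mu dt) - 1)` is also provided in `biomass_produced()` but
is convex in `mu` and over 24 h windows would make efficiency *increase*
between the two lowest setpoints, contradicting both the monotone decay the
system exhibits and the physical meaning of held-biomass production.

## The synthetic campaign generator

`generate_campaign()` emulates the staircase experiment: seven setpoints
(50–1,200 uE) held 24 h, three replicates for case 1 and two for cases 2–3,
with multiplicative log-normal noise (defaults: 2% on growth rate and
dissolved oxygen, 1% on outlet light — error bars in this kind of
experiment are small but nonzero, and these values generate comparable
scatter). The forward model runs in fast mode: under turbidostat hold the
per-step steady state is evaluated directly (field from the held biomass →
effective irradiance → Haldane rate → steady oxygen), which is what makes
the generate→fit closure exact at zero noise. What the generator does *not*
emulate: sensor drift, day/night cycles, photoacclimation (pigment
adjustment would change `alpha_cell` and `kappa(X)` over days),
contamination, or CFD-accurate light fluctuation spectra — so passing
recovery tests demonstrate estimator correctness under the stated noise
model, not robustness to every real-world failure mode.

## Estimation

`fit_haldane()` is multi-start (16 log-uniform starts over
`mu_max ∈ [1e-3, 2] h^-1`, `K ∈ [1, 1e3] W m^-2`, plus one data-driven
start) Levenberg–Marquardt in log-parameter space, so positivity is
structural. The loss is unweighted squared error on `mu` (symmetric error
bars); a relative-error option exists. Identical seeds give identical
results. Degeneracies are surfaced, not hidden: data monotone in irradiance
warn and flag `no_interior_maximum`; a fitted inhibition constant running
beyond ten times the start bound flags `K_I_i_at_bound` (the Monod limit).
On noiseless staircase data generated from any of the three packaged
parameter sets the fitter recovers all constants to 1e-6 relative; at 2%
noise with 3 replicates the medians over 20 seeds stay within a few
percent.

`fit_absorption_law()` inverts transmissions through the scatter-free path
law (after removing abiotic losses multiplicatively) and fits the power law
in log–log space — exact on its own forward model.
`fit_calibration_factors()` regresses measured abiotic outlet intensities
through the origin on the unit-factor model prediction, per case; the slope
is the factor. The default factors (1.0, 1.25, 1.25) encode only the
physically mandated ordering (panel-mounted sensor ⇒ less emitted light);
they are placeholders to be re-estimated from abiotic data on a real
instrument.

## Problem sizes and limitations

The shipped defaults are desk-scale by design: DOM grids of 2–4 mm
(10^4–10^5 cells, 26 ordinates, converging in ~10 iterations), ensembles of
10^2–10^3 particles, and 24 h holds at 0.05 h steps; the vignette and test
suite run on one CPU in minutes. Known limitations: monochromatic
radiative transfer (no spectra, no polarization, one interface
reflectance); the flow is a surrogate, so particle light-fluctuation
spectra are qualitative (their stationarity is asserted, their 3–6%
amplitude is not); no temperature, pH/carbon chemistry, maintenance
energy, or photoacclimation; oxygen is one well-mixed pool. The published
whole-system percentages that depend on the original 3-D model and its
unpublished fitted radiative coefficients (liquid-phase loss fractions,
perceived/absorbed-light reductions, absolute efficiency values) are
treated as qualitative ordering checks here, not as quantitative targets.
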