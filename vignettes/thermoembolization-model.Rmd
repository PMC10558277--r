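---
title: "Modeling mass and energy transport in thermoembolization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mass and energy transport in thermoembolization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoembo)
```

## The procedure and the model

Thermoembolization treats hypervascular tumors (most prominently
hepatocellular carcinoma) by delivering dichloroacetyl chloride (DCACl)
dissolved in mineral oil through an arterial catheter. The oil delays
hydrolysis long enough for the reagent to reach the target bed; once DCACl
escapes the solvent it reacts exothermically with tissue water, so one
injection simultaneously embolizes the supplying vessels, heats the
perfused territory, and deposits a chemically denaturing acid load.

`thermoembo` models this as two-phase flow in a porous medium coupled to
reactive energy transport, in the framework of continuum mixture theory.
Three co-located constituents share each material volume: the immobile
tissue skeleton with porosity $\phi$, and two mobile pore fluids — blood and
the oily bolus — with saturations $s_{blood} + s_{bolus} = 1$. Each fluid
obeys Darcy flow with mobility $\lambda_\imath = s_\imath
\kappa_\imath/\mu_\imath$,

$$v_\imath = -\lambda_\imath \nabla p_\imath, \qquad
p_{bolus} - p_{blood} = p_c(s_{blood}) = \frac{p_d}{s_{blood}},$$

where $p_c$ is a Brooks–Corey capillary pressure with displacement pressure
$p_d$. Hydrolysis converts bolus mass into the blood compartment at the
first-order rate $\gamma$, giving the mass exchange
$q_{bolus} = -\gamma\,\rho_{DCACl}\,\epsilon\,\phi\,s_{bolus}$ (with
$\epsilon$ the DCACl volume fraction of the bolus) and the volumetric heat
source

$$r = \frac{h\,\gamma\,\rho_{DCACl}\,\epsilon\,\phi\,s_{bolus}}{W_{DCACl}},$$

with $h = h_{DCA} + h_{salt}$ the combined heat of the hydrolysis and the
secondary neutralization reactions. A single mixture temperature $u$ (the
constituents are assumed in local thermal equilibrium) is advanced by

$$\rho c\,\partial_t u
 + \phi\left(\rho_b c_b s_b v_b + \rho_o c_o s_o v_o\right)\cdot\nabla u
 = \nabla\cdot(k \nabla u) + r,$$

with $k$ and $\rho c$ the volume-fraction-averaged conductivity and thermal
inertia. During the delivery window the vessel interface carries a Dirichlet
injection pressure, pure bolus inflow ($s_0 = 1$), and inflow of heat at the
*upstream temperature* $u_0$ — the calorimetric ceiling
$u_0 = u(x,0) + h\,n_{DCACl}/(m_{tissue} c_{tissue})$ reached by complete
hydrolysis of the injected dose in a reference gram of tissue. The far
boundary holds atmospheric pressure with zero saturation and temperature
gradients.

## What the numbers mean

The default `thermo_parameters()` set describes ex vivo renal delivery of
2 mol/L DCACl in oil: porosity and permeability are "soft rock" values
($\phi = 0.05$, $\kappa = 5\times10^{-12}\,m^2$), the hydrolysis rate
$\gamma = 2.33\times10^{-3}\,s^{-1}$ is the kind of value one obtains by
fitting the first-order rise model $u(t) = u_{ss}(1-e^{-\gamma t})$ to
thermometry curves (`fit_hydrolysis_rate()` automates exactly that fit), and
$h = 138$ kJ/mol combines the 93 kJ/mol hydrolysis enthalpy with 45 kJ/mol
from secondary reactions, treated as additive. Since $\epsilon$ is not a
directly measured quantity, its default is derived from the delivered
concentration: `dcacl_volume_fraction(2, 0.147, 1532)` $\approx 0.192$.
Tissue conductivity (0.5 W/m/K) and density (1050 kg/m³) are
literature-typical soft-tissue values, exposed in the parameter set because
only the tissue specific heat is otherwise constrained.

Temperatures are carried in °C throughout; the model is linear in $u$, so
the kelvin offset cancels identically. Pressures are SI pascals internally,
with `atm_to_pa()` available because injection pressures are quoted in
atmospheres (1 atm = 101.325 kPa).

One property of this model is worth calling out: the bolus saturation obeys
$\dot s = -\gamma_{\!e\!f\!f}\, s$ with
$\gamma_{\!e\!f\!f} = \gamma\,\epsilon\,\rho_{DCACl}/\rho_{bolus}$, because
the mass sink is scaled by the DCACl content of the bolus while the bolus
inertia is $\phi\rho_{bolus}$. The *temperature* approach to steady state in
a well-mixed region therefore follows $\gamma_{\!e\!f\!f}$, which equals the
configured $\gamma$ only when $\epsilon\,\rho_{DCACl} = \rho_{bolus}$. The
end-to-end parameter-recovery test uses such a parameter set; with the
defaults, a rate refit from probe temperatures estimates
$\gamma_{\!e\!f\!f}$, not $\gamma$.

## Discretization

The solver is a cell-centered finite-volume method on structured 1/2/3-D
grids (`make_box_mesh()`), with the vessel represented purely through
tagged boundary faces (`tag_vessel()`): the lumen is not meshed, the bolus
enters the porous domain through the tagged interface. All three equations
are advanced with backward-Euler implicit time stepping; convective terms
use first-order upwinding.

Each operator-split step proceeds flow-first:

1. **Pressure.** The total-pressure equation (sum of the two phase mass
   balances) is assembled with two-point flux approximation, harmonic-mean
   permeability-to-viscosity on faces with lagged upwinded saturation
   factors, the capillary-gradient flux and the reaction volume source on
   the right-hand side, and solved sparsely (Matrix). Dirichlet values are
   imposed through half-cell transmissibilities.
2. **Saturation.** The bolus mass balance is advanced in *fractional-flow
   form*: the conservative total face flux from the pressure solve is split
   between the phases by $f(s) = \lambda_o/(\lambda_o+\lambda_b)$, upwinded
   implicitly, plus an implicit capillary cross-diffusion term
   $f\lambda_b\,\partial_s p_c$ with donor-cell (upstream-in-$p_c$)
   coefficients. This form is algebraically equivalent to the phase-velocity
   form of the continuous equations but is monotone discretely: $f \in
   [0,1]$ caps each phase flux by the total flux and the donor-cell
   capillary mobility degenerates at $s \in \{0,1\}$, so saturations stay in
   $[0,1]$ at any time step without clipping. The nonlinear system is solved
   by damped Newton iteration (analytic Jacobian, residual backtracking,
   25-iteration cap); constitutive laws are extended linearly outside
   $[0,1]$ so the iteration sees a globally $C^1$ system.
3. **Temperature.** The energy equation is advanced with the end-of-step
   saturations and phase fluxes (frozen-coefficient splitting), two-point
   diffusion with harmonic-mean mixture conductivity, and non-conservative
   upwind convection, as one sparse linear solve.

A failed step is retried with $dt/2$ down to `dt_min` before the run
aborts — the standard implicit-solver fallback.

### Numerical choices, and why

* **Capillary floor.** $p_c = p_d/s_{blood}$ blows up as blood is fully
  displaced; the law is floored at $s_{min} = 10^{-3}$ (cap near
  $p_d/s_{min}$). The floor is applied through a $C^1$ smooth max with
  width $s_{min}/10$: a hard `max()` leaves a derivative kink on which
  Newton iterates oscillate when cells sit exactly at the cap, which is
  precisely where a strong injection drives them.
* **Donor-cell capillary mobility.** An arithmetic-mean face coefficient
  admits small over/undershoots at degenerate fronts; taking the
  coefficient from the higher-$p_c$ cell restores the discrete maximum
  principle.
* **Zero-velocity tie-break** in upwinding uses the arithmetic mean of the
  adjacent saturations — symmetric and consistent.
* **Post-injection boundary.** When the delivery window closes, vessel
  faces seal and the flow solve is skipped entirely: convective transport
  in this model exists only while injection pressure is applied, and only
  diffusion and reaction continue afterwards. (Holding atmospheric
  Dirichlet instead would keep driving flow; the far boundary condition
  remains configurable via `far_bc`.)
* **Vessel thermal inflow.** The Robin inflow coefficient for temperature
  is not a measurable quantity; the implementation uses its advection-
  dominated limit — during injection, inflow faces carry the upstream
  temperature $u_0$ both convectively and through a half-cell conductive
  exchange, i.e. the bolus enters *at* the hydrolysis temperature. After
  delivery the interface is insulated.
* **Tolerances.** Linear solves are direct sparse factorizations (residual
  checked against 1e-10 scaled); the saturation Newton converges to a
  scaled residual of 1e-10 relative to the flux scale.

## Synthetic data in place of imaging

The package generates everything a desk-scale study needs in code. The
structured mesh with a tagged vessel stands in for an image-segmented organ
mesh; `synthesize_thermometry()` emulates frame-based MR thermometry by
sampling checkpoints every 22.3 s (one dynamic frame) and adding i.i.d.
Gaussian noise with $\sigma = \sigma_{ref}/\mathrm{SNR}$ ($\sigma_{ref} =
10$ °C, so the default SNR of 10 gives a 1 °C noise floor — the constant is
a documented calibration, since only relative behavior is testable).
`line_profile()` (multilinear by default, nearest-cell as an option — profile
length is a user parameter) and `compare_profiles()` reproduce the
profile-statistics workflow used to validate such models: mean/max absolute
temperature difference and Pearson correlation with a two-sided p-value.

What passing tests therefore show is that the *solver* faithfully
integrates the stated model — conservation, closed-form limits, scheme
equivalence, qualitative post-delivery heating. They do not show that the
model reproduces any particular organ's temperature maps: real validation
needs real thermometry of a real vascular geometry, with its out-of-plane
vessels, heterogeneous perfusion and imaging noise structure, none of which
the synthetic generator emulates.

## Verification problem sizes

The shipped verification suite uses deliberately small problems chosen to
make the mathematical checks sharp: uniform-decay and well-mixed-heating
oracles on 4×4 sealed grids over the 20-minute window (dt = 1 s, <0.5%
against closed forms), a 200-cell 1-D diffusion step against the heat
kernel (<0.1 °C), a 100-cell implicit-vs-explicit advection comparison
(L1 < 10⁻³), 32×32 sealed transport with stream-function swirl fluxes for
mass conservation (<10⁻⁸ relative), and a 50-cell 1-D delivery run for the
post-injection heating property. A full 2-D delivery on a 32×32 grid runs
in seconds; the method is CFL-free, so dt = 1 s resolves both the 25 s
injection and the ~430 s reaction time scale comfortably.

## Known limitations

* Embolic feedback (coagulation, vessel spasm), Navier–Stokes flow in the
  lumen and fluid–structure coupling are not modeled; delivery simply stops
  with the pressure window.
* Blood perfusion heat sink is absent (appropriate ex vivo, not in vivo).
* Reaction byproducts (DCA, HCl, salts) are not tracked individually, and
  no pH/buffer chemistry or thermal damage model (Arrhenius/CEM43) is
  included.
* Relative permeability is linear in saturation ($\lambda = s\kappa/\mu$);
  no hysteresis, gravity, or compressibility.
* The operator splitting is first-order in dt, consistent with backward
  Euler; the Richardson test in the suite bounds the splitting error.

## A minimal run

```{r example, eval = FALSE}
params <- thermo_parameters()
mesh <- tag_vessel(make_box_mesh(c(0.05, 0.05), c(32, 32)),
                   vessel_spec(matrix(c(0.025, 0), 1, 2), 2e-3))
cfg <- sim_config(mesh, params, injection_schedule(params),
                  dt = 1, t_end = 1200)
sim <- run_simulation(cfg)
glance(sim)
autoplot(sim)
```
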