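---
title: "lyosim: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lyosim: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lyosim)
```

`lyosim` simulates a complete continuous-lyophilization cycle for a single
suspended vial: freezing (with controlled nucleation by vacuum-induced
surface freezing, VISF), primary drying (sublimation of free ice) and
secondary drying (desorption of bound water). Vials in the suspended-vial
configuration move contact-free through dedicated chambers and exchange heat
only by natural convection and thermal radiation, so one vial's trajectory
represents the whole batch. This vignette describes the model, its
assumptions, the numerical treatment, and the design decisions that were
genuinely open.

## Freezing

The product (solution of water and a non-volatile solute) is treated as a
lumped thermal capacity — justified at vial scale by the small Biot number —
and stepped through five stages, each an ODE system terminated by an event.

**Preconditioning.** Sensible cooling only:
$(m_s C_{p,s} + m_w C_{p,w})\,dT/dt = Q_{s1} + Q_{s2} + Q_{s3}$, with the
top load $Q_{s1} = h_{s1} A_z (T_u - T)$ and bottom load
$Q_{s2} = h_{s2} A_z (T_g - T)$ written in Newton form (radiation folded
into the coefficients by linearization), and the side load keeping its
fourth-power radiation term,
$Q_{s3} = h_{s3} A_r (T_g - T) + \sigma A_r F_{s3}(T_c^4 - T^4)$.

**VISF.** Lowering the total pressure evaporates a little water from the
surface; the film model gives
$dm_w/dt = -h_m A_z (x_{w,\mathrm{sat}} - x_{w,c})$ with the vapor mass
fractions computed from partial pressures and molar masses, and the energy
balance gains the term $\Delta H_\mathrm{vap}\, dm_w/dt$. When the
saturation pressure reaches the total pressure the interface fraction is
clamped at 1 (the pure-vapor/boiling limit of the fraction formula), which
keeps the flux at its mass-transfer-limited maximum $-h_m A_z (1 -
x_{w,c})$. This clamp matters: at VISF pressures of a few hundred pascals
the liquid is well above its saturation point and the strong evaporative
cooling that triggers nucleation comes precisely from this regime. The side
area $A_r$ is recomputed from the current liquid volume at every call.

**Nucleation.** The first nucleation is an instantaneous adiabatic jump: the
supercooled liquid at $T_n$ rises to the depressed freezing point $T_{f,l}$
while an ice mass $m_{i,n}$ forms, solving simultaneously
$(T_{f,l}-T_n)(m_s C_{p,s}+m_w C_{p,w}) = m_{i,n}\Delta H_\mathrm{fus}$ and
the molal depression
$T_{f,w}-T_{f,l} = K_f (m_s/M_s)/(m_w - m_{i,n})$
(`nucleation_jump()`, a bracketed 1-D root solve; residuals of both
equations are verified to 1e-10 in the tests). In stochastic mode the
nucleation time is the first event of a nonhomogeneous Poisson process with
rate $\lambda = k_n (T_{f,l}-T)^{b_n} V_l$; the survival form
$dP/dt = \lambda (1-P)$ is integrated alongside the thermal states and the
event fires when $P$ crosses a uniform draw $u$ — inverse-CDF sampling,
exact in distribution. The kinetic parameters $k_n, b_n$ have no defaults:
no source values exist, so stochastic mode requires them explicitly.

**Solidification.** Ice grows from the bottom and side surfaces
(heterogeneous nucleation), adding a conduction resistance: the bottom and
side coefficients become $U_{s2} = (1/h_{s2} + l/k_i)^{-1}$ and
$U_{s3} = (1/h_{s3} + r_o \ln(r_o/r)/k_i)^{-1}$, with the remaining liquid
kept as a cylinder geometrically similar to the initial fill
(`solidification_geometry()`; the volume closure
$V_i + V_\mathrm{liq} = A_z H_\mathrm{tot}$ holds to machine precision).
The liquid temperature is slaved to the depression curve $T(m_i)$, so
instead of a differential-algebraic system we integrate a single ODE:
$dm_i/dt = \sum Q / (C_\mathrm{eff}\, dT/dm_i - \Delta H_\mathrm{fus})$,
which keeps $m_w + m_i$ conserved exactly. The stage ends when the ice
reaches 95 % of the post-jump water inventory; the tests verify that moving
this coefficient across 0.85–0.95 changes the total freezing time by well
under 10 %.

**Cooling.** Sensible cooling of the frozen product
($m_s C_{p,s} + m_w C_{p,w} + m_i C_{p,i}$ as capacity) until the product
reaches a target temperature (default 235 K, chosen near the primary-drying
initial temperatures of the validation scenarios), with a horizon fallback.
The stage end defines the freeze-to-primary handoff; an option restores a
handoff at the end of solidification instead.

## Primary drying

A one-dimensional Stefan problem: the frozen region $S(t) < z < H$ conducts
heat, the sublimation front at $z = S$ consumes it,
$$\rho_f C_{p,f}\,\partial_t T = k_f\,\partial_z^2 T + q_\mathrm{rad},\qquad
  dS/dt = N_w/(\rho_f - \rho_e),\qquad
  N_w = \frac{p_{w,\mathrm{sat}}(T_S) - p_{w,c}}{R_p(S)},$$
with the empirical cake resistance $R_p = R_{p0} + R_{p1}S/(R_{p2}+S)$,
Newton heating at the bottom ($h_b$, shelf temperature $T_b$) and a
sublimation/radiation balance at the front. The side-wall radiation enters
as a local volumetric source $4\sigma F_{s3}(T_c^4 - T_j^4)/d$: both the
side area and the frozen volume scale with the frozen height, so the ratio
is height-independent — a global source referenced to a single temperature
would diverge as $S \to H$.

The moving domain is fixed by the Landau transformation
$\xi = (z-S)/(H-S)$, giving a convection–diffusion equation on $[0,1]$ with
a grid-advection term proportional to $(\xi - 1)\,dS/dt/(H-S)$, discretized
with second-order central differences; ghost nodes at both boundaries are
eliminated through the flux conditions. (In the discrete boundary
treatment we use the continuous-form factor $\xi_j - 1$, which vanishes at
the bottom node, as the continuous equation requires.)

## Secondary drying

Heat conduction in the dried cake on a fixed grid, coupled to
linear-driving-force desorption with an Arrhenius rate:
$\partial_t c_w = -f_a e^{-E_a/RT} c_w$ (the equilibrium concentration
$c_w^*$ defaults to 0, overridable), with the desorption enthalpy acting as
a distributed heat sink and the same boundary treatment as primary drying.
The run ends when the volume-average $c_w$ reaches the target
$c_{w,\infty}$ — the volume average matches how total residual moisture is
measured. Vapor transport through the cake is not modeled: desorption is
the rate-limiting step. Two desorption parameter sets ship with the
fixtures (the generic defaults $f_a = 1.5\times10^{-3}\,\mathrm{s^{-1}}$,
$E_a = 6500\,\mathrm{J\,mol^{-1}}$ and the data-estimated set $f_a = 0.42$,
$E_a = 2.05\times10^4$ of the validation cases); no reconciliation between
them is attempted.

## Chamber balance and condenser failure

When the total vapor flow $j_w = n_\mathrm{vial} A_z N_w$ exceeds the
condenser capacity $j_{w,\max}$, vapor accumulates:
$dp_{w,c}/dt = (j_w - j_{w,\max})\,R\bar T/(V_c M_w)$, fed back into the
sublimation driving force. Condenser removal is limited to the vapor
actually available (incoming flow plus the chamber inventory released over
a 1 s relaxation time); this replaces a hard floor at $p_{w,c}=0$, which is
non-smooth and stalls the stiff integrator when the condenser is oversized.
The mean chamber temperature $\bar T$ is held constant.
`condenser_plateau()` reports the plateau as the first interior maximum of
the pressure trace: the pressure relaxes onto its slow manifold (flux
pinned at capacity) within seconds, so a derivative-threshold criterion
referenced to the initial slope is degenerate, while the point where the
trace stops rising matches the visual "becomes constant" reading.

## Numerics

All stages use `deSolve::lsodar` (stiff BDF with adaptive steps) with root
functions as terminal events — nucleation, solidification end, cooling
target, $S = H$, mean moisture target. Defaults: `n_z = 25` grid nodes,
`rtol = 1e-6`, `atol = 1e-8`. The tests verify that doubling `n_z` changes
both drying times by far less than 1 %, so 25 nodes is comfortably
converged for these vial-scale problems while keeping a full cycle below a
second of compute.

Three guards keep the stiff solver robust without affecting accepted
solutions. (1) The Landau metric is singular at $S = H$; the front starts
at the floor $S_0 = 10^{-6} H$ and terminates at $S = (1-10^{-6})H$, and
trial steps beyond the threshold are clamped there — the untraversed sliver
of ice corresponds to micrometres and sub-second times. (2) Rejected
implicit iterates can wander to unphysical temperatures; the front
temperature entering the saturation-pressure exponential is floored so the
right-hand side stays finite and the step is simply rejected. (3) During
VISF the trial water mass is floored at a nanogram.

Protocol channels are piecewise-linear with endpoint clamping; step changes
in set-points are represented as short ramps (default 60 s, matching the
ramp durations of the VISF scenarios) to keep the right-hand sides
continuous.

Monte-Carlo nucleation ensembles exploit that the pre-nucleation dynamics
are independent of the stochastic draw: the shared trajectory and its
cumulative probability $P(t)$ are integrated once, and $n$ nucleation times
are obtained by inverting $P$ at $n$ uniform draws
(`monte_carlo_freezing()`). This is exact in distribution and reduces a
10⁴-run ensemble to one integration plus interpolation. Draws beyond the
probability reached within the horizon are reported as censored. One root
seed drives the ensemble; single stochastic runs draw their quantile from
their own seed without touching the caller's RNG state.

## Scenario fixtures and what they do (not) emulate

`make_fixture()` generates the studied configurations: the full-cycle
default (3 mL, 5 % sucrose-like solute, 10R vial), freezing validation
("1"), primary-drying validation at a low and high shelf temperature
("2a"/"2b"), secondary-drying validation at two initial moisture levels
("3a"/"3b"), the VISF pressure study ("visf-study"), condenser failure
("condenser-failure") and the thermal-gradient demonstration
("gradient-demo"). Two entries are synthetic stand-ins and are labelled as
such: the freezing-validation gas-temperature profile (a linear 268→233 K
ramp over 2 h replacing a measured curve that exists only as a figure) and
the stochastic nucleation kinetics ($k_n = 3.3\times10^{-9}$, $b_n = 12$,
chosen so that nucleation occurs within minutes at 10–15 K supercooling, a
realistic sharpness for vial-scale volumes). Fixtures emulate clean,
single-vial conditions: no vial-to-vial radiation network, no measurement
noise, no lot-to-lot variability in cake resistance — passing tests show
the model solves its equations correctly under the stated conditions, not
that those conditions capture any particular piece of equipment.

## Known limitations

- Thermophysical properties are constants; no temperature dependence.
- The sublimation front is flat (1-D); no axisymmetric effects.
- No crystal/pore-size prediction, hence $R_p$ is purely empirical.
- The freezing model is lumped; spatial gradients during freezing are not
  resolved.
- The chamber balance tracks water vapor only; inert-gas dynamics and
  pressure control loops are out of scope.
- The early-time frozen-layer temperature difference in the
  thermal-gradient demonstration is governed by the quasi-steady balance
  $\Delta T \approx h_b (T_b - T_\mathrm{bottom}) H / k_f$ and is therefore
  sensitive to the shelf temperature; with the default shelf (270 K) the
  package computes a larger early gradient than with the validation-case
  shelf (263 K). Both are available via configuration.
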