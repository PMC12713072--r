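# lyosim

Mechanistic simulation of **continuous lyophilization** (freeze drying) of
suspended vials, for process modelers and drug-product manufacturing
scientists. Vials in the suspended-vial configuration travel contact-free
through dedicated freezing and drying chambers, so every vial sees the same
radiative–convective environment and a single-vial model describes the
whole line.

The package implements the full cycle as coupled, event-driven ODE/PDE
models:

- **Freezing** — lumped energy balance through five stages: preconditioning,
  vacuum-induced surface freezing (VISF, evaporative cooling
  `dm_w/dt = -h_m A_z (x_w,sat - x_w,c)`), ice nucleation (instantaneous
  adiabatic jump solving `(T_f,l - T_n) C = m_i,n ΔH_fus` together with the
  molal freezing-point depression `T_f,w - T_f,l = K_f (m_s/M_s)/(m_w -
  m_i,n)`; deterministic at `T_n` or stochastic as a Poisson process with
  rate `λ = k_n (T_f,l - T)^{b_n} V_l`), solidification with ice-layer
  heat-transfer resistances, and final cooling.
- **Primary drying** — a Stefan moving-boundary problem: frozen-region heat
  conduction with side-wall radiation, sublimation flux
  `N_w = (p_w,sat(T_S) - p_w,c)/R_p(S)` against a growing cake resistance,
  front velocity `dS/dt = N_w/(ρ_f - ρ_e)`, solved on a Landau-transformed
  moving grid until `S = H`.
- **Secondary drying** — dried-cake conduction coupled to linear-driving-force
  desorption `∂c_w/∂t = -f_a e^{-E_a/RT} c_w`, terminated at a target mean
  residual moisture.
- **Chamber/condenser** — a dynamic water-vapor balance
  `dp_w,c/dt = (j_w - j_w,max) R T̄/(V_c M_w)` coupled two-way with primary
  drying, for condenser-failure / choked-flow analysis.

Stochastic nucleation ensembles (`monte_carlo_freezing()`) sample
first-nucleation times exactly in distribution by inverting the shared
cumulative-probability path, making 10⁴-run ensembles essentially free.

## Worked example

```r
library(lyosim)

cfg <- lyo_config()          # 3 mL fill, 5 % solute, 10R (24 mm) vial
cy  <- run_full_cycle(cfg)   # freeze -> primary -> secondary with handoffs
cy
#> <lyo_cycle>
#>   freezing:  t_f5 = 1.46 h (nucleation at 0.54 h)
#>   primary:   t_d1 = 5.70 h, max T = 235.0 K
#>   secondary: t_d2 = 5.87 h, final c_w = 0.01 kg/kg
```

The freezing stage preconditions the solution, pulls vacuum at 0.5 h and
nucleates when the product crosses the configured nucleation temperature;
primary drying then sublimes the ice in 5.7 h while the product stays at
235 K, and secondary drying desorbs bound water from 0.088 down to the
0.01 kg/kg target in 5.9 h.

Derived formulation quantities and the nucleation jump are available
directly:

```r
f <- derive_formulation_masses(3e-6, 0.05)   # additive-volume mixing
#> m_s = 1.528e-4 kg, m_w0 = 2.904e-3 kg
nucleation_jump(263.18, f$m_w0, f$m_s)
#> T_f_l = 272.82 K, m_i_n = 3.56e-4 kg   (supercooled liquid flashes to its
#>                                         depressed freezing point)
```

Scenario fixtures reproduce the studied configurations
(`make_fixture("2b")`, `"visf-study"`, `"condenser-failure"`, ...), and a
thin CLI wraps the simulators:

```sh
exec/lyosim cycle --seed 1 --out out/
exec/lyosim freeze --mode visf-stochastic --config cfg.yaml --seed 7 --out out/
exec/lyosim montecarlo --config cfg.yaml --n 10000 --seed 1 --out out/
```

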