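test_that("vapor-pressure and latent-heat correlations hit known anchors", {
  # triple point: both correlations near 611 Pa and consistent with each other
  expect_equal(psat_liquid(273.15), 610, tolerance = 0.01)
  expect_equal(psat_ice(273.15), 610, tolerance = 0.01)
  expect_equal(psat_liquid(273.15), psat_ice(273.15), tolerance = 0.01)
  # strictly increasing
  Ts <- seq(230, 310, by = 5)
  expect_true(all(diff(psat_liquid(Ts)) > 0))
  expect_true(all(diff(psat_ice(Ts)) > 0))
  # ice correlation vs published value near -20 C
  expect_equal(psat_ice(253.15), 103, tolerance = 0.02)
  # latent heat anchored at the normal boiling point, decreasing, ~2.5e6 at 0 C
  expect_equal(dH_vap(373.15), 2.257e6)
  expect_equal(dH_vap(273.15), 2.54e6, tolerance = 0.02)
  expect_true(all(diff(dH_vap(Ts)) < 0))
  expect_equal(dH_vap(647.1), 0)
  expect_error(psat_liquid(40), "outside")
})

test_that("evaporation flux follows the film model with the boiling-limit clamp", {
  cfg <- default_cfg
  A_z <- cfg$derived$A_z
  # hand evaluation of the vapor mass fractions at 268 K, 1e4 Pa
  p_sat <- psat_liquid(268)
  x_sat <- p_sat * 0.018 / (p_sat * 0.018 + (1e4 - p_sat) * 0.028)
  expect_equal(evaporation_flux(268, 1e4, 0, 6.34e-3, A_z),
               -6.34e-3 * A_z * x_sat)
  # dry chamber has zero far-field fraction; saturated interface gives x = 1
  expect_equal(evaporation_flux(268, p_sat, 0, 6.34e-3, A_z),
               -6.34e-3 * A_z * 1)
  # below-saturation total pressure keeps the maximum (clamped) rate
  expect_equal(evaporation_flux(268, 100, 0, 6.34e-3, A_z),
               -6.34e-3 * A_z * 1)
  # no driving force when chamber fraction equals interface fraction
  expect_equal(evaporation_flux(268, 1e4, p_sat, 6.34e-3, A_z), 0)
})

test_that("nucleation jump satisfies both balances simultaneously", {
  f <- derive_formulation_masses(3e-6, 0.05)
  j <- nucleation_jump(263.18, f$m_w0, f$m_s)
  # reference behavior: supercooled liquid flashes to ~272 K
  expect_equal(j$T_f_l, 272, tolerance = 0.01)
  expect_gt(j$m_i_n, 0)
  expect_lt(j$m_i_n, f$m_w0)
  # substitute-back residuals of the two equations
  C <- f$m_s * 1204 + f$m_w0 * 4187
  r1 <- (j$T_f_l - 263.18) * C - j$m_i_n * 3.34e5
  r2 <- (273.15 - j$T_f_l) - 1.86 * (f$m_s / 0.3423) / (f$m_w0 - j$m_i_n)
  expect_lt(abs(r1) / (j$m_i_n * 3.34e5), 1e-10)
  expect_lt(abs(r2) / (273.15 - j$T_f_l), 1e-10)
  # cross-check against a dense 1-D scan over the ice mass
  scan <- seq(0, f$m_w0 * 0.999, length.out = 20001)
  g <- (273.15 - 1.86 * (f$m_s / 0.3423) / (f$m_w0 - scan) - 263.18) * C -
    scan * 3.34e5
  expect_equal(j$m_i_n, scan[which.min(abs(g))], tolerance = 1e-3)
  # zero supercooling: no ice, temperature unchanged
  T_eq <- freezing_point(f$m_w0, f$m_s)
  j0 <- nucleation_jump(T_eq, f$m_w0, f$m_s)
  expect_equal(j0$m_i_n, 0)
  expect_equal(j0$T_f_l, T_eq)
  expect_error(nucleation_jump(T_eq + 1, f$m_w0, f$m_s), "infeasible")
})

test_that("Poisson nucleation probability matches the closed-form survival law", {
  # clamped above the freezing point
  expect_equal(nucleation_rate(275, 272.86, 3e-6, 1e7, 12), 0)
  expect_equal(nucleation_probability_rhs(275, 272.86, 3e-6, 1e7, 12, 0.2), 0)
  # constant rate: integrate dP/dt and compare with 1 - exp(-lambda t)
  lam <- 2e-3
  out <- deSolve::lsoda(c(P = 0), seq(0, 2000, 10),
                        function(t, y, p) list(lam * (1 - y[1])), NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(out[, "P"], 1 - exp(-lam * out[, "time"]), tolerance = 1e-7)
})

test_that("solidification geometry closes volumes and hits both endpoints", {
  f <- derive_formulation_masses(3e-6, 0.05)
  # start of solidification: full-width liquid cylinder, no bottom layer
  g0 <- solidification_geometry(f$m_w0, 0, f$m_s)
  expect_equal(g0$r, 0.012)
  expect_equal(g0$l, 0)
  expect_equal(g0$h_l, 3e-6 / (pi * 0.024^2 / 4))
  # volume closure along the stage
  for (frac in c(0.2, 0.5, 0.8, 0.95)) {
    m_i <- frac * f$m_w0
    g <- solidification_geometry(f$m_w0 - m_i, m_i, f$m_s)
    A_z <- pi * 0.024^2 / 4
    expect_equal(g$V_i + g$V_liq, A_z * g$H_tot, tolerance = 1e-12)
    expect_lte(g$r, 0.012)
  }
  # near-complete solidification approaches the frozen-product height
  m_i <- 0.999 * f$m_w0
  g1 <- solidification_geometry(f$m_w0 - m_i, m_i, f$m_s)
  H_frozen <- frozen_geometry(f$m_w0, f$m_s)$H
  expect_equal(g1$H_tot, H_frozen, tolerance = 0.01)
})

test_that("stage right-hand sides have the correct fixed points and signs", {
  cfg <- default_cfg
  m_w0 <- cfg$derived$m_w0
  m_s <- cfg$derived$m_s
  # equilibrium: all ambient channels at the product temperature
  expect_equal(precondition_rhs(280, m_w0, m_s, amb_uniform(280), cfg), 0)
  # colder ambient cools
  expect_lt(precondition_rhs(280, m_w0, m_s, amb_uniform(270), cfg), 0)
  # hand evaluation against the surface loads at the validation conditions
  cfg1 <- make_fixture("1")$config
  amb <- list(T_u = 272, T_g = 268, T_c = 272)
  A_r <- pi * 0.024 * cfg1$derived$h_l0
  Q <- surface_heat_loads(280, amb, cfg1$derived$A_z, A_r, cfg1$transport)
  expect_equal(precondition_rhs(280, m_w0, m_s, amb, cfg1),
               Q$Q_total / (m_s * 1204 + m_w0 * 4187))
  # VISF with h_m = 0 reduces exactly to preconditioning
  cfg0 <- lyo_config(transport = list(h_m = 0))
  amb_v <- c(amb_uniform(268), list())
  amb_v$p_t <- 1e4; amb_v$p_w_c <- 0
  v <- visf_rhs(268, m_w0, m_s, amb_v, cfg0)
  expect_equal(v$dT, precondition_rhs(268, m_w0, m_s, amb_v, cfg0))
  expect_equal(v$dm_w, 0)
  # evaporation always lowers dT/dt relative to the h_m = 0 case
  v1 <- visf_rhs(268, m_w0, m_s, amb_v, default_cfg)
  expect_lt(v1$dT, v$dT)
  expect_lt(v1$dm_w, 0)
  # adiabatic solidification stall
  T_slave <- 273.15 - 1.86 * (m_s / 0.3423) / (m_w0 / 2)
  s <- solidification_rhs(m_w0 / 2, m_w0, amb_uniform(T_slave), cfg)
  expect_equal(s$dm_i, 0)
  expect_equal(s$T, T_slave)
  # net cooling freezes water
  s2 <- solidification_rhs(m_w0 / 2, m_w0, amb_uniform(230), cfg)
  expect_gt(s2$dm_i, 0)
})

test_that("solidification reduces to the classical Stefan balance for a dilute solute", {
  # nearly pure water: temperature pinned at T_f,w, dm_i/dt = -Q/dH_fus
  cfg <- lyo_config(formulation = list(x_s = 1e-6))
  m_w0 <- cfg$derived$m_w0
  amb <- amb_uniform(250)
  s <- solidification_rhs(m_w0 / 2, m_w0, amb, cfg)
  expect_equal(s$T, 273.15, tolerance = 1e-4)
  expect_equal(s$dm_i, -s$Q_total / 3.34e5, tolerance = 1e-3)
})

test_that("full freezing run is deterministic, mass-conserving and energy-consistent", {
  cfg <- default_cfg
  f1 <- simulate_freezing(cfg)
  f2 <- simulate_freezing(cfg)
  expect_identical(f1$trajectory, f2$trajectory)
  tr <- f1$trajectory
  # stage timestamps are ordered
  tt <- unlist(f1$times)
  expect_true(all(diff(tt) >= 0))
  # mass conservation: m_w + m_i constant after nucleation
  post <- tr[tr$stage %in% c("nucleation", "solidification", "cooling"), ]
  expect_equal(max(post$m_w + post$m_i), min(post$m_w + post$m_i),
               tolerance = 1e-12)
  # VISF loss accounted: total before nucleation equals m_w0 - evaporated
  expect_equal(post$m_w[1] + post$m_i[1],
               cfg$derived$m_w0 - f1$evaporated, tolerance = 1e-9)
  # solidification temperature is slaved to the depression curve
  sol <- tr[tr$stage == "solidification", ]
  T_curve <- 273.15 - 1.86 * (cfg$derived$m_s / 0.3423) / sol$m_w
  expect_equal(sol$T, T_curve, tolerance = 1e-9)
  # end criterion: ice at t_f4 is 95% of the post-jump water inventory
  m_w_pre <- post$m_w[1] + post$m_i[1]       # pre-jump liquid mass
  m_w_tf3 <- m_w_pre - f1$nucleation$m_i_n   # post-jump liquid mass
  expect_equal(max(tr$m_i), 0.95 * m_w_tf3, tolerance = 1e-6)
  # energy audit over solidification: integral of Q equals
  # C_eff dT - dH_fus dm_i along the trajectory
  amb_t <- function(t) eval_protocol(freezing_protocol(cfg), t)
  Qs <- vapply(seq_len(nrow(sol)), function(i) {
    solidification_rhs(sol$m_i[i], m_w_pre, amb_t(sol$t[i]), cfg)$Q_total
  }, numeric(1))
  lhs <- trapz(sol$t, Qs)
  C_eff <- cfg$derived$m_s * 1204 + sol$m_w * 4187
  dT <- diff(sol$T); dmi <- diff(sol$m_i)
  rhs <- sum((utils::head(C_eff, -1) + utils::tail(C_eff, -1)) / 2 * dT) -
    3.34e5 * sum(dmi)
  expect_equal(lhs, rhs, tolerance = 5e-3)
})

test_that("solidification end-criterion coefficient barely affects freezing time", {
  t85 <- simulate_freezing(lyo_config(freezing = list(solid_end_frac = 0.85)))$times$t_f5
  t95 <- simulate_freezing(lyo_config(freezing = list(solid_end_frac = 0.95)))$times$t_f5
  expect_lt(abs(t85 - t95) / t95, 0.10)
})

test_that("stochastic mode without kinetics fails loudly; seeds reproduce draws", {
  cfg <- lyo_config(nucleation = list(mode = "stochastic"))
  expect_error(simulate_freezing(cfg, seed = 1), "k_n and b_n")
  fx <- make_fixture("visf-study", stochastic = TRUE)
  a <- simulate_freezing(fx$config, seed = 11)
  b <- simulate_freezing(fx$config, seed = 11)
  c <- simulate_freezing(fx$config, seed = 12)
  expect_identical(a$trajectory, b$trajectory)
  expect_false(isTRUE(all.equal(a$times$t_f2, c$times$t_f2)))
})

test_that("VISF nucleation happens earlier and evaporates more at lower pressure", {
  res <- lapply(c(1e4, 1e3, 1e2), function(p) {
    simulate_freezing(make_fixture("visf-study", visf_pressure = p)$config)
  })
  t_nuc <- vapply(res, function(r) r$times$t_f2, numeric(1))
  evap <- vapply(res, function(r) r$evaporated, numeric(1))
  expect_true(all(diff(t_nuc) < 0))
  expect_true(all(diff(evap) > 0))
  # all trigger exactly at the configured nucleation temperature
  for (r in res) expect_equal(r$nucleation$T_n, 260, tolerance = 1e-6)
})
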