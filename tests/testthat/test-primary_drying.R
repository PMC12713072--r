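test_that("cake resistance and sublimation flux follow the printed correlations", {
  expect_equal(cake_resistance(0), 1.5e4)
  expect_equal(cake_resistance(10), 1.5e4 + 3e7 / 2)  # half-saturation
  expect_equal(cake_resistance(1e9), 1.5e4 + 3e7, tolerance = 1e-6)
  S <- seq(0, 0.01, length.out = 50)
  expect_true(all(diff(cake_resistance(S)) >= 0))
  # direct evaluation oracle at 250 K, fresh cake
  expect_equal(sublimation_flux(250, 0, 3), (psat_ice(250) - 3) / 1.5e4)
  # no driving force -> zero flux, zero velocity
  expect_equal(sublimation_flux(250, 0, psat_ice(250)), 0)
  expect_equal(interface_velocity(0, 937, 215), 0)
  expect_equal(interface_velocity(2e-4, 937, 215), 2e-4 / (937 - 215))
  expect_error(interface_velocity(1e-4, 215, 937))
})

test_that("primary RHS has an equilibrium fixed point and correct steady limits", {
  cfg <- default_cfg
  n_z <- 25
  # uniform temperature equal to every ambient channel, flux forced off
  amb <- amb_uniform(260, p_w_c = 3)
  r <- primary_rhs(rep(260, n_z), 1e-9, amb, cfg, force_Nw = 0)
  expect_equal(max(abs(r$dtheta)), 0, tolerance = 1e-10)
  expect_equal(r$dS, 0)

  # radiation off, flux off, constant shelf: steady state is uniform at T_b
  cfg0 <- lyo_config(transport = list(F_s1 = 0, F_s3 = 0))
  amb0 <- list(T_b = 270, T_u = 300, T_c = 300, p_w_c = 3)
  r0 <- primary_rhs(rep(270, n_z), 1e-9, amb0, cfg0, force_Nw = 0)
  expect_equal(max(abs(r0$dtheta)), 0, tolerance = 1e-10)

  # frozen-layer conduction check: with radiation off and a small forced
  # front flux, the analytic linear conduction profile between the two
  # boundary fluxes is (up to the tiny grid-advection term) a steady state
  N_force <- 2e-5
  H <- cfg$derived$H
  k_f <- 2.07
  q <- N_force * 2.84e6                  # front heat demand (W m^-2)
  T_b <- 270
  T_bot <- T_b - q / cfg0$primary$h_b    # Newton balance at the bottom
  xi <- seq(0, 1, length.out = n_z)      # node 1 at the front (z = S ~ 0)
  T_lin <- T_bot - q / k_f * H * (1 - xi)
  r_lin <- primary_rhs(T_lin, 0,
                       list(T_b = T_b, T_u = 300, T_c = 300, p_w_c = 3),
                       cfg0, force_Nw = N_force)
  # residual dT/dt is negligible against the transient scale q/(rho C H)
  expect_lt(max(abs(r_lin$dtheta)), 1e-3 * q / (937 * 2163 * H))
})

test_that("front recedes monotonically, terminates at H, and conserves mass", {
  cfg <- default_cfg
  run <- simulate_primary(cfg)
  s <- run$summary
  expect_false(is.na(run$t_d1))
  expect_true(all(diff(s$S) >= -1e-15))
  expect_equal(max(s$S), run$H, tolerance = 1e-5)
  # sublimed-mass audit: (rho_f - rho_e) S(t) = integral of N_w dt
  lhs <- (cfg$thermo$rho_f - cfg$thermo$rho_e) * (max(s$S) - s$S[1])
  expect_equal(lhs, trapz(s$t, s$N_w), tolerance = 2e-3)
  # bottom heating: maximum temperature sits at the vial bottom throughout
  expect_equal(s$T_max, s$T_bottom, tolerance = 1e-12)
})

test_that("with constant resistance and strong heating the front advances quasi-linearly", {
  # large h_b pins the bottom near the shelf; R_p1 = 0 keeps R_p constant
  cfg <- lyo_config(primary = list(h_b = 500, T_b = 250, T_0 = 250,
                                   T_c = 250, T_u = 250),
                    transport = list(R_p1 = 0, F_s1 = 0, F_s3 = 0))
  run <- simulate_primary(cfg)
  s <- run$summary
  mid <- s[s$S > 0.3 * run$H & s$S < 0.9 * run$H, ]
  # quasi-steady flux: front temperature settles, so N_w is nearly constant
  expect_lt(stats::sd(mid$N_w) / mean(mid$N_w), 0.15)
  # and S(t) is nearly linear: compare against a straight-line fit
  fit <- stats::lm(S ~ t, data = mid)
  expect_lt(max(abs(stats::resid(fit))) / run$H, 0.025)
})

test_that("grid refinement and the hot-shelf case behave as expected", {
  cfg <- default_cfg
  t25 <- simulate_primary(cfg, n_z = 25)$t_d1
  t50 <- simulate_primary(cfg, n_z = 50)$t_d1
  expect_lt(abs(t50 - t25) / t25, 0.01)
  # hotter shelf dries strictly faster, all else equal
  t2a <- simulate_primary(make_fixture("2a")$config)$t_d1
  t2b <- simulate_primary(make_fixture("2b")$config)$t_d1
  expect_lt(t2b, t2a)
})

test_that("primary field maps the moving grid back to physical depth", {
  run <- simulate_primary(default_cfg, dt_out = 600)
  fld <- primary_field(run)
  expect_named(fld, c("t", "z", "T"))
  # every time slice spans front to bottom
  sl <- fld[fld$t == max(fld$t), ]
  expect_equal(max(sl$z), run$H, tolerance = 1e-6)
  expect_equal(nrow(sl), run$n_z)
})
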