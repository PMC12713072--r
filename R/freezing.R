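#' Saturation vapor pressure over liquid water
#'
#' Antoine-type correlation used for evaporation during vacuum-induced
#' surface freezing.
#'
#' @param T Temperature (K); valid above 43 K and below the critical point.
#' @return Saturation pressure (Pa).
#' @export
#' @examples
#' psat_liquid(273.15)  # ~610 Pa, the triple-point pressure
psat_liquid <- function(T) {
  if (any(T <= 43) || any(T >= 647.1)) {
    stop("psat_liquid: T outside (43, 647.1) K", call. = FALSE)
  }
  1e3 * exp(16.3872 - 3885.7 / (T - 42.98))
}

#' Latent heat of vaporization of water
#'
#' Watson-type correlation anchored at the normal boiling point
#' (2.257e6 J/kg at 373.15 K), vanishing at the critical point 647.1 K.
#'
#' @param T Temperature (K), below the critical point.
#' @return Latent heat (J kg^-1).
#' @export
dH_vap <- function(T) {
  if (any(T <= 0) || any(T > 647.1)) {
    stop("dH_vap: T outside (0, 647.1] K", call. = FALSE)
  }
  2.257e6 * ((1 - T / 647.1) / (1 - 373.15 / 647.1))^0.38
}

# mass fraction of water in the vapor phase from partial pressures
vapor_mass_fraction <- function(p_w, p_t, M_w, M_in) {
  if (p_w <= 0) return(0)
  if (p_w >= p_t) return(1)  # pure-vapor (boiling) limit
  p_w * M_w / (p_w * M_w + (p_t - p_w) * M_in)
}

#' Evaporative water-mass flux during VISF
#'
#' Film-model evaporation rate at the liquid surface, driven by the
#' difference between the saturated and chamber vapor mass fractions. When
#' the saturation pressure reaches the total pressure the interface fraction
#' is clamped at 1 (pure-vapor limit), keeping the flux at its
#' mass-transfer-limited maximum.
#'
#' @param T Liquid surface temperature (K).
#' @param p_t Total chamber pressure (Pa).
#' @param p_w_c Chamber water partial pressure (Pa).
#' @param h_m Mass-transfer coefficient (kg m^-2 s^-1).
#' @param A_z Evaporation (cross-section) area (m^2).
#' @param M_w,M_in Molar masses of water and inert gas (kg mol^-1).
#' @return `dm_w/dt` (kg s^-1), nonpositive.
#' @export
evaporation_flux <- function(T, p_t, p_w_c, h_m, A_z,
                             M_w = 0.018, M_in = 0.028) {
  p_sat <- psat_liquid(T)
  x_sat <- vapor_mass_fraction(p_sat, p_t, M_w, M_in)
  x_c <- vapor_mass_fraction(p_w_c, p_t, M_w, M_in)
  -h_m * A_z * max(x_sat - x_c, 0)
}

#' Equilibrium freezing point of the solution
#'
#' Molal freezing-point depression for the (possibly partially frozen)
#' solution, relative to the current liquid-water mass.
#'
#' @param m_w Liquid water mass (kg).
#' @param m_s Solute mass (kg).
#' @param K_f Molal depression constant (kg K mol^-1).
#' @param M_s Solute molar mass (kg mol^-1).
#' @param T_f_w Freezing point of pure water (K).
#' @return Freezing point (K).
#' @export
freezing_point <- function(m_w, m_s, K_f = 1.86, M_s = 0.3423,
                           T_f_w = 273.15) {
  stopifnot(m_w > 0)
  T_f_w - K_f * (m_s / M_s) / m_w
}

#' Instantaneous nucleation jump
#'
#' Solves the adiabatic energy balance of the first nucleation event
#' simultaneously with the molal freezing-point depression: a supercooled
#' liquid at `T_n` flashes to its (depressed) equilibrium freezing point
#' `T_f_l`, with the released heat of fusion freezing the ice mass `m_i_n`.
#'
#' @param T_n Nucleation (supercooled) temperature (K).
#' @param m_w Liquid water mass just before nucleation (kg).
#' @param m_s Solute mass (kg).
#' @param Cp_s,Cp_w Specific heats of solute and water (J kg^-1 K^-1).
#' @param dH_fus Heat of fusion (J kg^-1).
#' @inheritParams freezing_point
#' @return List with `T_f_l` (post-nucleation temperature, K) and `m_i_n`
#'   (ice formed, kg).
#' @export
#' @examples
#' f <- derive_formulation_masses(3e-6, 0.05)
#' nucleation_jump(263.18, f$m_w0, f$m_s)$T_f_l  # ~272.8 K
nucleation_jump <- function(T_n, m_w, m_s, Cp_s = 1204, Cp_w = 4187,
                            dH_fus = 3.34e5, K_f = 1.86, M_s = 0.3423,
                            T_f_w = 273.15) {
  stopifnot(m_w > 0)
  C_eff <- m_s * Cp_s + m_w * Cp_w
  T_fl_of <- function(m_i) {
    freezing_point(m_w - m_i, m_s, K_f, M_s, T_f_w)
  }
  g <- function(m_i) (T_fl_of(m_i) - T_n) * C_eff - m_i * dH_fus
  if (g(0) < 0) {
    stop("infeasible nucleation: T_n above the equilibrium freezing point",
         call. = FALSE)
  }
  if (g(0) == 0) return(list(T_f_l = T_fl_of(0), m_i_n = 0))
  upper <- m_w * (1 - 1e-12)
  sol <- stats::uniroot(g, c(0, upper), tol = .Machine$double.eps^0.75)
  m_i_n <- sol$root
  list(T_f_l = T_fl_of(m_i_n), m_i_n = m_i_n)
}

#' Poisson nucleation rate and cumulative-probability dynamics
#'
#' Stochastic ice nucleation is a nonhomogeneous Poisson process with rate
#' `lambda = k_n * (T_f_l - T)^b_n * V_l` (zero when not supercooled). The
#' cumulative probability that the first nucleus has formed evolves as
#' `dP/dt = lambda * (1 - P)`.
#'
#' @param T Product temperature (K).
#' @param T_f_l Equilibrium freezing point of the (ice-free) solution (K).
#' @param V_l Liquid volume (m^3).
#' @param k_n Rate prefactor (nuclei m^-3 s^-1 K^-b_n).
#' @param b_n Supercooling exponent.
#' @param P Current cumulative probability.
#' @return `nucleation_rate`: the Poisson rate (s^-1);
#'   `nucleation_probability_rhs`: `dP/dt` (s^-1).
#' @export
nucleation_rate <- function(T, T_f_l, V_l, k_n, b_n) {
  dT <- T_f_l - T
  if (dT <= 0) return(0)
  k_n * dT^b_n * V_l
}

#' @rdname nucleation_rate
#' @export
nucleation_probability_rhs <- function(T, T_f_l, V_l, k_n, b_n, P) {
  nucleation_rate(T, T_f_l, V_l, k_n, b_n) * (1 - P)
}

#' Geometry of the partially solidified product
#'
#' During solidification, ice grows inward from the bottom and side surfaces
#' while the remaining liquid keeps a cylindrical shape geometrically similar
#' to the initial fill. Given the current masses, returns the liquid-cylinder
#' radius and height, the bottom ice-layer thickness, and the total product
#' height, satisfying the volume closure
#' `V_ice + V_liquid = A_z * H_tot`.
#'
#' @param m_w Liquid water mass (kg).
#' @param m_i Ice mass (kg).
#' @param m_s Solute mass (kg).
#' @param rho_w,rho_s,rho_i Densities (kg m^-3).
#' @param d Vial inner diameter (m).
#' @param clamp If `TRUE`, a (slightly) negative bottom-layer thickness is
#'   clamped to zero instead of raising an error; used inside the ODE
#'   right-hand side where the closure can transiently be infeasible.
#' @return List with `r`, `h_l`, `l`, `r_o`, `H_tot` (all m) and the volumes
#'   `V_liq`, `V_i` (m^3).
#' @export
solidification_geometry <- function(m_w, m_i, m_s, rho_w = 1000,
                                    rho_s = 1587.9, rho_i = 917, d = 0.024,
                                    clamp = FALSE) {
  stopifnot(m_w > 0, m_i >= 0, m_s >= 0)
  A_z <- pi * d^2 / 4
  r_o <- d / 2
  V_liq <- m_w / rho_w + m_s / rho_s
  # reference: all ice melted back -> the similar cylinder fills the vial
  V_ref <- (m_w + m_i) / rho_w + m_s / rho_s
  s <- (V_liq / V_ref)^(1 / 3)
  r <- r_o * s
  h_l <- (V_ref / A_z) * s
  V_i <- m_i / rho_i
  l <- (V_i - (A_z - pi * r^2) * h_l) / A_z
  if (l < 0) {
    if (clamp) l <- 0
    else if (l < -1e-12) stop("solidification geometry infeasible: l < 0",
                              call. = FALSE)
    else l <- 0
  }
  list(r = r, h_l = h_l, l = l, r_o = r_o, H_tot = l + h_l,
       V_liq = V_liq, V_i = V_i)
}

# --- stage right-hand sides (exported as plain functions for testing) ------

#' Preconditioning energy balance
#'
#' Lumped sensible-heat balance of the liquid before any phase change:
#' `(m_s Cp_s + m_w Cp_w) dT/dt = Q_s1 + Q_s2 + Q_s3`.
#'
#' @param T Product temperature (K).
#' @param m_w,m_s Water and solute masses (kg).
#' @param amb Ambient record (list `T_u`, `T_g`, `T_c`).
#' @param cfg A [lyo_config()].
#' @return `dT/dt` (K s^-1).
#' @export
precondition_rhs <- function(T, m_w, m_s, amb, cfg) {
  fm <- cfg$formulation
  A_z <- cfg$derived$A_z
  V_liq <- m_w / fm$rho_w + m_s / fm$rho_s
  A_r <- pi * cfg$vial$d * (V_liq / A_z)
  Q <- surface_heat_loads(T, amb, A_z, A_r, cfg$transport)
  Q$Q_total / (m_s * cfg$thermo$Cp_s + m_w * cfg$thermo$Cp_w)
}

#' VISF energy and mass balance
#'
#' Adds evaporative cooling to the preconditioning balance:
#' the water mass decreases at the evaporation rate, and the corresponding
#' latent heat is removed from the product. The side area is recomputed from
#' the current liquid volume.
#'
#' @inheritParams precondition_rhs
#' @param amb Ambient record including `p_t` and `p_w_c`.
#' @return List with `dT` (K s^-1) and `dm_w` (kg s^-1).
#' @export
visf_rhs <- function(T, m_w, m_s, amb, cfg) {
  if (m_w <= 0) stop("VISF dry-out: m_w <= 0", call. = FALSE)
  fm <- cfg$formulation
  A_z <- cfg$derived$A_z
  V_liq <- m_w / fm$rho_w + m_s / fm$rho_s
  A_r <- pi * cfg$vial$d * (V_liq / A_z)
  Q <- surface_heat_loads(T, amb, A_z, A_r, cfg$transport)
  dm_w <- evaporation_flux(T, amb$p_t, amb$p_w_c, cfg$transport$h_m, A_z,
                           fm$M_w, fm$M_in)
  dT <- (Q$Q_total + dH_vap(T) * dm_w) /
    (m_s * cfg$thermo$Cp_s + m_w * cfg$thermo$Cp_w)
  list(dT = dT, dm_w = dm_w)
}

#' Solidification rate
#'
#' Single-ODE formulation of the solidification stage: the liquid
#' temperature is algebraically slaved to the freezing-point-depression
#' curve `T(m_i)`, so the energy balance with the latent-heat source reduces
#' to `dm_i/dt = Q_total / (C_eff dT/dm_i - dH_fus)`. Bottom and side heat
#' loads see the growing ice layer through overall coefficients.
#'
#' @param m_i Current ice mass (kg).
#' @param m_w_ref Liquid water mass corresponding to zero ice, i.e. the
#'   pre-nucleation water inventory (kg); the current liquid mass is
#'   `m_w_ref - m_i`, which conserves `m_w + m_i` through the stage.
#' @param amb Ambient record.
#' @param cfg A [lyo_config()].
#' @return List with `dm_i` (kg s^-1), the slaved temperature `T` (K) and
#'   the heat load `Q_total` (W).
#' @export
solidification_rhs <- function(m_i, m_w_ref, amb, cfg) {
  fm <- cfg$formulation
  th <- cfg$thermo
  m_s <- cfg$derived$m_s
  m_w <- m_w_ref - m_i
  if (m_w <= 0) stop("solidification: m_w exhausted", call. = FALSE)
  moles <- m_s / fm$M_s
  T <- fm$T_f_w - fm$K_f * moles / m_w
  dT_dmi <- -fm$K_f * moles / m_w^2  # dm_w = -dm_i
  geo <- solidification_geometry(m_w, m_i, m_s, fm$rho_w, fm$rho_s, fm$rho_i,
                                 cfg$vial$d, clamp = TRUE)
  A_z <- cfg$derived$A_z
  A_r <- pi * cfg$vial$d * geo$H_tot
  r_eff <- min(max(geo$r, 1e-9), geo$r_o)
  Q <- surface_heat_loads(T, amb, A_z, A_r, cfg$transport, k_i = th$k_i,
                          r_o = geo$r_o, ice = list(l = geo$l, r = r_eff))
  C_eff <- m_s * th$Cp_s + m_w * th$Cp_w
  dm_i <- Q$Q_total / (C_eff * dT_dmi - th$dH_fus)
  list(dm_i = dm_i, T = T, Q_total = Q$Q_total)
}

# --- full freezing simulation ----------------------------------------------

#' Simulate the freezing stage
#'
#' Event-driven simulation of the five freezing steps of a suspended vial:
#' preconditioning, vacuum-induced surface freezing (VISF, optional),
#' nucleation (deterministic at `T_n` or stochastic via the Poisson model),
#' solidification, and final cooling. Stage switches are located by the
#' integrator's root finding.
#'
#' @param cfg A [lyo_config()]. Freezing operating conditions are taken from
#'   `cfg$freezing`, nucleation settings from `cfg$nucleation`.
#' @param seed Integer seed for the stochastic nucleation draw; ignored in
#'   deterministic mode. Identical seeds give identical trajectories.
#' @param u Optional uniform(0,1) nucleation quantile overriding the seeded
#'   draw (used by Monte-Carlo drivers).
#'
#' @return A list of class `lyo_freezing`:
#'   \describe{
#'     \item{trajectory}{data.frame `t`, `stage`, `T`, `m_w`, `m_i`, `P`.}
#'     \item{times}{list `t_f1`..`t_f5` (s).}
#'     \item{nucleation}{list with `T_n` (trigger temperature), `T_f_l`,
#'       `m_i_n`, `u`.}
#'     \item{evaporated}{cumulative evaporated water mass during VISF (kg).}
#'     \item{final}{final state (T, m_w, m_i).}
#'   }
#' @export
simulate_freezing <- function(cfg, seed = NULL, u = NULL) {
  fz <- cfg$freezing
  nuc <- cfg$nucleation
  stochastic <- identical(nuc$mode, "stochastic")
  if (stochastic && (is.na(nuc$k_n) || is.na(nuc$b_n))) {
    stop("stochastic nucleation requires k_n and b_n (not printed defaults); ",
         "set them in cfg$nucleation", call. = FALSE)
  }
  if (stochastic && is.null(u)) {
    if (!is.null(seed)) {
      u <- withr_seed_runif(seed)
    } else {
      u <- stats::runif(1)
    }
  }
  proto <- freezing_protocol(cfg)
  m_s <- cfg$derived$m_s
  fm <- cfg$formulation
  numer <- cfg$numerics
  dt_out <- numer$dt_out

  lambda_of <- function(T, m_w) {
    T_fl <- freezing_point(m_w, m_s, fm$K_f, fm$M_s, fm$T_f_w)
    V_liq <- m_w / fm$rho_w + m_s / fm$rho_s
    nucleation_rate(T, T_fl, V_liq, nuc$k_n, nuc$b_n)
  }

  # ---- stage 1: preconditioning (T, P) ----
  t_stage_end <- if (fz$visf) fz$t_visf else fz$t_max
  pre_func <- function(t, y, parms) {
    amb <- eval_protocol(proto, t)
    dT <- precondition_rhs(y[1], cfg$derived$m_w0, m_s, amb, cfg)
    dP <- if (stochastic) lambda_of(y[1], cfg$derived$m_w0) * (1 - y[2]) else 0
    list(c(dT, dP))
  }
  pre_root <- function(t, y, parms) {
    if (stochastic) y[2] - u else y[1] - nuc$T_n
  }
  times <- stage_times(0, t_stage_end, dt_out)
  y0 <- c(T = fz$T_0, P = 0)
  out1 <- run_lsodar(y0, times, pre_func, pre_root, numer)
  nucleated_pre <- !is.null(out1$troot)
  t1_end <- out1$t_end
  traj1 <- data.frame(t = out1$out[, "time"], stage = "precondition",
                      T = out1$out[, "T"], m_w = cfg$derived$m_w0, m_i = 0,
                      P = if (stochastic) out1$out[, "P"] else NA_real_)
  T_now <- unname(out1$y_end["T"])
  P_now <- unname(out1$y_end["P"])
  m_w_now <- cfg$derived$m_w0
  evaporated <- 0
  traj2 <- NULL

  if (nucleated_pre || !fz$visf) {
    if (!nucleated_pre) {
      stop("nucleation never reached within t_max during preconditioning ",
           "(no VISF configured); partial trajectory not returned",
           call. = FALSE)
    }
    t_f1 <- t_f2 <- t1_end
  } else {
    t_f1 <- t1_end  # VISF start
    # ---- stage 2: VISF (T, m_w, P) ----
    visf_func <- function(t, y, parms) {
      amb <- eval_protocol(proto, t)
      m_w_eff <- max(y[2], 1e-9)  # trial steps may undershoot
      rhs <- visf_rhs(y[1], m_w_eff, m_s, amb, cfg)
      dP <- if (stochastic) lambda_of(y[1], m_w_eff) * (1 - y[3]) else 0
      list(c(rhs$dT, rhs$dm_w, dP))
    }
    visf_root <- function(t, y, parms) {
      r1 <- if (stochastic) y[3] - u else y[1] - nuc$T_n
      c(r1, y[2] - 1e-6 * cfg$derived$m_w0)  # dry-out guard
    }
    times <- stage_times(t_f1, fz$t_max, dt_out)
    y0 <- c(T = T_now, m_w = m_w_now, P = P_now)
    out2 <- run_lsodar(y0, times, visf_func, visf_root, numer)
    if (is.null(out2$troot)) {
      stop("nucleation never reached within t_max during VISF",
           call. = FALSE)
    }
    if (out2$iroot == 2L) {
      stop("VISF dry-out: liquid water exhausted before nucleation",
           call. = FALSE)
    }
    t_f2 <- out2$t_end
    traj2 <- data.frame(t = out2$out[, "time"], stage = "visf",
                        T = out2$out[, "T"], m_w = out2$out[, "m_w"], m_i = 0,
                        P = if (stochastic) out2$out[, "P"] else NA_real_)
    T_now <- unname(out2$y_end["T"])
    m_w_now <- unname(out2$y_end["m_w"])
    P_now <- unname(out2$y_end["P"])
    evaporated <- cfg$derived$m_w0 - m_w_now
  }

  # ---- stage 3: instantaneous nucleation jump ----
  th <- cfg$thermo
  T_trigger <- T_now
  jump <- nucleation_jump(T_now, m_w_now, m_s, th$Cp_s, th$Cp_w, th$dH_fus,
                          fm$K_f, fm$M_s, fm$T_f_w)
  t_f3 <- t_f2
  m_w_tf3 <- m_w_now - jump$m_i_n
  traj3 <- data.frame(t = t_f3, stage = "nucleation", T = jump$T_f_l,
                      m_w = m_w_tf3, m_i = jump$m_i_n, P = NA_real_)

  # ---- stage 4: solidification (m_i) ----
  m_w_ref <- m_w_now          # zero-ice water inventory (mass conservation)
  m_i_target <- fz$solid_end_frac * m_w_tf3
  sol_func <- function(t, y, parms) {
    amb <- eval_protocol(proto, t)
    list(solidification_rhs(y[1], m_w_ref, amb, cfg)$dm_i)
  }
  sol_root <- function(t, y, parms) y[1] - m_i_target
  times <- stage_times(t_f3, t_f3 + fz$t_max, dt_out)
  out4 <- run_lsodar(c(m_i = jump$m_i_n), times, sol_func, sol_root, numer)
  if (is.null(out4$troot)) {
    stop("solidification end criterion not reached within horizon",
         call. = FALSE)
  }
  t_f4 <- out4$t_end
  m_i4 <- out4$out[, "m_i"]
  m_w4 <- m_w_ref - m_i4
  T4 <- fm$T_f_w - fm$K_f * (m_s / fm$M_s) / m_w4
  traj4 <- data.frame(t = out4$out[, "time"], stage = "solidification",
                      T = T4, m_w = m_w4, m_i = m_i4, P = NA_real_)
  m_i_now <- unname(out4$y_end["m_i"])
  m_w_now <- m_w_ref - m_i_now
  T_now <- fm$T_f_w - fm$K_f * (m_s / fm$M_s) / m_w_now

  # ---- stage 5: cooling (T) ----
  V_tot <- m_i_now / fm$rho_i + m_w_now / fm$rho_w + m_s / fm$rho_s
  H_tot <- V_tot / cfg$derived$A_z
  A_r <- pi * cfg$vial$d * H_tot
  C_cool <- m_s * th$Cp_s + m_w_now * th$Cp_w + m_i_now * th$Cp_i
  cool_func <- function(t, y, parms) {
    amb <- eval_protocol(proto, t)
    Q <- surface_heat_loads(y[1], amb, cfg$derived$A_z, A_r, cfg$transport)
    list(Q$Q_total / C_cool)
  }
  cool_root <- function(t, y, parms) y[1] - fz$cooling_target
  times <- stage_times(t_f4, t_f4 + fz$t_max, dt_out)
  out5 <- run_lsodar(c(T = T_now), times, cool_func,
                     if (T_now > fz$cooling_target) cool_root else NULL,
                     numer)
  t_f5 <- out5$t_end
  traj5 <- data.frame(t = out5$out[, "time"], stage = "cooling",
                      T = out5$out[, "T"], m_w = m_w_now, m_i = m_i_now,
                      P = NA_real_)
  T_now <- unname(out5$y_end["T"])

  traj <- rbind(traj1, traj2, traj3, traj4, traj5)
  rownames(traj) <- NULL
  structure(list(
    trajectory = traj,
    times = list(t_f1 = t_f1, t_f2 = t_f2, t_f3 = t_f3, t_f4 = t_f4,
                 t_f5 = t_f5),
    nucleation = list(T_n = T_trigger, T_f_l = jump$T_f_l,
                      m_i_n = jump$m_i_n,
                      u = if (stochastic) u else NA_real_),
    evaporated = evaporated,
    final = list(T = T_now, m_w = m_w_now, m_i = m_i_now),
    config = cfg
  ), class = "lyo_freezing")
}

# deterministic uniform draw from an integer seed without touching the
# global RNG stream
withr_seed_runif <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(1)
}

stage_times <- function(t0, t1, dt) {
  stopifnot(t1 > t0)
  n <- max(2L, ceiling((t1 - t0) / dt) + 1L)
  seq(t0, t1, length.out = n)
}

# thin wrapper around deSolve::lsodar that reports the root (if any),
# the end time and the final state
run_lsodar <- function(y0, times, func, rootfunc, numer) {
  out <- if (is.null(rootfunc)) {
    deSolve::lsodar(y = y0, times = times, func = func, parms = NULL,
                    rtol = numer$rtol, atol = numer$atol)
  } else {
    deSolve::lsodar(y = y0, times = times, func = func, parms = NULL,
                    rootfunc = rootfunc,
                    rtol = numer$rtol, atol = numer$atol)
  }
  troot <- attr(out, "troot")
  iroot <- which(attr(out, "iroot") == 1L)
  nm <- names(y0)
  last <- out[nrow(out), , drop = TRUE]
  y_end <- last[seq_along(y0) + 1L]
  names(y_end) <- nm
  list(out = out,
       troot = if (length(troot)) troot[1] else NULL,
       iroot = if (length(iroot)) iroot[1] else NULL,
       t_end = unname(last[1]),
       y_end = y_end)
}
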