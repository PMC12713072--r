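#' Derive formulation masses from fill volume and solute fraction
#'
#' Converts a fill volume and solute mass fraction into total liquid, solute
#' and initial water masses assuming additive-volume mixing of water and
#' solute (the specific volumes of the two components add).
#'
#' @param V_l Fill volume of the solution (m^3).
#' @param x_s Solute mass fraction (0 <= x_s < 1).
#' @param rho_w Density of liquid water (kg m^-3).
#' @param rho_s Density of the solute (kg m^-3).
#'
#' @return A list with `m_l` (total liquid mass), `m_s` (solute mass) and
#'   `m_w0` (initial water mass), all in kg. The masses satisfy volume
#'   additivity: `m_w0/rho_w + m_s/rho_s == V_l`.
#' @export
#' @examples
#' derive_formulation_masses(3e-6, 0.05, 1000, 1587.9)
derive_formulation_masses <- function(V_l, x_s, rho_w = 1000, rho_s = 1587.9) {
  if (!is.finite(V_l) || V_l <= 0) stop("V_l must be positive", call. = FALSE)
  if (!is.finite(x_s) || x_s < 0 || x_s >= 1) {
    stop("x_s must be in [0, 1)", call. = FALSE)
  }
  if (rho_w <= 0 || rho_s <= 0) stop("densities must be positive", call. = FALSE)
  m_l <- V_l / ((1 - x_s) / rho_w + x_s / rho_s)
  list(m_l = m_l, m_s = x_s * m_l, m_w0 = (1 - x_s) * m_l)
}

#' Frozen-product geometry
#'
#' Frozen volume, product height and frozen density for a cylindrical product
#' of diameter `d`, assuming the water freezes to ice at density `rho_i` while
#' the solute keeps its density.
#'
#' @param m_w0 Initial water mass (kg).
#' @param m_s Solute mass (kg).
#' @param rho_i Ice density (kg m^-3).
#' @param rho_s Solute density (kg m^-3).
#' @param d Inner vial diameter (m).
#'
#' @return List with `V_f` (frozen volume, m^3), `H` (product height, m),
#'   `rho_f` (frozen density, kg m^-3) and `A_z` (cross-section, m^2).
#' @export
frozen_geometry <- function(m_w0, m_s, rho_i = 917, rho_s = 1587.9, d = 0.024) {
  if (m_w0 < 0 || m_s < 0) stop("masses must be nonnegative", call. = FALSE)
  if (m_w0 + m_s <= 0) stop("total mass must be positive", call. = FALSE)
  if (d <= 0) stop("d must be positive", call. = FALSE)
  V_f <- m_w0 / rho_i + m_s / rho_s
  A_z <- pi * d^2 / 4
  list(V_f = V_f, H = V_f / A_z, rho_f = (m_w0 + m_s) / V_f, A_z = A_z)
}

#' Build a full model configuration
#'
#' Assembles the complete parameter set of the simulator: formulation, vial
#' geometry, thermophysical constants, heat/mass-transfer parameters,
#' desorption and nucleation kinetics, stage operating conditions, and
#' numerics. All defaults correspond to a 3 mL, 5 % sucrose fill in a 10R
#' (24 mm) vial. Any subset can be overridden through `...` as named nested
#' lists, e.g. `lyo_config(transport = list(h_b = 30))`.
#'
#' Derived quantities (`m_s`, `m_w0`, `A_z`, `H`, `rho_f`, `V_f`) are
#' recomputed from the formulation and vial entries on construction.
#'
#' @param ... Named overrides for the sections `formulation`, `vial`,
#'   `thermo`, `transport`, `desorption`, `nucleation`, `freezing`,
#'   `primary`, `secondary`, `numerics`. Each must be a named list whose
#'   entries replace the defaults.
#'
#' @return An object of class `lyo_config` (a nested named list).
#' @export
#' @examples
#' cfg <- lyo_config(primary = list(h_b = 30))
#' cfg$derived$H
lyo_config <- function(...) {
  cfg <- list(
    formulation = list(
      V_l = 3e-6, x_s = 0.05,
      rho_w = 1000, rho_s = 1587.9, rho_i = 917,
      M_s = 0.3423, M_w = 0.018, M_in = 0.028,
      K_f = 1.86, T_f_w = 273.15
    ),
    vial = list(d = 0.024, eps_gl = 0.8),
    thermo = list(
      Cp_s = 1204, Cp_w = 4187, Cp_i = 2108, Cp_f = 2163, Cp_e = 2590,
      k_s = 0.126, k_w = 0.598, k_i = 2.25, k_f = 2.07, k_e = 0.217,
      rho_f = NA_real_, rho_e = 215, rho_d = 212.21,
      dH_fus = 3.34e5, dH_sub = 2.84e6, dH_des = 2.68e6
    ),
    transport = list(
      h_s1 = 5, h_s2 = 10, h_s3 = 8, h_b = 15,
      h_m = 6.34e-3,
      F_s1 = 0.8, F_s3 = 0.624,
      sigma = 5.67e-8,
      R_p0 = 1.5e4, R_p1 = 3.0e7, R_p2 = 10
    ),
    desorption = list(
      f_a = 1.5e-3, E_a = 6500, R = 8.314,
      c_w0 = 0.088, c_w_inf = 0.01, c_w_eq = 0
    ),
    nucleation = list(
      mode = "deterministic", T_n = 268,
      k_n = NA_real_, b_n = NA_real_
    ),
    # per-stage operating conditions; scalar channels may be replaced by
    # protocol_channel() breakpoint tables anywhere
    freezing = list(
      T_0 = 298.15,
      visf = TRUE, t_visf = 1800, visf_ramp = 60,
      T_g_pre = 268, T_g_visf = 230,
      T_cu_pre = 273, T_cu_visf = 240,
      p_t_pre = 1e5, p_t_visf = 1e4,
      p_w_c = 0,
      cooling_target = 235, t_max = 6 * 3600,
      solid_end_frac = 0.95
    ),
    primary = list(
      T_0 = 235, T_b = 270, T_c = 265, T_u = 265, p_w_c = 3, h_b = NA_real_
    ),
    secondary = list(
      T_0 = 273, T_b = 295, T_c = 290, T_u = 290, h_b = NA_real_
    ),
    numerics = list(
      n_z = 25, rtol = 1e-6, atol = 1e-8,
      S_floor = 1e-6, dt_out = 10, t_max_drying = 48 * 3600
    )
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      stop("unknown config section(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (sec in names(overrides)) {
      ov <- overrides[[sec]]
      stopifnot(is.list(ov))
      unknown <- setdiff(names(ov), names(cfg[[sec]]))
      if (length(unknown)) {
        stop("unknown key(s) in section '", sec, "': ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      cfg[[sec]][names(ov)] <- ov
    }
  }
  cfg <- finalize_config(cfg)
  class(cfg) <- "lyo_config"
  cfg
}

# recompute derived formulation/geometry quantities
finalize_config <- function(cfg) {
  fm <- cfg$formulation
  ms <- derive_formulation_masses(fm$V_l, fm$x_s, fm$rho_w, fm$rho_s)
  ge <- frozen_geometry(ms$m_w0, ms$m_s, fm$rho_i, fm$rho_s, cfg$vial$d)
  if (is.na(cfg$thermo$rho_f)) cfg$thermo$rho_f <- ge$rho_f
  # per-stage h_b falls back to the shared transport value
  for (st in c("primary", "secondary")) {
    if (is.na(cfg[[st]]$h_b)) cfg[[st]]$h_b <- cfg$transport$h_b
  }
  cfg$derived <- list(
    m_l = ms$m_l, m_s = ms$m_s, m_w0 = ms$m_w0,
    A_z = ge$A_z, V_f = ge$V_f, H = ge$H, rho_f = ge$rho_f,
    h_l0 = fm$V_l / ge$A_z
  )
  cfg
}

#' @export
print.lyo_config <- function(x, ...) {
  cat("<lyo_config>\n")
  cat(sprintf("  fill: %.2g mL, x_s = %.3g; vial d = %.3g m\n",
              x$formulation$V_l * 1e6, x$formulation$x_s, x$vial$d))
  cat(sprintf("  derived: m_s = %.4g kg, m_w0 = %.4g kg, H = %.4g m, rho_f = %.4g kg/m^3\n",
              x$derived$m_s, x$derived$m_w0, x$derived$H, x$derived$rho_f))
  cat(sprintf("  nucleation: %s (T_n = %.4g K)\n",
              x$nucleation$mode, x$nucleation$T_n))
  cat(sprintf("  grid: n_z = %d, rtol = %g\n",
              x$numerics$n_z, x$numerics$rtol))
  invisible(x)
}
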