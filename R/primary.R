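#' Saturation vapor pressure over ice
#'
#' Clausius-Clapeyron-type correlation for sublimation.
#'
#' @param T Temperature (K).
#' @return Saturation pressure (Pa).
#' @export
#' @examples
#' psat_ice(273.15)  # ~610 Pa; agrees with psat_liquid at the triple point
psat_ice <- function(T) {
  stopifnot(all(T > 0))
  exp(-6139.9 / T + 28.8912)
}

#' Dried-cake resistance to vapor flow
#'
#' Empirical saturating resistance: a constant surface term plus a
#' dried-layer term growing with the front depth `S`,
#' `R_p = R_p0 + R_p1 * S / (R_p2 + S)`.
#'
#' @param S Sublimation-front position / dried-layer thickness (m).
#' @param R_p0 Surface resistance (m s^-1).
#' @param R_p1 Dried-layer resistance scale (s^-1).
#' @param R_p2 Half-saturation thickness scale (m... per the fitted
#'   correlation).
#' @return Resistance (consistent units such that
#'   `N_w = (p_sat - p_c)/R_p` is a mass flux).
#' @export
cake_resistance <- function(S, R_p0 = 1.5e4, R_p1 = 3.0e7, R_p2 = 10) {
  stopifnot(all(S >= 0))
  R_p0 + R_p1 * S / (R_p2 + S)
}

#' Sublimation mass flux at the front
#'
#' `N_w = (p_w_sat(T_front) - p_w_c) / R_p(S)`, floored at zero when the
#' chamber pressure exceeds the front saturation pressure.
#'
#' @param T_front Front temperature (K).
#' @param S Front position (m).
#' @param p_w_c Chamber water partial pressure (Pa).
#' @param R_p0,R_p1,R_p2 Cake-resistance constants.
#' @return Mass flux (kg m^-2 s^-1), nonnegative.
#' @export
sublimation_flux <- function(T_front, S, p_w_c,
                             R_p0 = 1.5e4, R_p1 = 3.0e7, R_p2 = 10) {
  max(psat_ice(T_front) - p_w_c, 0) / cake_resistance(S, R_p0, R_p1, R_p2)
}

#' Sublimation-front velocity
#'
#' Mass balance at the moving interface: `dS/dt = N_w / (rho_f - rho_e)`.
#'
#' @param N_w Sublimation flux (kg m^-2 s^-1).
#' @param rho_f Frozen density (kg m^-3).
#' @param rho_e Effective dried density (kg m^-3); must be `< rho_f`.
#' @return Front velocity (m s^-1).
#' @export
interface_velocity <- function(N_w, rho_f, rho_e) {
  stopifnot(rho_f > rho_e)
  N_w / (rho_f - rho_e)
}

#' Primary-drying right-hand side
#'
#' Method-of-lines right-hand side for the frozen-region heat equation on
#' the Landau-transformed coordinate `xi = (z - S)/(H - S)` (node 1 at the
#' sublimation front, node `n_z` at the vial bottom), together with the
#' front velocity. Ghost nodes at both boundaries are eliminated with the
#' Newton-law (bottom) and sublimation/radiation (top) flux conditions; the
#' side-wall radiation enters as the local volumetric source
#' `4 sigma F_s3 (T_c^4 - T_j^4)/d`.
#'
#' @param theta Temperatures at the `n_z` grid nodes (K).
#' @param S Front position (m).
#' @param amb Ambient record: `T_b`, `T_u`, `T_c`, `p_w_c`.
#' @param cfg A [lyo_config()].
#' @param H Product height (m); defaults to the configured derived height.
#' @param force_Nw Optional override of the sublimation flux (testing).
#' @return List with `dtheta` (K s^-1), `dS` (m s^-1) and `N_w`
#'   (kg m^-2 s^-1).
#' @export
primary_rhs <- function(theta, S, amb, cfg, H = cfg$derived$H,
                        force_Nw = NULL) {
  th <- cfg$thermo
  tp <- cfg$transport
  pr <- cfg$primary
  n_z <- length(theta)
  stopifnot(n_z >= 3)
  if (S >= H) stop("front has passed the product height", call. = FALSE)
  dxi <- 1 / (n_z - 1)
  xi <- (seq_len(n_z) - 1) * dxi
  HS <- H - S
  N_w <- if (is.null(force_Nw)) {
    # guard against diverging solver iterates: keep the flux finite so the
    # step can be rejected gracefully rather than aborting in psat_ice
    sublimation_flux(max(theta[1], 1), S, amb$p_w_c,
                     tp$R_p0, tp$R_p1, tp$R_p2)
  } else force_Nw
  dS <- interface_velocity(N_w, th$rho_f, th$rho_e)

  # ghost values from the boundary flux conditions
  top_flux <- N_w * th$dH_sub - tp$sigma * tp$F_s1 * (amb$T_u^4 - theta[1]^4)
  T_ghost_top <- theta[2] - 2 * dxi * HS * top_flux / th$k_f
  T_ghost_bot <- theta[n_z - 1] -
    2 * dxi * HS * pr$h_b * (theta[n_z] - amb$T_b) / th$k_f

  Tm <- c(T_ghost_top, theta[seq_len(n_z - 1)])
  Tp <- c(theta[2:n_z], T_ghost_bot)
  diff_term <- th$k_f / (th$rho_f * th$Cp_f * HS^2) *
    (Tp - 2 * theta + Tm) / dxi^2
  adv_term <- -(xi - 1) / HS * dS * (Tp - Tm) / (2 * dxi)
  q_side <- 4 * tp$sigma * tp$F_s3 * (amb$T_c^4 - theta^4) / cfg$vial$d
  dtheta <- diff_term + adv_term + q_side / (th$rho_f * th$Cp_f)
  list(dtheta = dtheta, dS = dS, N_w = N_w)
}

#' Simulate primary drying
#'
#' Integrates the moving-boundary sublimation model from a (near-)zero
#' initial front position until the front reaches the product height
#' (`S = H`), detected as a terminal event. The front starts at the small
#' numerical floor `S_floor * H` to keep the transformed metric finite.
#'
#' @param cfg A [lyo_config()]; operating conditions from `cfg$primary`.
#' @param T_0 Initial temperature: scalar (uniform) or a length-`n_z`
#'   profile. Defaults to `cfg$primary$T_0`.
#' @param H Product height (m); defaults to the derived height.
#' @param n_z Number of grid nodes; defaults to `cfg$numerics$n_z`.
#' @param dt_out Output interval (s).
#' @param t_max Integration horizon (s).
#'
#' @return List of class `lyo_primary`:
#'   \describe{
#'     \item{summary}{data.frame `t`, `S`, `N_w`, `T_front`, `T_bottom`,
#'       `T_max`, `T_min`.}
#'     \item{profiles}{matrix of temperatures, one row per output time, one
#'       column per grid node (front to bottom).}
#'     \item{z}{function(t_index) physical node positions for a summary row.}
#'     \item{t_d1}{drying end time (s), `NA` if the horizon was hit first.}
#'   }
#' @export
simulate_primary <- function(cfg, T_0 = NULL, H = NULL, n_z = NULL,
                             dt_out = NULL, t_max = NULL) {
  pr <- cfg$primary
  numer <- cfg$numerics
  if (is.null(T_0)) T_0 <- pr$T_0
  if (is.null(H)) H <- cfg$derived$H
  if (is.null(n_z)) n_z <- numer$n_z
  if (is.null(dt_out)) dt_out <- max(numer$dt_out, 30)
  if (is.null(t_max)) t_max <- numer$t_max_drying
  theta0 <- if (length(T_0) == 1L) rep(T_0, n_z) else {
    stopifnot(length(T_0) == n_z)
    T_0
  }
  S0 <- numer$S_floor * H
  amb_of <- function(t) list(
    T_b = eval_channel(pr$T_b, t), T_u = eval_channel(pr$T_u, t),
    T_c = eval_channel(pr$T_c, t), p_w_c = eval_channel(pr$p_w_c, t)
  )
  func <- function(t, y, parms) {
    # trial steps may overshoot the terminal root; keep the metric finite by
    # clamping at the termination threshold itself
    S <- min(max(y[n_z + 1L], 0), H * (1 - numer$S_floor))
    rhs <- primary_rhs(y[seq_len(n_z)], S, amb_of(t), cfg, H = H)
    list(c(rhs$dtheta, rhs$dS), N_w = rhs$N_w)
  }
  rootfunc <- function(t, y, parms) y[n_z + 1L] - H * (1 - numer$S_floor)
  y0 <- c(theta0, S0)
  names(y0) <- c(paste0("T", seq_len(n_z)), "S")
  times <- stage_times(0, t_max, dt_out)
  out <- run_lsodar(y0, times, func, rootfunc, numer)
  M <- out$out
  profs <- M[, 1 + seq_len(n_z), drop = FALSE]
  S_tr <- M[, 1 + n_z + 1L]
  N_w <- M[, ncol(M)]
  summary <- data.frame(
    t = M[, "time"], S = S_tr, N_w = N_w,
    T_front = profs[, 1], T_bottom = profs[, n_z],
    T_max = apply(profs, 1, max), T_min = apply(profs, 1, min)
  )
  structure(list(
    summary = summary, profiles = unname(profs),
    t_d1 = if (!is.null(out$troot)) out$t_end else NA_real_,
    H = H, n_z = n_z, config = cfg
  ), class = "lyo_primary")
}

#' Long-format spatiotemporal temperatures from a primary-drying run
#'
#' Maps the moving-grid node temperatures back to physical depth
#' `z = S + xi (H - S)` for every output time.
#'
#' @param run A `lyo_primary` result.
#' @return data.frame with columns `t`, `z`, `T`.
#' @export
primary_field <- function(run) {
  n_z <- run$n_z
  xi <- (seq_len(n_z) - 1) / (n_z - 1)
  do.call(rbind, lapply(seq_len(nrow(run$summary)), function(i) {
    S <- run$summary$S[i]
    data.frame(t = run$summary$t[i], z = S + xi * (run$H - S),
               T = run$profiles[i, ])
  }))
}
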