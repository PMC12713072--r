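#' Linear-driving-force desorption rate
#'
#' First-order desorption of bound water from the dried cake with an
#' Arrhenius rate constant: `dc_w/dt = -f_a exp(-E_a/(R T)) (c_w - c_w_eq)`.
#'
#' @param T Temperature (K).
#' @param c_w Bound-water concentration (kg water / kg solid).
#' @param f_a Frequency factor (s^-1).
#' @param E_a Activation energy (J mol^-1).
#' @param R Gas constant (J mol^-1 K^-1).
#' @param c_w_eq Equilibrium concentration (kg/kg), default 0.
#' @return `dc_w/dt` (kg/kg s^-1).
#' @export
desorption_rate <- function(T, c_w, f_a = 1.5e-3, E_a = 6500, R = 8.314,
                            c_w_eq = 0) {
  -f_a * exp(-E_a / (R * T)) * (c_w - c_w_eq)
}

#' Secondary-drying right-hand side
#'
#' Method-of-lines right-hand side for heat conduction in the dried cake
#' coupled to bound-water desorption: central differences on a fixed grid
#' (node 1 at the top, node `n_z` at the bottom), radiative top boundary,
#' Newton-law bottom boundary, desorption heat sink, and the local side-wall
#' radiation source `4 sigma F_s3 (T_c^4 - T_j^4)/d`.
#'
#' @param T Temperatures at the grid nodes (K).
#' @param c_w Bound-water concentrations at the nodes (kg/kg).
#' @param amb Ambient record: `T_b`, `T_u`, `T_c`.
#' @param cfg A [lyo_config()].
#' @param H Product height (m).
#' @return List with `dT` (K s^-1) and `dc_w` (kg/kg s^-1).
#' @export
secondary_rhs <- function(T, c_w, amb, cfg, H = cfg$derived$H) {
  th <- cfg$thermo
  tp <- cfg$transport
  de <- cfg$desorption
  n_z <- length(T)
  stopifnot(n_z >= 3, length(c_w) == n_z)
  dz <- H / (n_z - 1)
  dc_w <- desorption_rate(T, c_w, de$f_a, de$E_a, de$R, de$c_w_eq)
  # ghost nodes from the boundary fluxes
  T_ghost_top <- T[2] + 2 * dz * tp$sigma * tp$F_s1 *
    (amb$T_u^4 - T[1]^4) / th$k_e
  T_ghost_bot <- T[n_z - 1] -
    2 * dz * cfg$secondary$h_b * (T[n_z] - amb$T_b) / th$k_e
  Tm <- c(T_ghost_top, T[seq_len(n_z - 1)])
  Tp <- c(T[2:n_z], T_ghost_bot)
  diff_term <- th$k_e / (th$rho_e * th$Cp_e) * (Tp - 2 * T + Tm) / dz^2
  des_term <- th$rho_d * th$dH_des / (th$rho_e * th$Cp_e) * dc_w
  q_side <- 4 * tp$sigma * tp$F_s3 * (amb$T_c^4 - T^4) / cfg$vial$d
  dT <- diff_term + des_term + q_side / (th$rho_e * th$Cp_e)
  list(dT = dT, dc_w = dc_w)
}

#' Simulate secondary drying
#'
#' Integrates dried-cake heat conduction coupled to linear-driving-force
#' desorption until the volume-average bound-water concentration reaches the
#' target `c_w_inf` (terminal event).
#'
#' @param cfg A [lyo_config()]; operating conditions from `cfg$secondary`,
#'   kinetics from `cfg$desorption`.
#' @param T_0 Initial temperature, scalar or length-`n_z` profile (K).
#' @param c_w0 Initial concentration, scalar or length-`n_z` profile (kg/kg).
#' @param H Product height (m).
#' @param n_z Number of grid nodes.
#' @param dt_out Output interval (s).
#' @param t_max Integration horizon (s).
#'
#' @return List of class `lyo_secondary`:
#'   \describe{
#'     \item{summary}{data.frame `t`, `c_w_mean`, `T_bottom`, `T_top`,
#'       `T_max`.}
#'     \item{T_profiles}{temperature matrix (time x node).}
#'     \item{c_profiles}{bound-water matrix (time x node).}
#'     \item{t_d2}{end time (s), `NA` if the horizon was hit first.}
#'   }
#' @export
simulate_secondary <- function(cfg, T_0 = NULL, c_w0 = NULL, H = NULL,
                               n_z = NULL, dt_out = NULL, t_max = NULL) {
  sc <- cfg$secondary
  de <- cfg$desorption
  numer <- cfg$numerics
  if (is.null(T_0)) T_0 <- sc$T_0
  if (is.null(c_w0)) c_w0 <- de$c_w0
  if (is.null(H)) H <- cfg$derived$H
  if (is.null(n_z)) n_z <- numer$n_z
  if (is.null(dt_out)) dt_out <- max(numer$dt_out, 30)
  if (is.null(t_max)) t_max <- numer$t_max_drying
  Tv <- if (length(T_0) == 1L) rep(T_0, n_z) else T_0
  cv <- if (length(c_w0) == 1L) rep(c_w0, n_z) else c_w0
  stopifnot(length(Tv) == n_z, length(cv) == n_z)
  amb_of <- function(t) list(
    T_b = eval_channel(sc$T_b, t), T_u = eval_channel(sc$T_u, t),
    T_c = eval_channel(sc$T_c, t)
  )
  func <- function(t, y, parms) {
    rhs <- secondary_rhs(y[seq_len(n_z)], y[n_z + seq_len(n_z)], amb_of(t),
                         cfg, H = H)
    list(c(rhs$dT, rhs$dc_w))
  }
  rootfunc <- function(t, y, parms) mean(y[n_z + seq_len(n_z)]) - de$c_w_inf
  y0 <- c(Tv, cv)
  names(y0) <- c(paste0("T", seq_len(n_z)), paste0("c", seq_len(n_z)))
  if (mean(cv) <= de$c_w_inf) {
    # degenerate target: already dry
    return(structure(list(
      summary = data.frame(t = 0, c_w_mean = mean(cv), T_bottom = Tv[n_z],
                           T_top = Tv[1], T_max = max(Tv)),
      T_profiles = matrix(Tv, nrow = 1), c_profiles = matrix(cv, nrow = 1),
      t_d2 = 0, H = H, n_z = n_z, config = cfg
    ), class = "lyo_secondary"))
  }
  times <- stage_times(0, t_max, dt_out)
  out <- run_lsodar(y0, times, func, rootfunc, numer)
  M <- out$out
  T_pr <- M[, 1 + seq_len(n_z), drop = FALSE]
  c_pr <- M[, 1 + n_z + seq_len(n_z), drop = FALSE]
  structure(list(
    summary = data.frame(
      t = M[, "time"], c_w_mean = rowMeans(c_pr),
      T_bottom = T_pr[, n_z], T_top = T_pr[, 1],
      T_max = apply(T_pr, 1, max)
    ),
    T_profiles = unname(T_pr), c_profiles = unname(c_pr),
    t_d2 = if (!is.null(out$troot)) out$t_end else NA_real_,
    H = H, n_z = n_z, config = cfg
  ), class = "lyo_secondary")
}
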