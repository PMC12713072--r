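#' Chamber water-vapor balance
#'
#' Rate of change of the chamber water partial pressure when the total
#' sublimation flow from `n_vial` vials competes with a finite condenser
#' capacity: `dp_w_c/dt = (j_w - j_w_max) R T_bar / (V_c M_w)` with
#' `j_w = n_vial A_z N_w`. Condenser removal is limited to the vapor actually
#' available (incoming flow plus chamber inventory released over a short
#' relaxation time), so an oversized condenser drives the pressure smoothly
#' to zero instead of through it.
#'
#' @param p_w_c Chamber water partial pressure (Pa).
#' @param N_w Per-vial sublimation flux (kg m^-2 s^-1).
#' @param cond Condenser parameters: list `j_w_max` (kg s^-1), `V_c` (m^3),
#'   `T_bar` (K), `n_vial`.
#' @param A_z Vial cross-section (m^2).
#' @param M_w Molar mass of water (kg mol^-1).
#' @param R Gas constant (J mol^-1 K^-1).
#' @param tau_inv Inventory relaxation time (s) limiting how fast the
#'   condenser can draw down the chamber inventory.
#' @return `dp_w_c/dt` (Pa s^-1).
#' @export
chamber_vapor_rhs <- function(p_w_c, N_w, cond, A_z, M_w = 0.018, R = 8.314,
                              tau_inv = 1) {
  j_w <- cond$n_vial * A_z * N_w
  # removal cannot exceed incoming vapor plus the releasable inventory
  j_avail <- j_w + max(p_w_c, 0) * cond$V_c * M_w / (R * cond$T_bar * tau_inv)
  j_rem <- min(cond$j_w_max, j_avail)
  (j_w - j_rem) * R * cond$T_bar / (cond$V_c * M_w)
}

#' Condenser parameter set
#'
#' @param j_w_max Maximum condenser capacity (kg s^-1).
#' @param V_c Chamber volume (m^3).
#' @param T_bar Mean chamber gas temperature (K).
#' @param n_vial Number of vials in the chamber.
#' @return A named list.
#' @export
condenser_params <- function(j_w_max = 1.8e-5, V_c = 0.118, T_bar = 260,
                             n_vial = 200) {
  stopifnot(j_w_max > 0, V_c > 0, T_bar > 0, n_vial >= 0)
  list(j_w_max = j_w_max, V_c = V_c, T_bar = T_bar, n_vial = n_vial)
}

#' Primary drying coupled to the chamber vapor balance
#'
#' Like [simulate_primary()], but the chamber water partial pressure is a
#' dynamic state fed back into the sublimation driving force, so condenser
#' failure / choked flow (total vapor production exceeding the condenser
#' capacity) raises the chamber pressure and slows drying.
#'
#' @inheritParams simulate_primary
#' @param condenser Condenser parameters from [condenser_params()].
#' @param p_w_c0 Initial chamber water partial pressure (Pa); defaults to
#'   the configured constant `cfg$primary$p_w_c`.
#' @return As [simulate_primary()], with a `p_w_c` column added to the
#'   summary.
#' @export
simulate_primary_with_condenser <- function(cfg, condenser, T_0 = NULL,
                                            H = NULL, n_z = NULL,
                                            p_w_c0 = NULL, dt_out = NULL,
                                            t_max = NULL) {
  pr <- cfg$primary
  numer <- cfg$numerics
  if (is.null(T_0)) T_0 <- pr$T_0
  if (is.null(H)) H <- cfg$derived$H
  if (is.null(n_z)) n_z <- numer$n_z
  if (is.null(p_w_c0)) p_w_c0 <- eval_channel(pr$p_w_c, 0)
  if (is.null(dt_out)) dt_out <- max(numer$dt_out, 10)
  if (is.null(t_max)) t_max <- numer$t_max_drying
  A_z <- cfg$derived$A_z
  M_w <- cfg$formulation$M_w
  theta0 <- if (length(T_0) == 1L) rep(T_0, n_z) else T_0
  amb_of <- function(t) list(
    T_b = eval_channel(pr$T_b, t), T_u = eval_channel(pr$T_u, t),
    T_c = eval_channel(pr$T_c, t)
  )
  func <- function(t, y, parms) {
    amb <- amb_of(t)
    amb$p_w_c <- max(y[n_z + 2L], 0)
    S <- min(max(y[n_z + 1L], 0), H * (1 - numer$S_floor))
    rhs <- primary_rhs(y[seq_len(n_z)], S, amb, cfg, H = H)
    dp <- chamber_vapor_rhs(y[n_z + 2L], rhs$N_w, condenser, A_z, M_w)
    list(c(rhs$dtheta, rhs$dS, dp), N_w = rhs$N_w)
  }
  rootfunc <- function(t, y, parms) y[n_z + 1L] - H * (1 - numer$S_floor)
  y0 <- c(theta0, numer$S_floor * H, p_w_c0)
  names(y0) <- c(paste0("T", seq_len(n_z)), "S", "p_w_c")
  times <- stage_times(0, t_max, dt_out)
  out <- run_lsodar(y0, times, func, rootfunc, numer)
  M <- out$out
  profs <- M[, 1 + seq_len(n_z), drop = FALSE]
  structure(list(
    summary = data.frame(
      t = M[, "time"], S = M[, "S"], N_w = M[, ncol(M)],
      p_w_c = M[, "p_w_c"],
      T_front = profs[, 1], T_bottom = profs[, n_z],
      T_max = apply(profs, 1, max), T_min = apply(profs, 1, min)
    ),
    profiles = unname(profs),
    t_d1 = if (!is.null(out$troot)) out$t_end else NA_real_,
    condenser = condenser, H = H, n_z = n_z, config = cfg
  ), class = "lyo_primary")
}

#' Pressure plateau of a condenser-failure run
#'
#' Locates the point where the chamber water partial pressure becomes
#' constant. The pressure rises quickly onto the slow manifold (sublimation
#' flow pinned at the condenser capacity) and then tracks the slowly warming
#' front until it levels off; the plateau is taken at the first interior
#' maximum of the trace (`dp/dt = 0`). If the trace is still rising at the
#' end of the run, the first time the pressure stays within `tol` (relative)
#' of its final value is used instead.
#'
#' @param run Result of [simulate_primary_with_condenser()].
#' @param tol Relative fallback tolerance defining "constant" (default 1%).
#' @return List with `p_plateau` (Pa) and `t_plateau` (s).
#' @export
condenser_plateau <- function(run, tol = 0.01) {
  s <- run$summary
  i <- which.max(s$p_w_c)
  if (i < nrow(s)) {
    return(list(p_plateau = s$p_w_c[i], t_plateau = s$t[i]))
  }
  p_inf <- s$p_w_c[nrow(s)]
  within <- abs(s$p_w_c - p_inf) <= tol * abs(p_inf)
  stays <- rev(cumprod(rev(within))) > 0
  j <- which(stays)[1]
  list(p_plateau = p_inf, t_plateau = s$t[j])
}
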