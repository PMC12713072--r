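#' Run a complete freeze / primary-drying / secondary-drying cycle
#'
#' Simulates the three process stages consecutively with state handoff: the
#' primary-drying initial temperature is the (uniform) product temperature at
#' the end of the freezing cooling stage, and the secondary-drying initial
#' temperature profile is the final primary-drying profile mapped onto the
#' fixed grid. The initial bound-water concentration is the configured
#' `c_w0` unless a profile is supplied.
#'
#' @param cfg A [lyo_config()].
#' @param seed Integer seed (stochastic nucleation only).
#' @param c_w0 Optional initial bound-water profile for secondary drying.
#' @param handoff Which freezing state feeds primary drying: end of the
#'   cooling stage (`"t_f5"`, default) or end of solidification (`"t_f4"`).
#' @return List of class `lyo_cycle` with elements `freezing`, `primary`,
#'   `secondary` (the per-stage results) and `summary` (named numeric vector
#'   of stage times and key scalars).
#' @export
run_full_cycle <- function(cfg, seed = NULL, c_w0 = NULL,
                           handoff = c("t_f5", "t_f4")) {
  handoff <- match.arg(handoff)
  fr <- simulate_freezing(cfg, seed = seed)
  T_handoff <- if (handoff == "t_f5") {
    fr$final$T
  } else {
    tr <- fr$trajectory
    utils::tail(tr$T[tr$stage == "solidification"], 1)
  }
  pd <- simulate_primary(cfg, T_0 = T_handoff)
  if (is.na(pd$t_d1)) stop("primary drying did not finish within the horizon",
                           call. = FALSE)
  T_sec0 <- pd$profiles[nrow(pd$profiles), ]
  sd <- simulate_secondary(cfg, T_0 = T_sec0, c_w0 = c_w0)
  if (is.na(sd$t_d2)) stop("secondary drying did not finish within the horizon",
                           call. = FALSE)
  summary <- c(
    unlist(fr$times),
    t_d1 = pd$t_d1, t_d2 = sd$t_d2,
    cycle_time = fr$times$t_f5 + pd$t_d1 + sd$t_d2,
    T_max_primary = max(pd$summary$T_max),
    T_max_secondary = max(sd$summary$T_max),
    evaporated = fr$evaporated,
    c_w_final = sd$summary$c_w_mean[nrow(sd$summary)]
  )
  structure(list(freezing = fr, primary = pd, secondary = sd,
                 summary = summary, handoff = handoff),
            class = "lyo_cycle")
}

#' @export
print.lyo_cycle <- function(x, ...) {
  s <- x$summary
  cat("<lyo_cycle>\n")
  cat(sprintf("  freezing:  t_f5 = %.2f h (nucleation at %.2f h)\n",
              s[["t_f5"]] / 3600, s[["t_f2"]] / 3600))
  cat(sprintf("  primary:   t_d1 = %.2f h, max T = %.1f K\n",
              s[["t_d1"]] / 3600, s[["T_max_primary"]]))
  cat(sprintf("  secondary: t_d2 = %.2f h, final c_w = %.4g kg/kg\n",
              s[["t_d2"]] / 3600, s[["c_w_final"]]))
  invisible(x)
}

#' Pre-nucleation trajectory with cumulative nucleation probability
#'
#' Integrates the preconditioning (and, if configured, VISF) dynamics over
#' the full horizon with the nucleation event disabled, recording the
#' cumulative first-nucleation probability `P(t)`. Because the
#' pre-nucleation dynamics do not depend on the stochastic draw, every
#' Monte-Carlo run shares this path; nucleation times are obtained by
#' inverting it.
#'
#' @param cfg A [lyo_config()] with stochastic kinetics set.
#' @return data.frame with columns `t`, `T`, `m_w`, `P`.
#' @export
nucleation_path <- function(cfg) {
  nuc <- cfg$nucleation
  if (is.na(nuc$k_n) || is.na(nuc$b_n)) {
    stop("nucleation_path requires k_n and b_n", call. = FALSE)
  }
  fz <- cfg$freezing
  proto <- freezing_protocol(cfg)
  m_s <- cfg$derived$m_s
  fm <- cfg$formulation
  numer <- cfg$numerics
  lambda_of <- function(T, m_w) {
    T_fl <- freezing_point(m_w, m_s, fm$K_f, fm$M_s, fm$T_f_w)
    V_liq <- m_w / fm$rho_w + m_s / fm$rho_s
    nucleation_rate(T, T_fl, V_liq, nuc$k_n, nuc$b_n)
  }
  t_sw <- if (fz$visf) fz$t_visf else fz$t_max
  pre_func <- function(t, y, parms) {
    amb <- eval_protocol(proto, t)
    dT <- precondition_rhs(y[1], cfg$derived$m_w0, m_s, amb, cfg)
    list(c(dT, lambda_of(y[1], cfg$derived$m_w0) * (1 - y[2])))
  }
  out1 <- run_lsodar(c(T = fz$T_0, P = 0), stage_times(0, t_sw, numer$dt_out),
                     pre_func, NULL, numer)
  path <- data.frame(t = out1$out[, "time"], T = out1$out[, "T"],
                     m_w = cfg$derived$m_w0, P = out1$out[, "P"])
  if (fz$visf) {
    visf_func <- function(t, y, parms) {
      amb <- eval_protocol(proto, t)
      rhs <- visf_rhs(y[1], max(y[2], 1e-9), m_s, amb, cfg)
      list(c(rhs$dT, rhs$dm_w, lambda_of(y[1], max(y[2], 1e-9)) * (1 - y[3])))
    }
    # stop once nucleation is (numerically) certain or the liquid runs low
    visf_root <- function(t, y, parms) {
      c(y[3] - (1 - 1e-10), y[2] - 1e-3 * cfg$derived$m_w0)
    }
    y0 <- c(T = out1$y_end[["T"]], m_w = cfg$derived$m_w0,
            P = out1$y_end[["P"]])
    out2 <- run_lsodar(y0, stage_times(t_sw, fz$t_max, numer$dt_out),
                       visf_func, visf_root, numer)
    seg <- data.frame(t = out2$out[, "time"], T = out2$out[, "T"],
                      m_w = out2$out[, "m_w"], P = out2$out[, "P"])
    path <- rbind(path, seg[-1, ])  # drop the duplicated switch time
  }
  path
}

#' Monte-Carlo ensemble of stochastic nucleation
#'
#' Draws `n_runs` first-nucleation events under the configured protocol by
#' inverse-transform sampling of the shared cumulative-probability path
#' (see [nucleation_path()]); this is exact in distribution and avoids
#' re-integrating identical pre-nucleation dynamics. Runs whose uniform draw
#' exceeds the probability reached within the horizon are censored.
#'
#' @param cfg A [lyo_config()] with stochastic kinetics.
#' @param n_runs Number of Monte-Carlo runs.
#' @param seed Integer seed; the ensemble is reproducible given the seed.
#' @return List with `draws` (data.frame `u`, `t_nuc`, `T_nuc`), `stats`
#'   (mean/sd/quantiles of nucleation time and temperature), `n_censored`,
#'   and the shared `path`.
#' @export
monte_carlo_freezing <- function(cfg, n_runs = 1e4, seed = 1) {
  path <- nucleation_path(cfg)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  u <- stats::runif(n_runs)
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else assign(".Random.seed", old, envir = globalenv())
  t_nuc <- invert_probability_path(path$t, path$P, u)
  T_nuc <- stats::approx(path$t, path$T, xout = t_nuc, rule = 2)$y
  ok <- !is.na(t_nuc)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  stat <- function(x) c(mean = mean(x), sd = stats::sd(x),
                        stats::quantile(x, qs))
  list(
    draws = data.frame(u = u, t_nuc = t_nuc, T_nuc = T_nuc),
    stats = list(t_nuc = stat(t_nuc[ok]), T_nuc = stat(T_nuc[ok])),
    n_censored = sum(!ok),
    path = path
  )
}

# earliest t with P(t) >= u (linear interpolation between recorded points);
# NA when u exceeds the probability reached within the horizon
invert_probability_path <- function(t, P, u) {
  stopifnot(!is.unsorted(P))
  vapply(u, function(ui) {
    if (ui > P[length(P)]) return(NA_real_)
    i <- which(P >= ui)[1]
    if (i == 1L || P[i] == P[i - 1L]) return(t[i])
    t[i - 1L] + (ui - P[i - 1L]) / (P[i] - P[i - 1L]) * (t[i] - t[i - 1L])
  }, numeric(1))
}
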