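#' Bundled scenario fixtures
#'
#' Builds the configuration for each bundled scenario: the full-cycle
#' default, the three validation setups (freezing; primary drying at low and
#' high shelf temperature; secondary drying at two initial moisture levels),
#' the VISF pressure study, the condenser-failure analysis and the
#' thermal-gradient demonstration.
#'
#' Fields that exist in the source scenarios only as plotted curves (the
#' measured gas-temperature profile of the freezing validation) are replaced
#' by synthetic stand-ins and marked as such here: case `"1"` uses a linear
#' gas-temperature ramp 268 K to 233 K over 2 h (synthetic). Stochastic
#' nucleation kinetics are never printed in the source tables; case
#' `"visf-study"` ships synthetic demonstration values
#' (`k_n = 3.3e-9`, `b_n = 12`).
#'
#' @param case One of `"default"`, `"1"`, `"2a"`, `"2b"`, `"3a"`, `"3b"`,
#'   `"visf-study"`, `"condenser-failure"`, `"gradient-demo"`.
#' @param visf_pressure VISF target pressure (Pa) for `"visf-study"`.
#' @param stochastic Use stochastic nucleation for `"visf-study"`.
#' @return A list with elements `config` (a [lyo_config()]) and, where the
#'   scenario needs them, `condenser` ([condenser_params()]) and `H`
#'   (height override, m).
#' @export
#' @examples
#' make_fixture("2b")$config$primary$T_b  # 313 K
make_fixture <- function(case = c("default", "1", "2a", "2b", "3a", "3b",
                                  "visf-study", "condenser-failure",
                                  "gradient-demo"),
                         visf_pressure = 100, stochastic = FALSE) {
  case <- as.character(case[1])
  valid <- c("default", "1", "2a", "2b", "3a", "3b", "visf-study",
             "condenser-failure", "gradient-demo")
  if (!case %in% valid) {
    stop("unknown case '", case, "'; valid cases: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  fx <- switch(
    case,
    "default" = list(config = lyo_config()),
    "1" = list(config = lyo_config(
      freezing = list(
        T_0 = 280, visf = FALSE,
        # measured gas profile not tabulated; synthetic linear ramp
        T_g_pre = protocol_channel(c(0, 7200), c(268, 233)),
        T_cu_pre = 272,
        t_max = 4 * 3600
      ),
      transport = list(h_s1 = 7, h_s2 = 18, h_s3 = 15),
      nucleation = list(mode = "deterministic", T_n = 263.18)
    )),
    "2a" = list(config = lyo_config(
      primary = list(T_0 = 231, T_b = 263, T_c = 275, T_u = 275, h_b = 16),
      transport = list(R_p1 = 3.4e7, R_p2 = 1)
    )),
    "2b" = list(config = lyo_config(
      primary = list(T_0 = 235, T_b = 313, T_c = 275, T_u = 275, h_b = 16),
      transport = list(R_p1 = 3.4e7, R_p2 = 1)
    )),
    "3a" = list(config = lyo_config(
      formulation = list(V_l = 2e-6),
      secondary = list(T_0 = 273, T_b = 293, T_c = 285, T_u = 285, h_b = 16),
      desorption = list(c_w0 = 0.088, f_a = 0.42, E_a = 2.05e4)
    )),
    "3b" = list(config = lyo_config(
      formulation = list(V_l = 2e-6),
      secondary = list(T_0 = 273, T_b = 293, T_c = 285, T_u = 285, h_b = 16),
      desorption = list(c_w0 = 0.075, f_a = 0.42, E_a = 2.05e4)
    )),
    "visf-study" = list(config = lyo_config(
      freezing = list(
        T_0 = 280, visf = TRUE, t_visf = 0.25 * 3600, visf_ramp = 60,
        T_g_pre = 268, T_g_visf = 260,
        T_cu_pre = 268, T_cu_visf = 260,
        p_t_pre = 1e5, p_t_visf = visf_pressure,
        t_max = 4 * 3600
      ),
      transport = list(h_s2 = 60, h_s3 = 60),
      nucleation = if (stochastic) {
        # synthetic demonstration kinetics (not from the source tables)
        list(mode = "stochastic", k_n = 3.3e-9, b_n = 12, T_n = 260)
      } else {
        list(mode = "deterministic", T_n = 260)
      }
    )),
    "condenser-failure" = list(
      config = lyo_config(),
      condenser = condenser_params(j_w_max = 1.8e-5, V_c = 0.118,
                                   T_bar = 260, n_vial = 200)
    ),
    "gradient-demo" = list(
      config = lyo_config(primary = list(h_b = 30)),
      H = 0.02
    )
  )
  fx$case <- case
  fx
}
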