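# shared ambient records and small helpers for hand-evaluated oracles

default_cfg <- lyo_config()

# ambient record with every channel at the same temperature (equilibrium)
amb_uniform <- function(T, p_t = 1e5, p_w_c = 0) {
  list(T_u = T, T_g = T, T_b = T, T_c = T, p_t = p_t, p_w_c = p_w_c)
}

# trapezoid quadrature of a sampled signal
trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
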