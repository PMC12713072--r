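#' Piecewise-linear protocol channel
#'
#' A protocol channel is a time series of ambient-condition breakpoints
#' (temperature or pressure) interpolated linearly in time and clamped to the
#' endpoint values outside the breakpoint range. Plain numeric scalars are
#' accepted everywhere a channel is: they denote a constant condition.
#'
#' @param time Breakpoint times (s), strictly increasing.
#' @param value Channel values at the breakpoints (K or Pa).
#' @return An object of class `protocol_channel`.
#' @export
#' @examples
#' p <- protocol_channel(c(0, 60), c(1e5, 1e4))  # 1-min pressure ramp
#' eval_channel(p, 30)                           # 5.5e4 Pa
protocol_channel <- function(time, value) {
  stopifnot(length(time) == length(value), length(time) >= 1)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("breakpoint times must be strictly increasing", call. = FALSE)
  }
  structure(list(time = as.numeric(time), value = as.numeric(value)),
            class = "protocol_channel")
}

#' Evaluate a protocol channel at given times
#'
#' @param ch A `protocol_channel` or a numeric scalar (constant channel).
#' @param t Time(s) at which to evaluate (s).
#' @return Channel value(s); linear between breakpoints, endpoint-clamped
#'   outside.
#' @export
eval_channel <- function(ch, t) {
  if (is.numeric(ch) && length(ch) == 1L) return(rep(ch, length(t)))
  stopifnot(inherits(ch, "protocol_channel"))
  if (length(ch$time) == 1L) return(rep(ch$value, length(t)))
  stats::approx(ch$time, ch$value, xout = t, rule = 2)$y
}

#' Step change expressed as a short linear ramp
#'
#' Operating protocols switch set-points between stages; to keep the ODE
#' right-hand sides continuous, a step at `t0` from `from` to `to` is modeled
#' as a linear ramp of duration `ramp` seconds.
#'
#' @param from,to Values before/after the switch.
#' @param t0 Switch start time (s).
#' @param ramp Ramp duration (s).
#' @return A `protocol_channel`.
#' @export
ramp_channel <- function(from, to, t0, ramp = 60) {
  protocol_channel(c(t0, t0 + ramp), c(from, to))
}

#' Ambient conditions of the freezing stage at time t
#'
#' Builds the full ambient record (gas, upper-surface and wall temperatures,
#' total pressure, chamber water partial pressure) for the freezing protocol
#' in a configuration. Channels in `cfg$freezing` given as scalars follow the
#' two-level pre-/post-VISF scheme with ramps of `visf_ramp` seconds at
#' `t_visf`; channels given as `protocol_channel`s are used as-is.
#'
#' @param cfg A `lyo_config`.
#' @return A list of `protocol_channel`s: `T_g`, `T_c`, `T_u`, `p_t`, `p_w_c`.
#' @export
freezing_protocol <- function(cfg) {
  fz <- cfg$freezing
  two_level <- function(pre, post) {
    if (inherits(pre, "protocol_channel")) return(pre)
    if (!fz$visf) return(protocol_channel(0, pre))
    ramp_channel(pre, post, fz$t_visf, fz$visf_ramp)
  }
  as_ch <- function(x) if (inherits(x, "protocol_channel")) x else protocol_channel(0, x)
  list(
    T_g = two_level(fz$T_g_pre, fz$T_g_visf),
    T_c = two_level(fz$T_cu_pre, fz$T_cu_visf),
    T_u = two_level(fz$T_cu_pre, fz$T_cu_visf),
    p_t = two_level(fz$p_t_pre, fz$p_t_visf),
    p_w_c = as_ch(fz$p_w_c)
  )
}

# evaluate a list of channels at a scalar time -> named list
eval_protocol <- function(proto, t) {
  lapply(proto, eval_channel, t = t)
}
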