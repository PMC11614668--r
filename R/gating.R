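#' Steady-state open fraction of a gating variable
#'
#' \eqn{\eta(V) = 1/2 + 1/2\,\tanh((V - V_{1/2})/\Delta V_\eta)}. Strictly
#' inside (0, 1) for finite voltage; increasing in V when `dv_eta > 0`,
#' decreasing when `dv_eta < 0`.
#'
#' @param v Membrane voltage (mV); vectorized.
#' @param spec A [gating_spec()].
#' @return Open fraction in (0, 1).
#' @export
gating_steady_state <- function(v, spec) {
  0.5 + 0.5 * tanh((v - spec$v_half) / spec$dv_eta)
}

#' Voltage-dependent time constant of a gating variable
#'
#' \eqn{\tau(V) = \tau_0 + \tau_1(1 - \tanh^2((V - V_{1/2})/\Delta V_\tau))},
#' a bell centred on `v_half` with range `[tau0, tau0 + tau1]`.
#'
#' @inheritParams gating_steady_state
#' @return Time constant (ms).
#' @export
gating_time_constant <- function(v, spec) {
  th <- tanh((v - spec$v_half) / spec$dv_tau)
  spec$tau0 + spec$tau1 * (1 - th * th)
}

#' Goldman-Hodgkin-Katz flux factor for the calcium channel
#'
#' Evaluates \eqn{V \,(\mathrm{Ca}_{ext} e^{-x} - \mathrm{Ca}) /
#' (1 - e^{-x})} with \eqn{x = ZFV/RT}, the nonlinear driving term of the
#' T-type calcium current. Concentrations enter as numeric values in uM, so
#' the factor has units mV x uM and multiplying by `g_cat` (nS) and the
#' a^3 b^3 gate product yields a current treated as pA.
#'
#' The quotient has a removable singularity at V = 0; for |x| < 1e-4 a
#' second-order series branch \eqn{(RT/ZF)(1 + x/2 + x^2/12)
#' (\mathrm{Ca}_{ext} e^{-x} - \mathrm{Ca})} is used, which matches the
#' direct evaluation to better than 1e-6 relative at the branch point.
#'
#' @param v Membrane voltage (mV); vectorized.
#' @param ca Intracellular calcium concentration (uM); vectorized.
#' @param params Interneuron parameters ([int_neuron_params()]).
#' @return Flux factor in mV x uM; positive values depolarize.
#' @export
ghk_factor <- function(v, ca, params) {
  if (any(ca <= 0)) stop("intracellular calcium must be positive", call. = FALSE)
  vt <- rt_over_zf(params)          # RT/ZF in mV
  x <- v / vt
  emx <- exp(-x)
  num <- params$ca_ext * emx - ca
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  if (any(small)) {
    xs <- x[small]
    out[small] <- vt * (1 + xs / 2 + xs * xs / 12) * num[small]
  }
  if (any(!small)) {
    out[!small] <- v[!small] * num[!small] / (1 - emx[!small])
  }
  out
}
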