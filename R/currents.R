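#' Construct a single-neuron state
#'
#' Default initial condition: voltage at the leak reversal, every gate at its
#' steady-state open fraction for that voltage, and (interneurons) calcium at
#' its resting concentration. This equilibrium-flavoured start minimizes
#' onset transients in network runs.
#'
#' @param params A [ra_neuron_params()] or [int_neuron_params()] object.
#' @param v Initial voltage (mV); default `params$e_l`.
#' @param gates Optional named numeric vector of gate open fractions in
#'   `[0, 1]`; defaults to the steady state at `v`.
#' @param ca Initial intracellular calcium (uM), interneurons only.
#' @return An object of class `neuron_state`: list with `v`, `gates`, and
#'   `ca` (NA for projection neurons).
#' @export
neuron_state <- function(params, v = params$e_l, gates = NULL, ca = NULL) {
  if (is.null(gates)) {
    gates <- vapply(params$gates, function(sp) gating_steady_state(v, sp), 0)
  }
  stopifnot(setequal(names(gates), names(params$gates)),
            all(gates >= 0 & gates <= 1))
  if (params$kind == "HVC_I") {
    if (is.null(ca)) ca <- params$ca0
    stopifnot(ca > 0)
  } else {
    ca <- NA_real_
  }
  structure(list(v = v, gates = gates[names(params$gates)], ca = ca),
            class = "neuron_state")
}

#' Per-channel membrane currents
#'
#' Evaluates each ionic current in the depolarizing-positive convention
#' \eqn{I = g \cdot \mathrm{gates} \cdot (E - V)}; the T-type calcium
#' current uses the GHK flux factor instead of a linear driving force,
#' \eqn{I_{CaT} = g_{CaT}\, a^3 b^3\, \mathrm{GHK}(V, [Ca])}.
#'
#' @param state A [neuron_state()].
#' @param params Matching neuron parameters.
#' @param channels Which currents to return. Defaults to every channel the
#'   neuron kind carries (`na`, `k`, `l` for HVC_RA; plus `cat`, `h` for the
#'   interneuron). Requesting `cat` or `h` for a projection neuron is a kind
#'   mismatch and raises an error.
#' @return Named numeric vector of currents (pA).
#' @export
membrane_currents <- function(state, params, channels = NULL) {
  have <- if (params$kind == "HVC_I") c("na", "k", "l", "cat", "h") else
    c("na", "k", "l")
  if (is.null(channels)) channels <- have
  bad <- setdiff(channels, have)
  if (length(bad)) {
    stop(sprintf("channel(s) %s not present in a %s neuron",
                 paste(bad, collapse = ", "), params$kind), call. = FALSE)
  }
  g <- state$gates
  v <- state$v
  out <- vapply(channels, function(ch) {
    switch(ch,
      na = params$g_na * g[["m"]]^3 * g[["h"]] * (params$e_na - v),
      k = params$g_k * g[["n"]]^4 * (params$e_k - v),
      l = params$g_l * (params$e_l - v),
      cat = params$g_cat * g[["a"]]^3 * g[["b"]]^3 *
        ghk_factor(v, state$ca, params),
      h = params$g_h * g[["H"]]^2 * (params$e_h - v)
    )
  }, 0)
  names(out) <- channels
  out
}

#' Time derivative of a single-neuron state
#'
#' The membrane equation sums all channel currents, synaptic current and
#' background current (all depolarizing-positive, pA) and divides by the
#' capacitance (pF), giving dV/dt in mV/ms. Each gate relaxes first-order
#' toward its voltage-dependent steady state, and interneuron calcium obeys
#' \eqn{d[Ca]/dt = \phi I_{CaT} + ([Ca]_0 - [Ca])/\tau_{Ca}}.
#'
#' @inheritParams membrane_currents
#' @param i_syn Summed synaptic current (pA), depolarizing-positive.
#' @param i_background Constant background current (pA).
#' @return A list shaped like the state: `v` (mV/ms), `gates` (1/ms), `ca`
#'   (uM/ms or NA).
#' @export
state_derivative <- function(state, params, i_syn = 0, i_background = 0) {
  cur <- membrane_currents(state, params)
  dv <- (sum(cur) + i_syn + i_background) / params$capacitance
  v <- state$v
  dgates <- vapply(names(params$gates), function(nm) {
    sp <- params$gates[[nm]]
    (gating_steady_state(v, sp) - state$gates[[nm]]) / gating_time_constant(v, sp)
  }, 0)
  dca <- NA_real_
  if (params$kind == "HVC_I") {
    dca <- params$phi * cur[["cat"]] + (params$ca0 - state$ca) / params$tau_ca
  }
  list(v = dv, gates = dgates, ca = dca)
}
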