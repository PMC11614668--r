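#' Presynaptic transmitter-release parameters
#'
#' The cleft transmitter concentration is a sigmoid of presynaptic voltage,
#' \eqn{[T] = T_{max} / (1 + e^{-(V_{pre} - V_p)/K_p})}: effectively zero at
#' rest and saturating at `t_max` during a spike. This collapses the whole
#' release cascade into its steady state.
#'
#' @param t_max Maximal cleft concentration (mM).
#' @param v_p Half-activation voltage (mV).
#' @param k_p Steepness (mV); > 0.
#' @return An object of class `release_params`.
#' @export
release_params <- function(t_max = 2.84, v_p = 2, k_p = 5) {
  stopifnot(t_max > 0, k_p > 0)
  structure(list(t_max = t_max, v_p = v_p, k_p = k_p),
            class = "release_params")
}

#' Postsynaptic receptor kinetics
#'
#' First-order open/close kinetics for ionotropic receptors. Defaults:
#' AMPA (alpha 1.1 /(mM ms), beta 0.19 /ms, E 0 mV) and GABA_A
#' (alpha 5 /(mM ms), beta 0.18 /ms, E -80 mV).
#'
#' @param kind `"AMPA"` or `"GABA_A"`.
#' @param alpha Opening rate (1/(mM ms)); overrides the kind default.
#' @param beta Closing rate (1/ms).
#' @param e_rev Reversal potential (mV).
#' @return An object of class `receptor_params`.
#' @export
receptor_params <- function(kind = c("AMPA", "GABA_A"), alpha = NULL,
                            beta = NULL, e_rev = NULL) {
  kind <- match.arg(kind)
  def <- switch(kind,
    AMPA = list(alpha = 1.1, beta = 0.19, e_rev = 0),
    GABA_A = list(alpha = 5, beta = 0.18, e_rev = -80)
  )
  p <- list(kind = kind,
            alpha = alpha %||% def$alpha,
            beta = beta %||% def$beta,
            e_rev = e_rev %||% def$e_rev)
  stopifnot(p$alpha > 0, p$beta > 0)
  structure(p, class = "receptor_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transmitter concentration released by a presynaptic voltage
#'
#' @param v_pre Presynaptic membrane voltage (mV); vectorized.
#' @param rp A [release_params()].
#' @return Concentration in (0, t_max) mM, increasing in `v_pre`.
#' @export
release_concentration <- function(v_pre, rp = release_params()) {
  rp$t_max / (1 + exp(-(v_pre - rp$v_p) / rp$k_p))
}

#' Time derivative of the receptor open fraction
#'
#' \eqn{dr/dt = \alpha [T] (1 - r) - \beta r}. Under integration from
#' `r` in `[0, 1]` with nonnegative `[T]` the open fraction stays in
#' `[0, 1]` and relaxes toward \eqn{r_\infty = \alpha T/(\alpha T + \beta)}.
#'
#' @param r Receptor open fraction in `[0, 1]`; vectorized.
#' @param t_conc Transmitter concentration (mM); must be >= 0.
#' @param rp A [receptor_params()].
#' @return Derivative in 1/ms.
#' @export
receptor_derivative <- function(r, t_conc, rp) {
  if (any(t_conc < 0)) {
    stop("transmitter concentration must be nonnegative", call. = FALSE)
  }
  rp$alpha * t_conc * (1 - r) - rp$beta * r
}

#' One directed chemical synapse
#'
#' @param source Presynaptic neuron id, or 0 for the A11 trigger channel.
#' @param target Postsynaptic neuron id.
#' @param receptor A [receptor_params()] object, or `"AMPA"`/`"GABA_A"`.
#' @param g_max Maximal conductance (nS); >= 0.
#' @return An object of class `synapse_spec`.
#' @export
synapse_spec <- function(source, target, receptor, g_max) {
  if (is.character(receptor)) receptor <- receptor_params(receptor)
  stopifnot(inherits(receptor, "receptor_params"), g_max >= 0)
  if (identical(source, target)) {
    stop("a synapse may not connect a neuron to itself", call. = FALSE)
  }
  structure(list(source = as.integer(source), target = as.integer(target),
                 receptor = receptor, g_max = g_max),
            class = "synapse_spec")
}

#' Synaptic current seen by the postsynaptic cell
#'
#' Computed in the same depolarizing-positive convention as the ionic
#' currents, \eqn{I = g_{max}\, r\, (E_{rev} - V_{post})}: AMPA input is
#' positive (excitatory) for a cell below 0 mV, GABA_A input negative
#' (inhibitory) above -80 mV. Summing with "+" into the membrane equation
#' therefore gives each receptor its physiological sign.
#'
#' @param spec A [synapse_spec()].
#' @param v_post Postsynaptic voltage (mV).
#' @param r Receptor open fraction; defaults to 0 if not given.
#' @return Current in pA.
#' @export
synaptic_current <- function(spec, v_post, r) {
  stopifnot(all(r >= 0 & r <= 1))
  spec$g_max * r * (spec$receptor$e_rev - v_post)
}
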