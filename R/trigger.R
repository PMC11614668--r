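#' A11 neuromodulatory trigger-pulse parameters
#'
#' The dopaminergic A11 cell group projects into HVC and gates motif
#' initiation. Its cleft transmitter concentration is modelled as a small
#' baseline `t_min`, an exponential rise with time constant `tau_r` that
#' reaches the peak `t_peak` after the transition time
#' \eqn{t_{trans} = \tau_r \ln(t_{peak}/t_{min})}, and an exponential decay
#' back to baseline with time constant `tau_f`. The decay branch
#' \eqn{(t_{peak} - t_{min}) e^{-(t - t_{on} - t_{trans})/\tau_f} + t_{min}}
#' is constructed from the continuity condition, so the pulse is continuous
#' everywhere and attains its maximum `t_peak` exactly.
#'
#' @param t_min Baseline concentration (mM); small and positive.
#' @param t_peak Peak concentration (mM); must exceed `t_min`.
#' @param tau_r,tau_f Rise and fall time constants (ms).
#' @param onset Time at which the pulse leaves baseline (ms).
#' @return An object of class `trigger_params`.
#' @export
trigger_params <- function(t_min = 0.001, t_peak = 2.84, tau_r = 1.2,
                           tau_f = 1.2, onset = 10) {
  stopifnot(t_min > 0, tau_r > 0, tau_f > 0)
  if (t_min >= t_peak) {
    stop("trigger baseline t_min must be below the peak t_peak", call. = FALSE)
  }
  structure(list(t_min = t_min, t_peak = t_peak, tau_r = tau_r,
                 tau_f = tau_f, onset = onset),
            class = "trigger_params")
}

#' Rise-to-fall transition time of the trigger pulse
#'
#' \eqn{t_{trans} = \tau_r \ln(t_{peak}/t_{min})}, measured from onset;
#' strictly increasing in the peak-to-baseline ratio. With the default
#' parameters this is 1.2 ln(2840) ~ 9.54 ms.
#'
#' @param tp A [trigger_params()].
#' @return Transition time (ms).
#' @export
transition_time <- function(tp) {
  tp$tau_r * log(tp$t_peak / tp$t_min)
}

#' Trigger transmitter concentration at time t
#'
#' Piecewise: baseline `t_min` before `onset`; exponential rise
#' \eqn{t_{min} e^{(t - t_{on})/\tau_r}} until the transition time; then the
#' continuity-matched exponential decay back to baseline.
#'
#' @param t Time (ms); vectorized.
#' @param tp A [trigger_params()].
#' @return Concentration (mM).
#' @export
trigger_concentration <- function(t, tp) {
  tt <- transition_time(tp)
  s <- t - tp$onset
  out <- rep(tp$t_min, length(t))
  rise <- s > 0 & s <= tt
  fall <- s > tt
  out[rise] <- tp$t_min * exp(s[rise] / tp$tau_r)
  out[fall] <- (tp$t_peak - tp$t_min) * exp(-(s[fall] - tt) / tp$tau_f) +
    tp$t_min
  out
}

#' Receptor drive from the trigger pulse
#'
#' The postsynaptic kinetics of the A11 projection follow the same
#' first-order receptor equation as ordinary synapses, with the transmitter
#' concentration supplied by [trigger_concentration()] instead of a
#' presynaptic voltage. In the network the A11 channel forms a GABA_A
#' synapse onto the interneuron.
#'
#' @param t Time (ms).
#' @param tp A [trigger_params()].
#' @param receptor A [receptor_params()].
#' @param r Receptor open fraction.
#' @return dr/dt in 1/ms.
#' @export
trigger_receptor_drive <- function(t, tp, receptor, r) {
  receptor_derivative(r, trigger_concentration(t, tp), receptor)
}
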