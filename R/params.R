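#' Gating-variable kinetics specification
#'
#' Describes one voltage-gated channel activation or inactivation variable.
#' The steady state is a shifted tanh sigmoid,
#' \eqn{\eta(V) = 1/2 + 1/2 \tanh((V - V_{1/2})/\Delta V_\eta)}, and the
#' voltage-dependent time constant is
#' \eqn{\tau(V) = \tau_0 + \tau_1 (1 - \tanh^2((V - V_{1/2})/\Delta V_\tau))}.
#' Most gates use the same slope for both curves; the interneuron's
#' hyperpolarization-activated gate is the one exception and carries distinct
#' `dv_eta` and `dv_tau`.
#'
#' @param v_half Half-activation voltage (mV).
#' @param dv_eta Slope of the steady-state sigmoid (mV); negative for gates
#'   activated by hyperpolarization.
#' @param dv_tau Slope of the time-constant bell (mV). Defaults to `dv_eta`.
#' @param tau0 Voltage-independent floor of the time constant (ms); > 0.
#' @param tau1 Voltage-dependent amplitude of the time constant (ms); >= 0.
#' @param exponent Integer power with which the gate enters its current
#'   (1 to 4).
#' @return An object of class `gating_spec`.
#' @seealso [gating_steady_state()], [gating_time_constant()]
#' @export
gating_spec <- function(v_half, dv_eta, dv_tau = dv_eta, tau0, tau1,
                        exponent = 1L) {
  stopifnot(is.numeric(v_half), length(v_half) == 1L,
            is.numeric(dv_eta), dv_eta != 0,
            is.numeric(dv_tau), dv_tau != 0,
            is.numeric(tau0), tau0 > 0,
            is.numeric(tau1), tau1 >= 0)
  exponent <- as.integer(exponent)
  if (!exponent %in% 1:4) {
    stop("gate exponent must be an integer in 1..4", call. = FALSE)
  }
  structure(
    list(v_half = v_half, dv_eta = dv_eta, dv_tau = dv_tau,
         tau0 = tau0, tau1 = tau1, exponent = exponent),
    class = "gating_spec"
  )
}

# Physical constants for the GHK flux factor (SI; temperature in kelvin).
.FARADAY <- 96485.33212     # C / mol
.GAS_CONST <- 8.314462618   # J / (mol K)

#' HVC_RA projection-neuron parameters
#'
#' Membrane and channel parameters of the excitatory HVC neuron that projects
#' to the robust nucleus of the arcopallium (RA). The cell carries fast
#' sodium (m^3 h), delayed-rectifier potassium (n^4) and leak channels.
#' Defaults are the published values for this cell class; any field can be
#' overridden.
#'
#' Units: conductances nS, reversal potentials mV, capacitance pF. With
#' these units nS x mV = pA and pA / pF = mV/ms, so all table values are
#' usable verbatim in the membrane equation.
#'
#' @param ... Named overrides of the default fields (e.g. `g_na = 1000`).
#' @return An object of class `neuron_params`, kind `"HVC_RA"`.
#' @examples
#' p <- ra_neuron_params()
#' p$g_na
#' @export
ra_neuron_params <- function(...) {
  p <- list(
    kind = "HVC_RA",
    capacitance = 10,            # pF
    g_na = 1050, e_na = 55,      # nS, mV
    g_k = 120, e_k = -90,
    g_l = 3, e_l = -80,
    gates = list(
      m = gating_spec(-30, 9.5, 9.5, 0.01, 0.0, 3L),
      h = gating_spec(-45, -7, -7, 0.1, 0.75, 1L),
      n = gating_spec(-35, 10, 10, 0.1, 0.5, 4L)
    )
  )
  new_neuron_params(p, ...)
}

#' HVC interneuron parameters
#'
#' Parameters of the inhibitory HVC interneuron. On top of the Na/K/leak
#' complement (shared gate kinetics with the projection neuron but larger
#' maximal conductances) the cell carries a T-type low-threshold calcium
#' current (a^3 b^3 gates, Goldman-Hodgkin-Katz flux) and a
#' hyperpolarization-activated inward current (H^2 gate). Intracellular
#' calcium relaxes toward its resting level and is driven by the calcium
#' current: \eqn{d[Ca]/dt = \phi I_{CaT} + ([Ca]_0 - [Ca])/\tau_{Ca}}.
#'
#' @inheritParams ra_neuron_params
#' @return An object of class `neuron_params`, kind `"HVC_I"`.
#' @export
int_neuron_params <- function(...) {
  p <- list(
    kind = "HVC_I",
    capacitance = 10,
    g_na = 1200, e_na = 55,
    g_k = 200, e_k = -90,
    g_l = 3, e_l = -80,
    g_cat = 0.1,                 # nS (GHK-scaled; current comes out in pA)
    g_h = 2, e_h = -40,
    ca_ext = 2500,               # uM extracellular calcium
    ca0 = 1.11,                  # uM resting intracellular calcium
    phi = 3.88,                  # uM / (ms pA)
    tau_ca = 0.143,              # ms
    valence = 2,
    temperature = 310,           # K
    gates = list(
      m = gating_spec(-30, 9.5, 9.5, 0.01, 0.0, 3L),
      h = gating_spec(-45, -7, -7, 0.1, 0.75, 1L),
      n = gating_spec(-35, 10, 10, 0.1, 0.5, 4L),
      a = gating_spec(-30, 32.9, 32.9, 4.44, 4.24, 3L),
      b = gating_spec(-62, -62.5, -62.5, 2.9, 7.57, 3L),
      H = gating_spec(-60, -10, -5.5, 214, 158, 2L)
    )
  )
  new_neuron_params(p, ...)
}

new_neuron_params <- function(p, ...) {
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown neuron parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  validate_neuron_params(p)
  structure(p, class = "neuron_params")
}

validate_neuron_params <- function(p) {
  stopifnot(p$capacitance > 0,
            p$g_na >= 0, p$g_k >= 0, p$g_l >= 0)
  if (p$kind == "HVC_I") {
    stopifnot(p$g_cat >= 0, p$g_h >= 0,
              p$ca_ext > p$ca0, p$ca0 > 0,
              p$tau_ca > 0, p$temperature > 0)
  }
  invisible(p)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<neuron_params> kind %s, C = %g pF\n", x$kind, x$capacitance))
  cat(sprintf("  g_Na %g nS (E %g mV), g_K %g nS (E %g mV), g_L %g nS (E %g mV)\n",
              x$g_na, x$e_na, x$g_k, x$e_k, x$g_l, x$e_l))
  if (x$kind == "HVC_I") {
    cat(sprintf("  g_CaT %g nS (GHK), g_H %g nS (E %g mV), [Ca]_ext %g uM\n",
                x$g_cat, x$g_h, x$e_h, x$ca_ext))
  }
  cat("  gates:", paste(names(x$gates), collapse = ", "), "\n")
  invisible(x)
}

#' Thermal voltage scale RT/ZF for a divalent ion
#'
#' @param params Interneuron parameters (supplies temperature and valence).
#' @return RT/ZF in millivolts.
#' @keywords internal
rt_over_zf <- function(params) {
  1000 * .GAS_CONST * params$temperature / (params$valence * .FARADAY)
}

#' Read the shipped neuron parameter tables
#'
#' The package ships its neuron, synapse and trigger parameter sets as a
#' plain-text table (one record per parameter with value, unit and source
#' tag) under `extdata/`. The programmatic defaults in
#' [ra_neuron_params()], [int_neuron_params()] and friends are cross-checked
#' against this file in the test suite.
#'
#' @return A data frame with columns `block`, `parameter`, `value`, `unit`.
#' @export
parameter_table <- function() {
  path <- system.file("extdata", "model_parameters.tsv", package = "hvcnet",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
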