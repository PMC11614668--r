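#' Assemble an HVC network specification
#'
#' A network is a list of neurons (each with an id, parameters and a
#' constant background current), a list of directed synapses, an optional
#' A11 trigger pulse, and the release parameters shared by all chemical
#' synapses. Synapses whose `source` is 0 are driven by the trigger
#' concentration instead of a presynaptic voltage and require `trigger`.
#'
#' @param neurons List of lists with fields `id` (unique positive integer),
#'   `params` (a `neuron_params`), and `i_background` (pA).
#' @param synapses List of [synapse_spec()] objects.
#' @param trigger A [trigger_params()] or `NULL`.
#' @param release A [release_params()] shared by all synapses.
#' @return An object of class `hvc_network`.
#' @export
hvc_network <- function(neurons, synapses = list(), trigger = NULL,
                        release = release_params()) {
  ids <- vapply(neurons, function(n) as.integer(n$id), 0L)
  if (anyDuplicated(ids) || any(ids <= 0L)) {
    stop("neuron ids must be unique positive integers", call. = FALSE)
  }
  for (n in neurons) {
    stopifnot(inherits(n$params, "neuron_params"), is.finite(n$i_background))
  }
  for (s in synapses) {
    stopifnot(inherits(s, "synapse_spec"))
    if (!s$target %in% ids) {
      stop(sprintf("synapse target %d is not a neuron id", s$target),
           call. = FALSE)
    }
    if (s$source != 0L && !s$source %in% ids) {
      stop(sprintf("synapse source %d is not a neuron id", s$source),
           call. = FALSE)
    }
    if (s$source == 0L && is.null(trigger)) {
      stop("a trigger-driven synapse (source 0) requires a trigger block",
           call. = FALSE)
    }
  }
  structure(list(neurons = neurons, synapses = synapses,
                 trigger = trigger, release = release),
            class = "hvc_network")
}

#' @export
print.hvc_network <- function(x, ...) {
  kinds <- vapply(x$neurons, function(n) n$params$kind, "")
  cat(sprintf("<hvc_network> %d neurons (%d HVC_RA, %d HVC_I), %d synapses%s\n",
              length(x$neurons), sum(kinds == "HVC_RA"), sum(kinds == "HVC_I"),
              length(x$synapses),
              if (is.null(x$trigger)) "" else ", A11 trigger"))
  invisible(x)
}

neuron_entry <- function(id, params, i_background, v0 = NULL) {
  list(id = as.integer(id), params = params, i_background = i_background,
       v0 = v0)
}

#' A single isolated neuron as a network
#'
#' Convenience wrapper used by the rheobase search and the single-cell
#' figures: one neuron, no synapses, no trigger.
#'
#' @param params Neuron parameters.
#' @param i_background Constant background current (pA).
#' @param v0 Optional initial voltage (mV); defaults to the leak reversal.
#' @return An `hvc_network` with one neuron (id 1).
#' @export
build_single_neuron <- function(params = ra_neuron_params(),
                                i_background = 0, v0 = NULL) {
  hvc_network(list(neuron_entry(1L, params, i_background, v0 = v0)))
}

#' Interneuron--HVC_RA microcircuit
#'
#' The two-cell circuit that produces a single projection-neuron burst per
#' trigger pulse: the A11 channel inhibits the tonically firing interneuron
#' (GABA_A, 8 nS), the interneuron inhibits the projection neuron (GABA_A,
#' 8 nS), and -- in the bidirectional variant -- the projection neuron
#' excites the interneuron back (AMPA, 7 nS), which truncates the burst to
#' its physiological length. Neuron 1 is the interneuron, neuron 2 the
#' HVC_RA cell (background 300 pA).
#'
#' The interneuron background defaults to 250 pA: the interneuron model is
#' bistable over a wide current range (a depolarized non-spiking state
#' coexists with the tonic-firing limit cycle), and 250 pA is the smallest
#' round current at which the cell both fires tonically under the baseline
#' A11 drive and recovers tonic firing after the trigger pulse -- the
#' qualitative behavior every network experiment requires. See the
#' package vignette.
#'
#' @param bidirectional Include the HVC_RA -> interneuron AMPA synapse?
#' @param trigger Trigger pulse; default onset 10 ms.
#' @param i_bg_int,i_bg_ra Background currents (pA).
#' @param g_a11_int,g_int_ra,g_ra_int Maximal conductances (nS).
#' @return An `hvc_network` with 2 neurons and 2 (unidirectional) or 3
#'   (bidirectional) synapses.
#' @export
build_microcircuit <- function(bidirectional = TRUE,
                               trigger = trigger_params(),
                               i_bg_int = 250, i_bg_ra = 300,
                               g_a11_int = 8, g_int_ra = 8, g_ra_int = 7) {
  neurons <- list(
    neuron_entry(1L, int_neuron_params(), i_bg_int),
    neuron_entry(2L, ra_neuron_params(), i_bg_ra)
  )
  synapses <- list(
    synapse_spec(0L, 1L, "GABA_A", g_a11_int),
    synapse_spec(1L, 2L, "GABA_A", g_int_ra)
  )
  if (bidirectional) {
    synapses <- c(synapses, list(synapse_spec(2L, 1L, "AMPA", g_ra_int)))
  }
  hvc_network(neurons, synapses, trigger = trigger)
}

#' Feedforward chain of HVC_RA neurons behind the microcircuit
#'
#' The syllable-producing architecture: one interneuron (id 1) and `n_ra`
#' projection neurons (ids 2..n_ra+1). The first projection neuron sits in
#' the bidirectional microcircuit (A11 -> INT, INT -> RA1, RA1 -> INT) and
#' each RA_i excites RA_(i+1) through an AMPA synapse. The first chain edge
#' uses `g_first` (default 10 nS, compensating the weaker first burst) and
#' all later edges `g_chain` (default 8.2 nS, the value at which the 4-spike
#' burst is copied unchanged). Only RA1 receives the 300 pA background;
#' downstream cells get 50 pA, which stands in for the net inhibitory tone
#' that keeps them silent until the burst arrives.
#'
#' @param n_ra Number of projection neurons (>= 2).
#' @param g_first Conductance of the RA1 -> RA2 edge (nS).
#' @param g_chain Conductance of later edges: a scalar, or a vector of
#'   length `n_ra - 2` giving each edge RA_i -> RA_(i+1) for i >= 2.
#' @param trigger Trigger pulse; default onset 10 ms.
#' @param i_bg_first,i_bg_rest,i_bg_int Background currents (pA).
#' @return An `hvc_network` with `n_ra + 1` neurons and `n_ra + 2` synapses.
#' @export
build_chain_network <- function(n_ra = 50, g_first = 10, g_chain = 8.2,
                                trigger = trigger_params(),
                                i_bg_first = 300, i_bg_rest = 50,
                                i_bg_int = 250) {
  n_ra <- as.integer(n_ra)
  if (n_ra < 2L) stop("a chain needs at least 2 HVC_RA neurons", call. = FALSE)
  n_later <- n_ra - 2L
  if (length(g_chain) == 1L) g_chain <- rep(g_chain, n_later)
  if (length(g_chain) != n_later) {
    stop(sprintf("g_chain must be a scalar or have length %d", n_later),
         call. = FALSE)
  }
  ra_params <- ra_neuron_params()
  neurons <- c(
    list(neuron_entry(1L, int_neuron_params(), i_bg_int)),
    lapply(seq_len(n_ra), function(i) {
      neuron_entry(i + 1L, ra_params,
                   if (i == 1L) i_bg_first else i_bg_rest)
    })
  )
  g_edges <- c(g_first, g_chain)
  synapses <- c(
    list(
      synapse_spec(0L, 1L, "GABA_A", 8),
      synapse_spec(1L, 2L, "GABA_A", 8),
      synapse_spec(2L, 1L, "AMPA", 7)
    ),
    lapply(seq_len(n_ra - 1L), function(i) {
      synapse_spec(i + 1L, i + 2L, "AMPA", g_edges[i])
    })
  )
  hvc_network(neurons, synapses, trigger = trigger)
}

#' Ids of the HVC_RA neurons in a network
#'
#' @param net An `hvc_network`.
#' @return Integer vector of neuron ids, in construction order.
#' @export
ra_neuron_ids <- function(net) {
  ids <- vapply(net$neurons, function(n) n$id, 0L)
  kinds <- vapply(net$neurons, function(n) n$params$kind, "")
  ids[kinds == "HVC_RA"]
}
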