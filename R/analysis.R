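#' Detect spikes in a voltage trace
#'
#' A spike is an upward crossing of `threshold` (default 0 mV); the
#' reported spike time is the local voltage maximum following the crossing
#' (up to the point where the trace falls back below threshold). Crossings
#' closer than `guard` to the previous accepted spike are discarded, which
#' makes the detector robust to small ripples on a spike peak.
#'
#' @param v Numeric voltage trace (mV), uniformly sampled.
#' @param time Time grid (ms) of the same length; must be uniform.
#' @param threshold Crossing threshold (mV).
#' @param guard Minimum separation between spikes (ms).
#' @return Numeric vector of spike times (ms), strictly increasing.
#' @export
detect_spikes <- function(v, time, threshold = 0, guard = 1) {
  stopifnot(length(v) == length(time), length(v) >= 2L)
  dts <- diff(time)
  if (diff(range(dts)) > 1e-9 * max(dts)) {
    stop("detect_spikes requires a uniform time grid", call. = FALSE)
  }
  above <- v >= threshold
  ups <- which(!above[-length(above)] & above[-1L]) + 1L
  if (!length(ups)) return(numeric(0))
  downs <- which(above[-length(above)] & !above[-1L])
  spikes <- numeric(0)
  for (i in ups) {
    j <- downs[downs >= i]
    end <- if (length(j)) j[1L] else length(v)
    peak <- i - 1L + which.max(v[i:end])
    tpk <- time[peak]
    if (!length(spikes) || tpk - spikes[length(spikes)] >= guard) {
      spikes <- c(spikes, tpk)
    }
  }
  spikes
}

#' Spike table for a whole simulation
#'
#' Applies [detect_spikes()] to every recorded neuron.
#'
#' @param traces An `hvc_traces` object.
#' @inheritParams detect_spikes
#' @return Data frame with columns `neuron` (id) and `time` (ms).
#' @export
spike_table <- function(traces, threshold = 0, guard = 1) {
  ids <- as.integer(sub("^v_", "", colnames(traces$v)))
  out <- lapply(seq_along(ids), function(j) {
    st <- detect_spikes(traces$v[, j], traces$time, threshold, guard)
    if (length(st)) data.frame(neuron = ids[j], time = st)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(neuron = integer(0), time = numeric(0))
  res
}

#' Group a spike train into bursts
#'
#' Maximal runs of spikes whose consecutive interspike intervals are all
#' below `isi_gap` form one burst. Burst duration is the time from the
#' first to the last spike peak.
#'
#' @param times Strictly increasing spike times (ms).
#' @param isi_gap Gap (ms) that separates bursts; default 15.
#' @return Data frame with one row per burst: `onset`, `offset`,
#'   `duration`, `n_spikes`, `mean_isi` (NA for single-spike bursts).
#' @export
group_bursts <- function(times, isi_gap = 15) {
  stopifnot(isi_gap > 0)
  if (!length(times)) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), n_spikes = integer(0),
                      mean_isi = numeric(0)))
  }
  stopifnot(!is.unsorted(times, strictly = TRUE))
  grp <- cumsum(c(1, diff(times) >= isi_gap))
  do.call(rbind, lapply(split(times, grp), function(ts) {
    data.frame(onset = ts[1L], offset = ts[length(ts)],
               duration = ts[length(ts)] - ts[1L],
               n_spikes = length(ts),
               mean_isi = if (length(ts) > 1L) mean(diff(ts)) else NA_real_)
  }))
}

#' Rheobase of an isolated neuron by bisection
#'
#' Finds, to `resolution`, the minimal constant background current that
#' elicits at least one spike from the isolated neuron over `duration`.
#' Both brackets are validated first: the lower must be spikeless and the
#' upper must spike.
#'
#' @param params Neuron parameters ([ra_neuron_params()] by default usage).
#' @param i_low,i_high Bracketing currents (pA).
#' @param resolution Bisection resolution (pA).
#' @param duration Simulated time per probe (ms).
#' @param dt Integration step (ms).
#' @return The threshold current (pA): the smallest probed current that
#'   spikes, within `resolution` of the true rheobase.
#' @export
rheobase_search <- function(params, i_low = 100, i_high = 300,
                            resolution = 1, duration = 500, dt = 0.02) {
  stopifnot(i_low < i_high, resolution > 0)
  n_spikes_at <- function(i_bg) {
    net <- build_single_neuron(params, i_background = i_bg)
    tr <- simulate_network(net, sim_config(duration = duration, dt = dt))
    length(detect_spikes(tr$v[, 1L], tr$time))
  }
  if (n_spikes_at(i_low) > 0) {
    stop(sprintf("invalid bracket: %g pA already elicits spikes", i_low),
         call. = FALSE)
  }
  if (n_spikes_at(i_high) == 0) {
    stop(sprintf("invalid bracket: %g pA elicits no spikes", i_high),
         call. = FALSE)
  }
  lo <- i_low
  hi <- i_high
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (n_spikes_at(mid) > 0) hi <- mid else lo <- mid
  }
  hi
}

#' Burst summary of a chain simulation
#'
#' Per-projection-neuron burst statistics plus the burst-onset intervals
#' for requested neuron pairs. Neurons that never burst are reported as
#' absent rows rather than errors.
#'
#' @param traces An `hvc_traces` from a chain network.
#' @param pairs Optional list of 2-vectors of RA indices (1-based position
#'   along the chain) whose onset differences are reported.
#' @param isi_gap Burst-grouping gap (ms).
#' @return A list with `bursts` (data frame: `ra_index`, `neuron`,
#'   `n_bursts`, `onset`, `duration`, `n_spikes` of the first burst) and
#'   `intervals` (data frame: `from`, `to`, `interval` in ms).
#' @export
chain_summary <- function(traces, pairs = list(c(2, 25), c(25, 26), c(2, 50)),
                          isi_gap = 15) {
  ids <- ra_neuron_ids(traces$net)
  tab <- spike_table(traces)
  rows <- lapply(seq_along(ids), function(i) {
    ts <- tab$time[tab$neuron == ids[i]]
    b <- group_bursts(ts, isi_gap)
    data.frame(ra_index = i, neuron = ids[i], n_bursts = nrow(b),
               onset = if (nrow(b)) b$onset[1L] else NA_real_,
               duration = if (nrow(b)) b$duration[1L] else NA_real_,
               n_spikes = if (nrow(b)) b$n_spikes[1L] else 0L)
  })
  bursts <- do.call(rbind, rows)
  intervals <- NULL
  if (length(pairs)) {
    intervals <- do.call(rbind, lapply(pairs, function(p) {
      p <- as.integer(p)
      if (any(p < 1L | p > length(ids))) {
        stop("pair indices must address RA neurons present in the chain",
             call. = FALSE)
      }
      data.frame(from = p[1L], to = p[2L],
                 interval = bursts$onset[p[2L]] - bursts$onset[p[1L]])
    }))
  }
  list(bursts = bursts, intervals = intervals)
}

#' Classify burst propagation along a chain
#'
#' Implements the three regimes of the conductance-robustness analysis:
#' a `"faithful copy"` when every projection neuron repeats the same spike
#' count as the second neuron; `"decaying"` when counts never increase
#' along the chain and shrink below that reference (vanishing entirely in
#' the strongly subcritical regime); `"growing"` when counts never
#' decrease and exceed it.
#'
#' @param n_spikes Integer vector of first-burst spike counts, ordered
#'   along the chain (position 1 = first projection neuron).
#' @return One of `"faithful copy"`, `"decaying"`, `"growing"`, `"mixed"`.
#' @export
classify_propagation <- function(n_spikes) {
  stopifnot(length(n_spikes) >= 2L)
  ref <- n_spikes[2L]
  later <- n_spikes[-1L]          # the first neuron's burst is trigger-shaped
  if (all(later == ref)) return("faithful copy")
  if (all(diff(later) <= 0L) && any(later < ref)) return("decaying")
  if (all(diff(later) >= 0L) && any(later > ref)) return("growing")
  "mixed"
}

#' Sweep a chain conductance and summarize propagation
#'
#' Rebuilds the chain for each conductance value, simulates it, and
#' reports per-neuron spike counts together with the propagation
#' classification.
#'
#' @param g_values Conductance values (nS) to probe.
#' @param edge Which edge family to vary: `"chain"` (all RA->RA edges after
#'   the first) or `"first"` (the RA1->RA2 edge only).
#' @param n_ra Number of projection neurons in the probe chain.
#' @param duration Simulated time (ms).
#' @param dt Integration step (ms).
#' @param settle Warm-up time (ms) before the recorded window.
#' @param ... Further arguments to [build_chain_network()].
#' @return A list with `table` (data frame: `g`, `classification`,
#'   `min_spikes`, `max_spikes`, `last_spikes`) and `counts` (list of
#'   per-neuron spike-count vectors, one per value).
#' @export
sweep_conductance <- function(g_values, edge = c("chain", "first"),
                              n_ra = 50, duration = 200, dt = 0.02,
                              settle = 50, ...) {
  edge <- match.arg(edge)
  stopifnot(all(is.finite(g_values)))
  counts <- lapply(g_values, function(g) {
    net <- if (edge == "chain") {
      build_chain_network(n_ra = n_ra, g_chain = g, ...)
    } else {
      build_chain_network(n_ra = n_ra, g_first = g, ...)
    }
    tr <- simulate_network(net, sim_config(duration = duration, dt = dt,
                                           settle = settle))
    chain_summary(tr, pairs = NULL)$bursts$n_spikes
  })
  tab <- data.frame(
    g = g_values,
    classification = vapply(counts, classify_propagation, ""),
    min_spikes = vapply(counts, min, 0L),
    max_spikes = vapply(counts, max, 0L),
    last_spikes = vapply(counts, function(x) x[length(x)], 0L)
  )
  list(table = tab, counts = counts)
}

#' Sweep the trigger baseline concentration
#'
#' Scales `t_min` by each factor and measures the pulse peak, its width at
#' 10% of peak, and the transition time. Peak and width are measured
#' numerically on a fine grid so the claimed invariance is observed, not
#' assumed; the transition time comes from its closed form. Only the
#' transition time moves, by \eqn{-\tau_r \ln(\mathrm{factor})}.
#'
#' @param tp Trigger parameters to scale.
#' @param factors Positive multipliers for `t_min`.
#' @param dt Grid spacing (ms) for the numeric peak/width measurement.
#' @return Data frame: `factor`, `t_min`, `peak` (mM), `width10` (ms),
#'   `transition` (ms).
#' @export
sweep_tmin <- function(tp = trigger_params(), factors = c(0.1, 1, 10),
                       dt = 0.001) {
  stopifnot(all(factors > 0))
  do.call(rbind, lapply(factors, function(f) {
    tpf <- trigger_params(t_min = tp$t_min * f, t_peak = tp$t_peak,
                          tau_r = tp$tau_r, tau_f = tp$tau_f,
                          onset = tp$onset)
    tt <- transition_time(tpf)
    # include the exact transition point so the grid maximum is the peak
    tgrid <- sort(c(seq(tp$onset - 1, tp$onset + tt + 12 * tpf$tau_f,
                        by = dt), tp$onset + tt))
    conc <- trigger_concentration(tgrid, tpf)
    peak <- max(conc)
    above <- tgrid[conc >= 0.1 * peak]
    data.frame(factor = f, t_min = tpf$t_min, peak = peak,
               width10 = max(above) - min(above), transition = tt)
  }))
}
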