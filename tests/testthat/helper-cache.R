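# Expensive reference simulations, run once per test session.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.sim_cache[[key]])) assign(key, fn(), envir = .sim_cache)
  .sim_cache[[key]]
}

micro_traces <- function(bidirectional) {
  cached(paste0("micro_", bidirectional), function() {
    simulate_network(build_microcircuit(bidirectional),
                     sim_config(duration = 120, settle = 50))
  })
}

chain_traces <- function() {
  cached("chain_default", function() {
    simulate_network(build_chain_network(),
                     sim_config(duration = 200, settle = 50))
  })
}

ra_burst <- function(traces, column = 2L) {
  group_bursts(detect_spikes(traces$v[, column], traces$time))
}

# Synthetic voltage trace with gaussian spike bumps at given times.
synthetic_spike_trace <- function(spike_times, duration, dt = 0.02,
                                  baseline = -80, peak = 30, width = 0.3) {
  tgrid <- seq(0, duration, by = dt)
  v <- rep(baseline, length(tgrid))
  for (ts in spike_times) {
    v <- v + (peak - baseline) * exp(-(tgrid - ts)^2 / (2 * width^2))
  }
  list(time = tgrid, v = v)
}
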