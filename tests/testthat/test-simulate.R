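test_that("zero-duration run returns the initial state only", {
  net <- build_single_neuron(ra_neuron_params(), i_background = 0)
  tr <- simulate_network(net, sim_config(duration = 0))
  expect_equal(nrow(tr$v), 1L)
  expect_equal(unname(tr$v[1, 1]), -80)   # leak reversal start
})

test_that("gate variables stay in [0,1] throughout a network run", {
  tr <- micro_traces(TRUE)
  expect_gte(tr$gate_range[1], -1e-6)
  expect_lte(tr$gate_range[2], 1 + 1e-6)
  expect_gte(tr$r_range[1], -1e-6)
  expect_lte(tr$r_range[2], 1 + 1e-6)
})

test_that("non-finite states abort with a named diagnostic", {
  # a wildly unstable configuration: huge conductance, coarse step
  p <- ra_neuron_params(g_na = 1e9)
  net <- build_single_neuron(p, i_background = 300)
  expect_error(simulate_network(net, sim_config(duration = 5, dt = 0.5)),
               "non-finite state variable '.+' at t")
})

test_that("fixed-step RK4 agrees with an adaptive high-accuracy solver", {
  net <- build_microcircuit(TRUE)
  cfg <- sim_config(duration = 60)
  tr <- simulate_network(net, cfg)
  ode <- network_ode(net)
  ref <- deSolve::ode(y = ode$state0, times = tr$time,
                      func = function(t, y, p) list(ode$derivative(t, y)),
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  for (j in 1:2) {
    v_rk <- tr$v[, j]
    v_ref <- ref[, paste0("v_", j)]
    s_rk <- detect_spikes(v_rk, tr$time)
    s_ref <- detect_spikes(v_ref, tr$time)
    expect_equal(length(s_rk), length(s_ref))
    expect_lt(max(abs(s_rk - s_ref)), 0.1)
    # voltage agreement away from spikes; the mask covers the pre-spike
    # threshold-crossing shoulder (~2 ms), where a sub-step phase shift
    # on a ~100 mV/ms ramp dominates the pointwise difference
    near_spike <- Reduce(`|`, lapply(s_ref, function(s)
      abs(tr$time - s) < 2.5), rep(FALSE, length(tr$time)))
    expect_lt(max(abs(v_rk - v_ref)[!near_spike]), 0.5)
  }
})

test_that("step halving: linear system near machine precision, smooth
           nonlinear segment shows 4th-order error decay", {
  p <- ra_neuron_params(g_na = 0, g_k = 0)
  leak <- build_single_neuron(p, i_background = 0, v0 = -60)
  dev <- check_convergence(leak, sim_config(duration = 20))
  expect_lt(as.numeric(dev), 1e-8)
  # subthreshold projection neuron: smooth approach to rest
  sub <- build_single_neuron(ra_neuron_params(), i_background = 100)
  d1 <- as.numeric(check_convergence(sub, sim_config(duration = 30,
                                                     dt = 0.02)))
  d2 <- as.numeric(check_convergence(sub, sim_config(duration = 30,
                                                     dt = 0.01)))
  expect_gt(d1 / d2, 10)    # ~16x for a clean 4th-order method; the
  expect_lt(d1 / d2, 64)    # near-stability-limit m gate inflates the ratio
})

test_that("warm-up leaves the trigger-relative timeline intact", {
  net <- build_microcircuit(TRUE)
  tr <- micro_traces(TRUE)
  expect_equal(tr$time[1], 0)
  expect_equal(max(tr$time), 120)
  # projection neuron is silent before trigger onset (10 ms) after warm-up
  pre <- detect_spikes(tr$v[tr$time <= 10, 2], tr$time[tr$time <= 10])
  expect_length(pre, 0)
  # interneuron is tonically active before onset
  int_pre <- detect_spikes(tr$v[tr$time <= 10, 1], tr$time[tr$time <= 10])
  expect_gt(length(int_pre), 2)
})

test_that("single projection neuron spike count is monotone in current", {
  counts <- vapply(c(50, 150, 200, 300), function(i) {
    net <- build_single_neuron(ra_neuron_params(), i_background = i)
    tr <- simulate_network(net, sim_config(duration = 100))
    length(detect_spikes(tr$v[, 1], tr$time))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0L)    # 50 pA is subthreshold
  expect_gt(counts[4], 0L)
})
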